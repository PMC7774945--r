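# The desk-scale six-arm study shared by the end-to-end assertions.
# Expensive (several minutes), so it is computed once per test session.
desk_run <- function() memo("desk_run", suppressMessages(
  run_comparison(pipeline_config(seed = 1L))))
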
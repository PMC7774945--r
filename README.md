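# detomo

Dual-energy virtual-monochromatic super-resolution processing for
limited-angle chest digital tomosynthesis (DT), end to end and in pure
R/Rcpp: synthetic three-material chest phantoms, linear-sweep dual-energy
projection simulation, projection-space material decomposition and virtual
monochromatic (VM) synthesis, unsharp-masked residual-learning
super-resolution, SART / TV / FISTA iterative reconstruction, bilateral
post-filtering, and the image-quality metrology (SDNR, Gumbel ripple
statistics, radial MTF, NPS) to compare them.

## Who this is for

Researchers in tomographic image reconstruction who want a self-contained,
deterministic sandbox for projection-space dual-energy processing chains on
limited-angle geometries — e.g. to study how much of a ground-glass
nodule's contrast survives each stage, or how rib-induced "ripple" streaks
respond to regularisation and filtering — without device data.

## The models at the core

**Three-material decomposition.** For each detector pixel, with line
integrals `g` measured at two effective energies and linear attenuation
coefficients `mu_m(E)` of the basis materials (bone surrogate, soft
tissue, nodule foam),

    [ mu_b(E_l)  mu_s(E_l)  mu_n(E_l) ] [t_b]   [ g_low  ]
    [ mu_b(E_h)  mu_s(E_h)  mu_n(E_h) ] [t_s] = [ g_high ]
    [     1          1          1     ] [t_n]   [   L    ]

is solved for per-material path lengths, with `L` the total matter path
length (volume conservation). A VM projection at display energy `E` is
`V(E) = sum_m t_m mu_m(E)`; 60 keV maximises nodule contrast.

**Residual super-resolution.** A convolutional network `f` is trained on
down/upscaled projection pairs to predict the missing high-frequency
residual, applied through a skip connection: `G = S(H) + f(S(H))`, after
unsharp masking `k (V - G_sigma V) + V`.

**SART–TV–FISTA.** Per outer iteration: a relaxed SART sweep
`s <- s + lambda * (A^T W_r (g - A s)) / W_v`, 20 steepest-descent steps on
the total variation `||s||_TV = sum sqrt(dx^2 + dy^2 + dz^2)` with
per-voxel step `beta * ||s - s_0||`, and the FISTA extrapolation with
`t' = (1 + sqrt(1 + 4 t^2)) / 2`.

**Bilateral filter.** Normalised double-Gaussian weighting (spatial SD
`sigma_d`, window `2(2 sigma_d) + 1`; range SD `sigma_r` on the
min/max-normalised slice).

## Worked example

The whole study — simulate one dual-energy acquisition of a chest phantom
with a 5 mm nodule, then reconstruct and score six processing arms — is one
call:

```r
library(detomo)
run <- run_comparison(pipeline_config(seed = 1))
print(run)
```

```
<comparison_report>
  note: polychromatic arms use the high-energy effective-monochromatic stack as the polychromatic stand-in
  fbp                    SDNR  0.2200  ripple  0.06311  hf-NPS 3.490e-02
  sart                   SDNR  0.2000  ripple  0.05997  hf-NPS 2.016e-01
  sart_tv_fista          SDNR  1.3743  ripple  0.01639  hf-NPS 1.601e-05
  de_vm_sart_tv_fista    SDNR  1.2338  ripple  0.01315  hf-NPS 2.201e-05
  de_vm_vdsr             SDNR  0.8220  ripple  0.02157  hf-NPS 1.381e-04
  de_vm_vdsr_bf          SDNR  1.0488  ripple  0.00972  hf-NPS 4.440e-05
```

Reading the columns: **SDNR** is the nodule's signal-difference-to-noise
ratio on the in-focus slice (higher is better) — the TV-regularised
iterative arms recover several times the nodule contrast of FBP/SART;
unsharp masking + SR sharpen the projections at a noise cost that the
bilateral filter then partly wins back. **ripple** is the mean Gumbel
largest adjacent-pixel variation inside a lung window aligned with the
sweep axis, after calibrating each slice to the ground-truth attenuation
scale (lower is better) — unregularised FBP is worst and the with-BF arm
best. **hf-NPS** is the high-frequency noise power on a companion uniform
water phantom in the same calibrated units (lower is better) — TV
regularisation suppresses water noise by four orders of magnitude
relative to plain SART.

Individual stages are plain functions if you want to compose your own
chain:

```r
ph   <- make_chest_phantom()
geom <- acquisition_geometry("desk")
de   <- simulate_dual_energy(ph, geom, 40, 70, n0 = 2e5, seed = 1)
fra  <- decompose(de$low, de$high)
vm   <- synthesize_vm(fra, 60)
vol  <- reconstruct(vm, "sart_tv_fista", recon_grid(c(128, 128, 64), c(2, 2, 4)))
slice <- in_focus_plane(vol)
```

A thin command-line wrapper over the same functions lives at
`inst/scripts/detomo.R` (phantom / simulate / vm / recon / bf / run
subcommands; volumes and stacks travel as multi-page 32-bit TIFF with JSON
sidecars).

See `vignettes/detomo-methods.Rmd` for the models, parameter meanings and
the numerical design decisions.

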
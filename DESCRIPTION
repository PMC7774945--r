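Package: detomo
Title: Dual-Energy Virtual-Monochromatic Super-Resolution Digital Tomosynthesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for limited-angle
    dual-energy chest digital tomosynthesis. Generates three-material digital
    chest phantoms, simulates linear-sweep dual-energy projection acquisitions,
    performs projection-space three-material decomposition and virtual
    monochromatic synthesis, sharpens projections with an unsharp-masked
    residual-learning super-resolution network, reconstructs volumes with
    filtered backprojection, SART and TV-regularised FISTA-accelerated SART,
    applies edge-preserving bilateral post-filtering, and evaluates image
    quality with RMSE, SDNR, Gumbel extreme-value ripple statistics, radial
    MTF and noise power spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tiff,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
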
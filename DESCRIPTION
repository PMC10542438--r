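Package: spectval
Title: Quantitative Validation of Monte Carlo SPECT Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitatively validating Monte Carlo simulations of
    gamma-camera (SPECT) systems against experimental acquisitions. Provides
    an energy-dependent intrinsic-efficiency correction workflow (photopeak
    fitting, absolute-efficiency calculation with full uncertainty
    propagation, weighted log-quadratic correction fits with a
    perturbation-refit uncertainty band, and event-by-event Poisson-sampled
    application), energy-spectrum comparison with per-bin percentage
    residuals and window-weighted means, projection-domain metrics
    (sensitivity and sensitivity ratios, sinogram consistency checks, peak
    signal-to-noise ratio with a shifted-self baseline, Gaussian profile
    FWHM with two-axis uncertainties), quadrature uncertainty budgets, and a
    synthetic-data module that emulates calibration-ampoule spectra,
    dual-head phantom acquisitions with radioactive decay, point-source
    planar images and background acquisitions with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    minpack.lm
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
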
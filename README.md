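# spectval

Quantitative validation of Monte Carlo SPECT simulations in R.

Monte Carlo simulations of gamma cameras (GATE/Geant4 and friends) are
routinely used as a "ground truth" for scatter studies, energy-window
optimisation and quantification research — but a simulation is only a ground
truth after it has been validated against the physical scanner with known
uncertainties. `spectval` implements that validation workflow as a tested,
reusable pipeline for medical-physics researchers: it derives the
energy-dependent intrinsic-efficiency correction that reconciles a simulated
camera with a real one, applies it event by event, propagates every
uncertainty, and quantifies simulation/experiment agreement in both the
spectrum and the projection domain.

## The method

**Intrinsic efficiency.** For each gamma line of a set of traceable
calibration sources, a Gaussian (plus linear local background) is fitted to
the photopeak and the absolute detection efficiency is

    eps = N / (A * I_gamma),
    (sigma_eps/eps)^2 = (sigma_N/N)^2 + (sigma_A/A)^2 + (sigma_I/I)^2,

with *N* the net count rate, *A* the activity and *I_gamma* the emission
intensity (all uncertainties standard, k = 1, assumed uncorrelated).

**Efficiency correction.** The per-line ratios of experimental to simulated
efficiency are fitted with the log-quadratic form conventional for NaI
detectors,

    eps_cor(E) = a + b ln(E) + c ln^2(E)   for E >= E_break,

with a linear piece below the lowest calibration energy (46 keV for the
reference camera) anchored to zero at 2 keV. The fit uncertainty is the
standard deviation of 1000 refits after perturbing each ratio point by a
normal deviate with its own standard uncertainty. The correction is applied
to the simulated event list by event-by-event Poisson sampling
(`k ~ Poisson(eps_cor(E))` replicates per event).

**Agreement metrics.** With the corrected simulation in hand:

* per-bin percentage residuals between simulated and experimental energy
  spectra (compared as counts/s, 2 keV bins) with inverse-variance
  window-weighted means;
* sensitivity `S = c/(A*T)` in counts/(s·MBq) per energy window, with
  `(sigma_S/S)^2 = (sigma_c/c)^2 + (sigma_A/A)^2 + (sigma_eps/eps)^2`, and
  simulation/experiment sensitivity ratios;
* per-projection sinogram ratios against the ±3σ band of the sensitivity
  ratio;
* slice-wise PSNR (`20 log10(32768/sqrt(MSE))`) against a shifted-self
  experimental baseline;
* point-source FWHM from Gaussian profile fits with uncertainties on both
  axes (Poisson on counts, half a pixel on position).

A synthetic-data module generates every input with known ground truth —
calibration-ampoule spectra, dual-head tomographic phantom acquisitions with
radioactive decay, point-source planar images, backgrounds — so the whole
pipeline closes on itself in the test suite.

## Worked example

```r
library(spectval)

## published-table arithmetic -------------------------------------------
combineQuadrature(refActivityBudget("Tc-99m"))
#> [1] 0.892          # percent, activity uncertainty combined in quadrature

tab <- refSensitivityTable("Tc-99m")
sensitivityRatio(vu(tab$sim[1], tab$sim_sigma[1]),
                 vu(tab$exp[1], tab$exp_sigma[1]))
#> 0.9717 ± 0.02132   # cylinder EM window, simulation/experiment

weightedMeanVU(tab$ratio, tab$ratio_sigma)
#> 0.9909 ± 0.01109   # average sensitivity ratio over all Tc-99m windows

## the reference piecewise efficiency correction ------------------------
corr <- referenceCorrection()
evaluateCorrection(corr, c(2, 46, 113, 140.5, 208))
#> [1] 0.0000 0.2987 0.5365 0.5533 0.5433

## full synthetic closure run -------------------------------------------
cfg <- readRunConfig(system.file("extdata", "demo_config.yaml",
                                 package = "spectval"))
rep <- runValidation(cfg, reportDir = "demo_report")
rep$sinogram$EM@weightedMean    # 1 ± 0.003344
rep$spectrum$window_means$EM    # (-0.12 ± 0.33) %
rep$psnr$EM$sim_vs_exp          # 96.68 ± 0.18 dB (baseline 97.7 ± 0.18 dB)
```

The demo run generates a simulated and an "experimental" acquisition from
the same ground truth, derives the efficiency correction from synthetic
calibration spectra, and verifies closure: the sinogram weighted-mean ratio
is consistent with 1 and the window residual means with 0, each within 3σ.
The report directory receives `report.json` plus CSV tables of the residual
series and per-projection sinogram ratios.

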
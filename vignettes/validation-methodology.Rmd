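---
title: "Validating a Monte Carlo SPECT simulation: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a Monte Carlo SPECT simulation: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectval)
```

## The problem

A Monte Carlo model of a SPECT camera reproduces photon transport well but
not the electronic signal-processing chain, so raw simulated event lists
over-count relative to the physical scanner — increasingly so at low
energy. `spectval` implements the standard remedy: measure the camera's
absolute intrinsic efficiency with traceable calibration sources, measure
the same quantity in the simulation, and fold the ratio back into the
simulation event by event. Every downstream comparison (spectra,
sensitivities, sinograms, images, resolution) then carries the correction
and its uncertainty.

All uncertainties in the package are standard uncertainties (k = 1) and
all quadrature combinations assume uncorrelated components.

## The efficiency correction

For each calibration gamma line, `fitPhotopeak()` fits
$A\,e^{-(x-\mu)^2/2s^2} + b_0 + b_1 x$ to the spectrum inside a fit window
by least squares. The linear local background is our choice (ampoule
spectra sit on a scatter continuum; the term is testable against
constructed spectra and leaves a pure Gaussian's area untouched). The net
count rate is the Gaussian area over live time with its sigma from the
$(A, s)$ covariance by the delta method. `absoluteEfficiency()` then forms
$\varepsilon = N/(A\,I_\gamma)$ with relative sigmas added in quadrature.

`fitCorrection()` fits the experimental/simulated ratios with
$a + b\ln E + c\ln^2 E$, the conventional NaI efficiency form, by weighted
least squares with $1/\sigma^2$ weights. Whether the original analysis
weighted this fit is unknowable from the outside; inverse-variance is the
defensible default and an `unweighted` switch is provided. Below the lowest
calibration energy (46 keV for the reference camera) a linear piece joins
(2 keV, 0) to the log-quadratic's value at the breakpoint: the
log-quadratic alone would cross zero near 26 keV, whereas the measured
efficiency vanishes near 2 keV. The two pieces are allowed to be
discontinuous at the breakpoint when explicit published (rounded)
coefficients are supplied; evaluation clips at zero and the left piece
applies on [anchor, breakpoint).

The fit uncertainty band (`fitUncertaintyBand()`) perturbs every ratio
point by a normal deviate with the point's own sigma and refits, 1000
times by default; the per-energy band sigma is the sample standard
deviation of the refitted curves (linear piece re-derived per refit).
Refits that fail are excluded and counted; more than 5 % failures is an
error. Where a coverage statement is needed (the efficiency-recovery check
in the test suite), "inside the band" means within 1.96 band sigmas — a
95 % pointwise coverage convention; a 1-sigma band would cover only ~68 %
by construction.

`applyCorrection()` implements the event-by-event Poisson reading:
each event is replicated $k \sim \mathrm{Poisson}(\varepsilon_{cor}(E))$
times. This is the default because it generalises to corrections above
one; thinning (`mode = "thin"`, keep with probability
$\min(\varepsilon, 1)$) is offered for variance-sensitive studies and
clamps values above one with a warning. Both modes have expected output
count $\sum_i \varepsilon_{cor}(E_i)$ when the correction stays below one.

## Comparison metrics

**Spectra** are compared as count-rate densities (counts/s) so differing
live times cannot bias residuals; raw counts are kept for the Poisson
sigmas. Bins with zero experimental counts are excluded and counted —
a percentage residual is undefined there. The window-weighted mean is
inverse-variance with sigma $1/\sqrt{\sum 1/\sigma_i^2}$. When the two
spectra are known to have inconsistent absolute normalisations (the
reference scanner's spectrum-export software produced a slightly different
total than its projection images), `normaliseTotal()` rescales one to the
other's total; this touches only the spectrum comparison, never the
sensitivity chain.

**Sensitivity** is counts/(s·MBq) per isotope: branching ratios are
deliberately excluded because emission and scatter windows of the same
acquisition are compared side by side. The simulated sensitivity carries
the window-averaged relative band sigma of the applied correction as an
extra quadrature term; the experimental one carries the activity
uncertainty instead.

**Sinograms.** Per-projection count ratios are formed after dividing the
simulation by the measured sensitivity ratio, so sensitivity discrepancies
are validated separately from acquisition geometry. Projections are
flagged when $|r-1|$ exceeds three sigmas of that sensitivity ratio. For
the weighted mean the weights use the variance predicted under agreement
(proportional to the experimental projection counts): weights built from
each projection's *observed* sigma correlate with its own noise and bias
the mean low at small counts. With weights proportional to experimental
counts the weighted mean reduces to the ratio of summed counts — near one
by construction when the normalising ratio comes from the same stacks,
which is precisely why the per-projection band flags, not the mean, carry
most of the validation content.

**PSNR** uses $20\log_{10}(32768/\sqrt{\mathrm{MSE}})$ per projection
slice (32768 being the positive ceiling convention for unsigned 16-bit
projections) aggregated as a weighted mean ± weighted standard deviation
with slice total counts as weights — the plain reading of a "weighting
mean" over slices of very different occupancy. Zero-MSE slices are
reported as an infinite sentinel and excluded from the aggregate with a
count. Because PSNR is not absolute, the baseline compares each
experimental slice to itself shifted by one pixel along each in-plane
axis; the two single-axis shifted comparisons are pooled and the overlap
region only is used (no wrap-around, which would manufacture artificial
edges). Pooling per axis rather than applying one diagonal translation
keeps the baseline sensitive to structure along both axes — a diagonal
shift maps a checkerboard onto itself and would report perfect
self-similarity for a maximally structured image.

**FWHM.** A 1-pixel-wide profile is taken through the maximum-count pixel
("centre" of a point-source image is read as the peak position) and a
Gaussian plus constant is fitted with uncertainties on both axes: Poisson
on counts, half a pixel on position. No installed nonlinear
orthogonal-distance solver exists in this stack, so the two-axis contract
is implemented with the standard iterated effective-variance scheme,
$\sigma^2_{\mathrm{eff}} = \sigma_y^2 + f'(x)^2\sigma_x^2$, re-weighting a
Levenberg–Marquardt fit four times. The parameter covariance is taken
unscaled — the weights are absolute, known uncertainties — so the
half-pixel abscissa term propagates into the FWHM sigma. That matters: a
plain Gaussian fitted to pixel-integrated data overestimates the width by
roughly $w^2/12$ in variance (about 0.4 mm here), and only the
absolute-uncertainty covariance makes that bias visible as statistically
insignificant rather than hiding it behind a residual-rescaled sigma of a
few hundredths of a millimetre.

## The synthetic generators

The generators produce the statistical structure the analysis assumes and
nothing more. Calibration acquisitions place a Gaussian photopeak of
expected area $A\,I_\gamma\,\varepsilon(E)\,t$ per line (the efficiency
definition inverted) over a gently descending continuum truncated at the
line's Compton electron edge, all bins Poisson. Energy resolution follows
$r(E) = r(E_{ref})\sqrt{E_{ref}/E}$ from 9.5 % FWHM at 140 keV — the
inverse square-root extrapolation conventional for NaI digitiser models —
and spatial blurring is an isotropic 3.2 mm FWHM Gaussian. Phantom
acquisitions draw per-projection event counts from
activity × decay × head sensitivity × shape weight, with both heads
acquiring each rotation step simultaneously (so the last projection of
head 1 is acquired about half an hour after the first, and a dual-head
acquisition shows a decay discontinuity between projections 59 and 60).
The "experimental" partner is an independently seeded realisation thinned
by the ground-truth camera-efficiency curve and binned into unsigned
16-bit stacks. Point sources distribute a fixed total multinomially under
a 2-D Gaussian whose FWHM adds collimator and intrinsic blur in
quadrature, emulating a count-terminated acquisition. Backgrounds are
Poisson in rate × duration per bin or pixel.

What the generators deliberately do **not** model: photon transport,
attenuation and collimator septal penetration, energy-dependent spatial
resolution, detector dead time, non-circular orbits, and any realism of
the continuum beyond its statistical role. Passing closure tests therefore
demonstrates that the analysis chain is unbiased and propagates
uncertainty correctly under its own assumptions — not that any particular
physics model is right.

All generators are bit-reproducible: each artefact draws from a sub-stream
derived by stable hashing of the config seed and an artefact tag, so
generation order cannot change results.

## Numerical choices and degenerate inputs

* Energy windows and bins are half-open [lo, hi): an event exactly at a
  boundary belongs to the upper bin, so adjacent emission/scatter windows
  partition events with no double counting.
* Pixel convention: detector-face origin at the centre, pixel (0, 0)
  top-left, centres at $(i+0.5)\,\times$ pixel size; out-of-field events
  are counted and reported, never silently dropped.
* Photopeak fits start from the maximum bin and an eighth of the window
  width; non-convergence, all-zero and flat windows are errors with
  diagnostics, as are profile peaks on the image border.
* `weightedMeanVU()` treats a zero-sigma input as exact: it is returned
  verbatim, and disagreeing zero-sigma inputs are an error rather than a
  silent infinity.
* Spectrum grids must agree to 1e-9 before any bin-wise operation;
  empty simulated bins keep a finite residual sigma via a one-count floor.
* The demo/closure problem sizes are chosen for desk-scale runs: ~4×10⁵
  simulated events per phantom acquisition, 120 projections of 128×128
  pixels, 1000-refit bands, 500 000-count point sources. These reproduce
  the statistical behaviour of the method at a few seconds per full run.

## Known limitations

Sensitivity closure inherits whatever correlation exists between the
calibration constants used on both sides of a ratio; as in the underlying
methodology, activity and intensity sigmas are propagated as uncorrelated
even where they cancel, making the quoted ratio sigmas conservative.
Isotope-specific energy-correction maps (a camera acquired with a
different map can shift its sensitivity) are out of scope, as are
reconstruction-domain metrics and non-circular orbits.
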
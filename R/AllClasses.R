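#' @import methods
NULL

#' A scalar value with a standard uncertainty
#'
#' The currency of every metric in the package: a measured or derived scalar
#' together with its standard (k = 1) uncertainty.
#'
#' @slot value numeric scalar.
#' @slot sigma non-negative numeric scalar, the standard uncertainty.
#' @exportClass ValueWithUncertainty
setClass("ValueWithUncertainty",
  representation(value = "numeric", sigma = "numeric"),
  validity = function(object) {
    if (length(object@value) != 1L || length(object@sigma) != 1L)
      return("value and sigma must be scalars")
    if (is.na(object@value)) return("value must not be NA")
    if (!is.finite(object@sigma) || object@sigma < 0)
      return("sigma must be finite and >= 0")
    TRUE
  }
)

#' An acquisition energy window
#'
#' Windows are specified, as on the scanner console, by a centre energy and a
#' half-width in percent; the bounds are derived as centre * (1 -+ p/100) and
#' treated as half-open [lo, hi) so adjacent emission/scatter windows
#' partition events unambiguously.
#'
#' @slot label character label such as "EM", "SC", "EM1".
#' @slot centreKeV positive centre energy in keV.
#' @slot halfWidthPercent positive half width in percent of the centre.
#' @exportClass EnergyWindow
setClass("EnergyWindow",
  representation(label = "character", centreKeV = "numeric",
                 halfWidthPercent = "numeric"),
  validity = function(object) {
    if (length(object@centreKeV) != 1L || !is.finite(object@centreKeV) ||
        object@centreKeV <= 0)
      return("centreKeV must be a positive scalar")
    if (length(object@halfWidthPercent) != 1L ||
        !is.finite(object@halfWidthPercent) || object@halfWidthPercent <= 0)
      return("halfWidthPercent must be a positive scalar")
    TRUE
  }
)

#' A binned energy spectrum with live time
#'
#' Counts on a strictly increasing uniform energy grid (default bin width
#' 2 keV) together with the live time of the acquisition, so that spectra
#' with different durations can be compared as count rates.
#'
#' @slot binEdgesKeV numeric vector of bin edges, uniform and increasing.
#' @slot counts non-negative numeric vector, one per bin.
#' @slot liveTimeS positive live time in seconds.
#' @exportClass EnergySpectrum
setClass("EnergySpectrum",
  representation(binEdgesKeV = "numeric", counts = "numeric",
                 liveTimeS = "numeric"),
  validity = function(object) {
    ne <- length(object@binEdgesKeV)
    if (ne < 2L) return("need at least two bin edges")
    if (length(object@counts) != ne - 1L)
      return("length(counts) must equal length(binEdgesKeV) - 1")
    w <- diff(object@binEdgesKeV)
    if (any(w <= 0)) return("bin edges must be strictly increasing")
    if (max(abs(w - w[1])) > 1e-9 * w[1])
      return("bin grid must be uniform (within 1e-9 relative)")
    if (any(!is.finite(object@counts)) || any(object@counts < 0))
      return("counts must be finite and >= 0")
    if (length(object@liveTimeS) != 1L || !is.finite(object@liveTimeS) ||
        object@liveTimeS <= 0)
      return("liveTimeS must be a positive scalar")
    TRUE
  }
)

#' A stack of gamma-camera projection images
#'
#' An integer array of n_projections x rows x cols (default 120 x 128 x 128)
#' unsigned-16-bit pixel values with acquisition geometry: pixel size, time
#' per projection, and the dual-head layout (projections 0..59 belong to
#' head 1, 60..119 to head 2 in the default configuration).
#'
#' @slot pixels integer array, dim = c(nProjections, rows, cols).
#' @slot pixelSizeMm positive pixel size in mm (default 4.2578).
#' @slot timePerProjectionS positive time per projection in seconds.
#' @slot nHeads integer number of detector heads.
#' @slot projectionsPerHead integer projections acquired per head.
#' @exportClass ProjectionStack
setClass("ProjectionStack",
  representation(pixels = "array", pixelSizeMm = "numeric",
                 timePerProjectionS = "numeric", nHeads = "integer",
                 projectionsPerHead = "integer"),
  validity = function(object) {
    d <- dim(object@pixels)
    if (length(d) != 3L) return("pixels must be a 3-d array")
    if (!is.numeric(object@pixels)) return("pixels must be numeric")
    if (any(object@pixels < 0) || any(object@pixels > 65535))
      return("pixel values must lie in [0, 65535] (unsigned 16-bit)")
    if (any(object@pixels != round(object@pixels)))
      return("pixel values must be integers")
    if (d[1] != object@nHeads * object@projectionsPerHead)
      return("nProjections must equal nHeads * projectionsPerHead")
    if (object@pixelSizeMm <= 0) return("pixelSizeMm must be > 0")
    if (object@timePerProjectionS <= 0)
      return("timePerProjectionS must be > 0")
    TRUE
  }
)

#' A list of detected photon events with acquisition metadata
#'
#' One row per detected photon: deposited energy in keV, in-plane detector
#' coordinates in mm (origin at the detector face centre), the projection
#' index the event belongs to, and the time since acquisition start.
#'
#' @slot events data.frame with columns energy_keV, x_mm, y_mm,
#'   projection_index, time_s.
#' @slot nProjections integer number of projections in the owning acquisition.
#' @slot durationS total acquisition duration in seconds.
#' @exportClass DetectedEvents
setClass("DetectedEvents",
  representation(events = "data.frame", nProjections = "integer",
                 durationS = "numeric"),
  validity = function(object) {
    need <- c("energy_keV", "x_mm", "y_mm", "projection_index", "time_s")
    miss <- setdiff(need, names(object@events))
    if (length(miss))
      return(paste("missing event columns:", paste(miss, collapse = ", ")))
    ev <- object@events
    if (nrow(ev)) {
      if (any(!is.finite(ev$energy_keV)) || any(ev$energy_keV <= 0))
        return("energy_keV must be finite and > 0")
      if (any(ev$projection_index < 0) ||
          any(ev$projection_index >= object@nProjections))
        return("projection_index out of [0, nProjections)")
      if (any(ev$time_s < 0) || any(ev$time_s > object@durationS))
        return("time_s out of [0, durationS]")
    }
    if (object@nProjections < 1L) return("nProjections must be >= 1")
    if (object@durationS <= 0) return("durationS must be > 0")
    TRUE
  }
)

#' A single gamma-line calibration measurement
#'
#' One gamma emission of a traceable calibration source: its energy, emission
#' intensity and source activity (each with standard uncertainty), the live
#' time, and the acquired energy spectrum the photopeak is fitted in.
#'
#' @slot isotope character isotope label (e.g. "Tc-99m").
#' @slot energyKeV gamma-line energy in keV.
#' @slot intensityPercent [ValueWithUncertainty] emission intensity in percent.
#' @slot activityKBq [ValueWithUncertainty] source activity in kBq.
#' @slot liveTimeS live time of the acquisition in seconds.
#' @slot spectrum [EnergySpectrum] the acquired spectrum.
#' @exportClass CalibrationPoint
setClass("CalibrationPoint",
  representation(isotope = "character", energyKeV = "numeric",
                 intensityPercent = "ValueWithUncertainty",
                 activityKBq = "ValueWithUncertainty",
                 liveTimeS = "numeric", spectrum = "EnergySpectrum"),
  validity = function(object) {
    ip <- object@intensityPercent@value
    if (ip <= 0 || ip > 100)
      return("intensityPercent must lie in (0, 100]")
    if (object@activityKBq@value <= 0) return("activity must be > 0")
    if (object@energyKeV <= 0) return("energyKeV must be > 0")
    if (object@liveTimeS <= 0) return("liveTimeS must be > 0")
    TRUE
  }
)

#' An absolute-efficiency measurement at one energy
#'
#' The absolute detection efficiency epsilon = N / (A * I_gamma) at one
#' gamma-line energy, with its propagated standard uncertainty.
#'
#' @slot energyKeV gamma-line energy in keV.
#' @slot epsilon [ValueWithUncertainty] absolute efficiency.
#' @slot label character source label.
#' @exportClass EfficiencyPoint
setClass("EfficiencyPoint",
  representation(energyKeV = "numeric", epsilon = "ValueWithUncertainty",
                 label = "character"),
  validity = function(object) {
    if (object@energyKeV <= 0) return("energyKeV must be > 0")
    if (object@epsilon@value < 0) return("efficiency must be >= 0")
    TRUE
  }
)

#' The piecewise energy-dependent efficiency-correction function
#'
#' A log-quadratic a + b ln(E) + c ln^2(E) above the breakpoint energy
#' (the lowest calibration energy, 46 keV by default) and a linear piece
#' below it, anchored so the correction vanishes at the anchor energy
#' (2 keV by default). Evaluations are clipped below at zero. An optional
#' refit ensemble (one coefficient triple per perturbation refit) provides a
#' per-energy uncertainty band.
#'
#' @slot a,b,c log-quadratic coefficients.
#' @slot breakpointKeV switch-over energy in keV.
#' @slot slope,intercept coefficients of the linear low-energy piece.
#' @slot anchorKeV energy at which the linear piece vanishes.
#' @slot ensemble numeric matrix (n_refits x 3) of perturbed-refit
#'   coefficients, or a 0-row matrix when no band has been computed.
#' @exportClass EfficiencyCorrection
setClass("EfficiencyCorrection",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 breakpointKeV = "numeric", slope = "numeric",
                 intercept = "numeric", anchorKeV = "numeric",
                 ensemble = "matrix"),
  prototype(ensemble = matrix(numeric(0), 0, 3)),
  validity = function(object) {
    for (nm in c("a", "b", "c", "breakpointKeV", "slope", "intercept",
                 "anchorKeV"))
      if (length(slot(object, nm)) != 1L || !is.finite(slot(object, nm)))
        return(paste(nm, "must be a finite scalar"))
    if (object@breakpointKeV <= object@anchorKeV)
      return("breakpointKeV must exceed anchorKeV")
    at_anchor <- object@intercept + object@slope * object@anchorKeV
    if (abs(at_anchor) > 1e-9)
      return("linear piece must vanish at the anchor energy")
    if (ncol(object@ensemble) != 3L)
      return("ensemble must have 3 columns (a, b, c)")
    TRUE
  }
)

#' A named uncertainty budget combined in quadrature
#'
#' An ordered list of independent (uncorrelated) percentage uncertainty
#' components; the combined uncertainty is the square root of the sum of
#' squares.
#'
#' @slot components data.frame with columns component (character) and
#'   percent (non-negative numeric).
#' @exportClass UncertaintyBudget
setClass("UncertaintyBudget",
  representation(components = "data.frame"),
  validity = function(object) {
    cmp <- object@components
    if (!all(c("component", "percent") %in% names(cmp)))
      return("components needs columns 'component' and 'percent'")
    if (nrow(cmp) == 0L) return("budget must have at least one component")
    if (any(!is.finite(cmp$percent)) || any(cmp$percent < 0))
      return("all components must be finite and >= 0")
    TRUE
  }
)

#' The digitiser blurring model of the simulated camera
#'
#' Energy resolution is specified as a FWHM fraction at a reference energy
#' and extrapolated with an inverse square-root law,
#' r(E) = r(E_ref) * sqrt(E_ref / E); intrinsic spatial blurring is an
#' isotropic Gaussian of fixed FWHM.
#'
#' @slot energyResolutionFwhmAtRef FWHM fraction at the reference energy
#'   (default 0.095, i.e. 9.5 percent).
#' @slot referenceEnergyKeV reference energy in keV (default 140).
#' @slot spatialFwhmMm intrinsic spatial FWHM in mm (default 3.2).
#' @exportClass DigitiserModel
setClass("DigitiserModel",
  representation(energyResolutionFwhmAtRef = "numeric",
                 referenceEnergyKeV = "numeric", spatialFwhmMm = "numeric"),
  prototype(energyResolutionFwhmAtRef = 0.095, referenceEnergyKeV = 140,
            spatialFwhmMm = 3.2),
  validity = function(object) {
    r <- object@energyResolutionFwhmAtRef
    if (r <= 0 || r >= 1) return("resolution fraction must be in (0, 1)")
    if (object@referenceEnergyKeV <= 0)
      return("referenceEnergyKeV must be > 0")
    if (object@spatialFwhmMm <= 0) return("spatialFwhmMm must be > 0")
    TRUE
  }
)

#' Activity and emission model of a synthetic phantom acquisition
#'
#' @slot totalActivityMBq [ValueWithUncertainty] activity at acquisition
#'   start, in MBq.
#' @slot halfLifeS half-life in seconds (Inf disables decay).
#' @slot headSensitivity length-2 positive reals, relative sensitivity of the
#'   two detector heads (default c(1, 1)).
#' @slot lines data.frame with columns energy_keV and intensity (relative
#'   emission intensities, need not sum to 1).
#' @slot scatterFraction fraction of detected counts in the scatter
#'   continuum below each photopeak.
#' @slot sensitivityCountsPerMBqS detected counts per second per MBq at unit
#'   head sensitivity; sets the statistical scale of the acquisition.
#' @slot sourceSigmaMm in-plane Gaussian extent of the projected source
#'   distribution, mm.
#' @exportClass PhantomActivitySpec
setClass("PhantomActivitySpec",
  representation(totalActivityMBq = "ValueWithUncertainty",
                 halfLifeS = "numeric", headSensitivity = "numeric",
                 lines = "data.frame", scatterFraction = "numeric",
                 sensitivityCountsPerMBqS = "numeric",
                 sourceSigmaMm = "numeric"),
  validity = function(object) {
    if (object@totalActivityMBq@value <= 0) return("activity must be > 0")
    if (object@halfLifeS <= 0) return("halfLifeS must be > 0")
    if (length(object@headSensitivity) != 2L ||
        any(object@headSensitivity <= 0))
      return("headSensitivity must be two positive reals")
    if (!all(c("energy_keV", "intensity") %in% names(object@lines)))
      return("lines needs columns energy_keV and intensity")
    if (any(object@lines$intensity <= 0) || any(object@lines$energy_keV <= 0))
      return("line energies and intensities must be > 0")
    if (object@scatterFraction < 0 || object@scatterFraction >= 1)
      return("scatterFraction must be in [0, 1)")
    if (object@sensitivityCountsPerMBqS <= 0)
      return("sensitivityCountsPerMBqS must be > 0")
    if (object@sourceSigmaMm <= 0) return("sourceSigmaMm must be > 0")
    TRUE
  }
)

#' Per-bin percentage residuals between two spectra
#'
#' @slot binCentresKeV bin centres in keV.
#' @slot residualPercent per-bin residual 100 * (sim - exp) / exp.
#' @slot sigmaPercent statistical standard uncertainty of each residual.
#' @slot nExcluded number of bins excluded because the experimental count
#'   was zero.
#' @exportClass ResidualSeries
setClass("ResidualSeries",
  representation(binCentresKeV = "numeric", residualPercent = "numeric",
                 sigmaPercent = "numeric", nExcluded = "integer"),
  validity = function(object) {
    n <- length(object@binCentresKeV)
    if (length(object@residualPercent) != n ||
        length(object@sigmaPercent) != n)
      return("residual arrays must have equal length")
    if (any(object@sigmaPercent < 0)) return("sigma must be >= 0")
    TRUE
  }
)

#' A sensitivity measurement for one energy window
#'
#' @slot S [ValueWithUncertainty] sensitivity in counts/(s x MBq).
#' @slot window character window label.
#' @slot source "simulation" or "experiment".
#' @exportClass SensitivityResult
setClass("SensitivityResult",
  representation(S = "ValueWithUncertainty", window = "character",
                 source = "character"),
  validity = function(object) {
    if (object@S@value < 0) return("sensitivity must be >= 0")
    if (!object@source %in% c("simulation", "experiment"))
      return("source must be 'simulation' or 'experiment'")
    TRUE
  }
)

#' Per-projection sinogram comparison of two stacks
#'
#' @slot ratio per-projection sim/exp count ratio (NA where excluded).
#' @slot sigma per-projection Poisson standard uncertainty of the ratio.
#' @slot flagged logical, TRUE where |ratio - 1| exceeds 3 x the
#'   sensitivity-ratio sigma.
#' @slot weightedMean [ValueWithUncertainty] inverse-variance weighted mean
#'   ratio over projections.
#' @slot bandSigma the sensitivity-ratio sigma defining the +-3 sigma band.
#' @slot nExcluded projections excluded for zero experimental counts.
#' @exportClass SinogramComparison
setClass("SinogramComparison",
  representation(ratio = "numeric", sigma = "numeric", flagged = "logical",
                 weightedMean = "ValueWithUncertainty", bandSigma = "numeric",
                 nExcluded = "integer"))
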
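#' Create a value with standard uncertainty
#'
#' @param value numeric scalar.
#' @param sigma non-negative standard uncertainty (default 0).
#' @return a [ValueWithUncertainty-class].
#' @examples
#' vu(36.33, 0.73)
#' @export
vu <- function(value, sigma = 0) {
  new("ValueWithUncertainty", value = as.numeric(value),
      sigma = as.numeric(sigma))
}

#' @rdname ValueWithUncertainty-class
#' @aliases uValue,ValueWithUncertainty-method
setMethod("uValue", "ValueWithUncertainty", function(object) object@value)

#' @rdname ValueWithUncertainty-class
#' @aliases uSigma,ValueWithUncertainty-method
setMethod("uSigma", "ValueWithUncertainty", function(object) object@sigma)

setMethod("show", "ValueWithUncertainty", function(object) {
  cat(formatVU(object), "\n")
})

#' Format a value with uncertainty as "value +- sigma"
#'
#' @param x a [ValueWithUncertainty-class].
#' @param digits significant digits for display.
#' @return character scalar.
#' @export
formatVU <- function(x, digits = 4) {
  paste0(signif(x@value, digits), " ± ", signif(x@sigma, digits))
}

#' Create an energy window
#'
#' @param label window label, e.g. "EM" or "SC1".
#' @param centreKeV centre energy in keV.
#' @param halfWidthPercent half width as percent of the centre.
#' @return an [EnergyWindow-class].
#' @examples
#' em <- energyWindow("EM", 140.5, 10)
#' windowBounds(em)
#' @export
energyWindow <- function(label, centreKeV, halfWidthPercent) {
  new("EnergyWindow", label = as.character(label),
      centreKeV = as.numeric(centreKeV),
      halfWidthPercent = as.numeric(halfWidthPercent))
}

#' @rdname windowBounds
#' @aliases windowBounds,EnergyWindow-method
setMethod("windowBounds", "EnergyWindow", function(window) {
  p <- window@halfWidthPercent / 100
  c(lo_keV = window@centreKeV * (1 - p), hi_keV = window@centreKeV * (1 + p))
})

setMethod("show", "EnergyWindow", function(object) {
  b <- windowBounds(object)
  cat(sprintf("EnergyWindow %s: %.4g keV ± %.4g%% -> [%.4g, %.4g) keV\n",
              object@label, object@centreKeV, object@halfWidthPercent,
              b[1], b[2]))
})

#' Which events/energies fall inside a window
#'
#' Half-open convention: an energy exactly at the upper bound is outside.
#'
#' @param energyKeV numeric vector of energies.
#' @param window an [EnergyWindow-class].
#' @return logical vector.
#' @export
inWindow <- function(energyKeV, window) {
  b <- windowBounds(window)
  energyKeV >= b[[1]] & energyKeV < b[[2]]
}

#' Create an energy spectrum
#'
#' @param binEdgesKeV uniform increasing bin edges in keV.
#' @param counts counts per bin.
#' @param liveTimeS live time in seconds.
#' @return an [EnergySpectrum-class].
#' @export
energySpectrum <- function(binEdgesKeV, counts, liveTimeS) {
  new("EnergySpectrum", binEdgesKeV = as.numeric(binEdgesKeV),
      counts = as.numeric(counts), liveTimeS = as.numeric(liveTimeS))
}

#' @rdname EnergySpectrum-class
#' @aliases binEdges,EnergySpectrum-method
setMethod("binEdges", "EnergySpectrum", function(object) object@binEdgesKeV)

#' @rdname EnergySpectrum-class
#' @aliases binCentres,EnergySpectrum-method
setMethod("binCentres", "EnergySpectrum", function(object) {
  e <- object@binEdgesKeV
  (e[-1] + e[-length(e)]) / 2
})

#' @rdname EnergySpectrum-class
#' @aliases binWidth,EnergySpectrum-method
setMethod("binWidth", "EnergySpectrum",
          function(object) diff(object@binEdgesKeV[1:2]))

#' @rdname EnergySpectrum-class
#' @aliases specCounts,EnergySpectrum-method
setMethod("specCounts", "EnergySpectrum", function(object) object@counts)

#' @rdname EnergySpectrum-class
#' @aliases liveTime,EnergySpectrum-method
setMethod("liveTime", "EnergySpectrum", function(object) object@liveTimeS)

setMethod("show", "EnergySpectrum", function(object) {
  e <- object@binEdgesKeV
  cat(sprintf(paste0("EnergySpectrum: %d bins of %.4g keV on [%.4g, %.4g] ",
                     "keV, %.6g counts in %.6g s live time\n"),
              length(object@counts), binWidth(object), e[1], e[length(e)],
              sum(object@counts), object@liveTimeS))
})

#' Create a projection stack
#'
#' @param pixels integer array of dim c(nProjections, rows, cols); a matrix
#'   is promoted to a single-projection stack.
#' @param pixelSizeMm pixel size in mm.
#' @param timePerProjectionS acquisition time per projection in seconds.
#' @param nHeads number of detector heads.
#' @param projectionsPerHead projections per head.
#' @return a [ProjectionStack-class].
#' @export
projectionStack <- function(pixels, pixelSizeMm = 4.2578,
                            timePerProjectionS = 32, nHeads = 2L,
                            projectionsPerHead = 60L) {
  if (is.matrix(pixels)) {
    pixels <- array(pixels, dim = c(1L, nrow(pixels), ncol(pixels)))
    nHeads <- 1L
    projectionsPerHead <- 1L
  }
  storage.mode(pixels) <- "integer"
  new("ProjectionStack", pixels = pixels,
      pixelSizeMm = as.numeric(pixelSizeMm),
      timePerProjectionS = as.numeric(timePerProjectionS),
      nHeads = as.integer(nHeads),
      projectionsPerHead = as.integer(projectionsPerHead))
}

#' @rdname ProjectionStack-class
#' @aliases pixelData,ProjectionStack-method
setMethod("pixelData", "ProjectionStack", function(object) object@pixels)

#' @rdname ProjectionStack-class
#' @aliases pixelSize,ProjectionStack-method
setMethod("pixelSize", "ProjectionStack", function(object) object@pixelSizeMm)

#' @rdname ProjectionStack-class
#' @aliases nProjections,ProjectionStack-method
setMethod("nProjections", "ProjectionStack",
          function(object) dim(object@pixels)[1])

setMethod("show", "ProjectionStack", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(paste0("ProjectionStack: %d x %d x %d, %.4f mm pixels, ",
                     "%g s/projection, %d head(s), %.6g total counts\n"),
              d[1], d[2], d[3], object@pixelSizeMm,
              object@timePerProjectionS, object@nHeads,
              sum(as.numeric(object@pixels))))
})

#' Create a detected-event list
#'
#' @param events data.frame with columns energy_keV, x_mm, y_mm,
#'   projection_index (0-based), time_s.
#' @param nProjections number of projections in the acquisition.
#' @param durationS total acquisition duration in seconds.
#' @return a [DetectedEvents-class].
#' @export
detectedEvents <- function(events, nProjections, durationS) {
  new("DetectedEvents", events = as.data.frame(events),
      nProjections = as.integer(nProjections),
      durationS = as.numeric(durationS))
}

#' @rdname DetectedEvents-class
#' @aliases eventData,DetectedEvents-method
setMethod("eventData", "DetectedEvents", function(object) object@events)

#' @rdname DetectedEvents-class
#' @aliases nProjections,DetectedEvents-method
setMethod("nProjections", "DetectedEvents",
          function(object) object@nProjections)

setMethod("length", "DetectedEvents", function(x) nrow(x@events))

setMethod("show", "DetectedEvents", function(object) {
  cat(sprintf(
    "DetectedEvents: %d events, %d projections, %.6g s duration\n",
    nrow(object@events), object@nProjections, object@durationS))
})

#' Create a calibration point
#'
#' @param isotope isotope label.
#' @param energyKeV gamma-line energy in keV.
#' @param intensityPercent [ValueWithUncertainty-class] emission intensity, %.
#' @param activityKBq [ValueWithUncertainty-class] activity in kBq.
#' @param liveTimeS live time in seconds.
#' @param spectrum the acquired [EnergySpectrum-class].
#' @return a [CalibrationPoint-class].
#' @export
calibrationPoint <- function(isotope, energyKeV, intensityPercent,
                             activityKBq, liveTimeS, spectrum) {
  new("CalibrationPoint", isotope = as.character(isotope),
      energyKeV = as.numeric(energyKeV),
      intensityPercent = intensityPercent, activityKBq = activityKBq,
      liveTimeS = as.numeric(liveTimeS), spectrum = spectrum)
}

setMethod("show", "CalibrationPoint", function(object) {
  cat(sprintf(
    "CalibrationPoint %s @ %g keV: I = %s %%, A = %s kBq, t = %g s\n",
    object@isotope, object@energyKeV, formatVU(object@intensityPercent),
    formatVU(object@activityKBq), object@liveTimeS))
})
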
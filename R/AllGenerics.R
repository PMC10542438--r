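#' @rdname ValueWithUncertainty-class
#' @param object a package object.
#' @export
setGeneric("uValue", function(object) standardGeneric("uValue"))

#' @rdname ValueWithUncertainty-class
#' @export
setGeneric("uSigma", function(object) standardGeneric("uSigma"))

#' @rdname EnergySpectrum-class
#' @export
setGeneric("binEdges", function(object) standardGeneric("binEdges"))

#' @rdname EnergySpectrum-class
#' @export
setGeneric("binCentres", function(object) standardGeneric("binCentres"))

#' @rdname EnergySpectrum-class
#' @export
setGeneric("binWidth", function(object) standardGeneric("binWidth"))

#' @rdname EnergySpectrum-class
#' @export
setGeneric("specCounts", function(object) standardGeneric("specCounts"))

#' @rdname EnergySpectrum-class
#' @export
setGeneric("liveTime", function(object) standardGeneric("liveTime"))

#' @rdname ProjectionStack-class
#' @export
setGeneric("pixelData", function(object) standardGeneric("pixelData"))

#' @rdname ProjectionStack-class
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname DetectedEvents-class
#' @export
setGeneric("eventData", function(object) standardGeneric("eventData"))

#' @rdname DetectedEvents-class
#' @export
setGeneric("nProjections", function(object) standardGeneric("nProjections"))

#' Bounds of an energy window
#'
#' Derive the half-open bounds \[lo, hi) of an [EnergyWindow-class] as
#' `centre * (1 - p/100)` and `centre * (1 + p/100)`.
#'
#' @param window an [EnergyWindow-class].
#' @return named numeric vector `c(lo_keV = ..., hi_keV = ...)`.
#' @examples
#' windowBounds(energyWindow("EM", 140.5, 10))  # 126.45, 154.55
#' @export
setGeneric("windowBounds", function(window) standardGeneric("windowBounds"))

#' @rdname UncertaintyBudget-class
#' @param object a package object.
#' @export
setGeneric("combinedPercent",
           function(object) standardGeneric("combinedPercent"))
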
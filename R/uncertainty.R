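#' Create an uncertainty budget
#'
#' @param components data.frame with columns `component` and `percent`, or a
#'   named numeric vector of percentages.
#' @return an [UncertaintyBudget-class].
#' @examples
#' b <- uncertaintyBudget(c(capacitance = 0.1, reproducibility = 0.1,
#'                          calibration = 0.88))
#' combineQuadrature(b)
#' @export
uncertaintyBudget <- function(components) {
  if (is.numeric(components)) {
    components <- data.frame(
      component = if (is.null(names(components)))
        paste0("component", seq_along(components)) else names(components),
      percent = as.numeric(components))
  }
  new("UncertaintyBudget", components = as.data.frame(components))
}

#' Read an uncertainty budget from a two-column CSV
#'
#' Expected columns: `component`, `percent`.
#'
#' @param path CSV file path.
#' @return an [UncertaintyBudget-class].
#' @export
readBudget <- function(path) {
  if (!file.exists(path)) stop("budget file not found: ", path)
  uncertaintyBudget(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Combine an uncertainty budget in quadrature
#'
#' Components are assumed uncorrelated; the combined percentage uncertainty
#' is `sqrt(sum(percent^2))`.
#'
#' @param budget an [UncertaintyBudget-class] (or anything accepted by
#'   [uncertaintyBudget()]).
#' @param signif_digits significant digits for the returned value, matching
#'   how such tables are conventionally reported (default 3); use `NULL`
#'   for no rounding.
#' @return combined uncertainty in percent.
#' @export
combineQuadrature <- function(budget, signif_digits = 3) {
  if (!is(budget, "UncertaintyBudget")) budget <- uncertaintyBudget(budget)
  out <- sqrt(sum(budget@components$percent^2))
  if (!is.null(signif_digits)) out <- signif(out, signif_digits)
  out
}

#' @rdname UncertaintyBudget-class
#' @aliases combinedPercent,UncertaintyBudget-method
setMethod("combinedPercent", "UncertaintyBudget",
          function(object) combineQuadrature(object, signif_digits = NULL))

setMethod("show", "UncertaintyBudget", function(object) {
  cat(sprintf("UncertaintyBudget: %d components, combined %.4g%%\n",
              nrow(object@components), combinedPercent(object)))
})

#' Inverse-variance weighted mean of values with uncertainties
#'
#' Computes `sum(x_i / s_i^2) / sum(1 / s_i^2)` with standard uncertainty
#' `1 / sqrt(sum(1 / s_i^2))`. If any input has zero uncertainty the weights
#' degenerate: the zero-sigma value is returned exactly (an error is raised
#' if several zero-sigma inputs disagree).
#'
#' @param values list of [ValueWithUncertainty-class] objects, or a numeric
#'   vector paired with `sigmas`.
#' @param sigmas optional numeric vector of standard uncertainties.
#' @return a [ValueWithUncertainty-class].
#' @examples
#' weightedMeanVU(c(0.972, 1.111, 0.915, 1.020),
#'                c(0.021, 0.026, 0.020, 0.023))
#' @export
weightedMeanVU <- function(values, sigmas = NULL) {
  if (is.list(values)) {
    sigmas <- vapply(values, uSigma, numeric(1))
    values <- vapply(values, uValue, numeric(1))
  }
  if (is.null(sigmas) || length(sigmas) != length(values))
    stop("sigmas must accompany values, one per value")
  if (length(values) == 0L) stop("need at least one value")
  zero <- sigmas == 0
  if (any(zero)) {
    vz <- unique(values[zero])
    if (length(vz) > 1L)
      stop("degenerate weights: multiple zero-sigma values disagree")
    return(vu(vz, 0))
  }
  w <- 1 / sigmas^2
  vu(sum(w * values) / sum(w), 1 / sqrt(sum(w)))
}

#' Ratio of two values with uncertainties
#'
#' Relative standard uncertainties are added in quadrature, the propagation
#' rule for an uncorrelated quotient.
#'
#' @param num,den [ValueWithUncertainty-class] numerator and denominator.
#' @return a [ValueWithUncertainty-class].
#' @export
vuRatio <- function(num, den) {
  if (den@value == 0) stop("denominator value is zero")
  if (num@value == 0) return(vu(0, num@sigma / abs(den@value)))
  r <- num@value / den@value
  rel <- sqrt((num@sigma / num@value)^2 + (den@sigma / den@value)^2)
  vu(r, abs(r) * rel)
}
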
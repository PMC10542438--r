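# Building, background-correcting, normalising and comparing energy
# spectra. Comparisons operate on count-rate densities (counts/s/keV) so
# differing live times never bias the residuals; the raw counts are kept
# for the Poisson uncertainty of each bin.

checkSameGrid <- function(a, b) {
  ea <- binEdges(a); eb <- binEdges(b)
  if (length(ea) != length(eb) || max(abs(ea - eb)) > 1e-9)
    stop("alignment error: spectra are on different bin grids")
}

#' Bin a detected-event list into an energy spectrum
#'
#' Half-open bin convention: an event exactly at a bin edge lands in the
#' upper bin. The spectrum conserves the event total exactly; events
#' outside the requested range are an error rather than silently dropped.
#'
#' @param events a [DetectedEvents-class].
#' @param binWidthKeV bin width in keV (default 2).
#' @param rangeKeV `c(lo, hi)` grid range; default covers all events
#'   starting at 0.
#' @param liveTimeS live time; defaults to the acquisition duration.
#' @return an [EnergySpectrum-class].
#' @export
buildSpectrum <- function(events, binWidthKeV = 2, rangeKeV = NULL,
                          liveTimeS = NULL) {
  stopIfNot(binWidthKeV > 0, "bin width must be > 0")
  e <- events@events$energy_keV
  if (is.null(rangeKeV)) {
    hi <- if (length(e)) ceiling(max(e) / binWidthKeV) * binWidthKeV else
      binWidthKeV
    rangeKeV <- c(0, max(hi, binWidthKeV))
  }
  edges <- uniformEdges(rangeKeV[1], rangeKeV[2], binWidthKeV)
  if (length(e) && (any(e < rangeKeV[1]) || any(e >= rangeKeV[2])))
    stop("events outside the requested energy range; widen rangeKeV")
  idx <- findInterval(e, edges, rightmost.closed = FALSE, left.open = FALSE)
  counts <- tabulate(idx, nbins = length(edges) - 1L)
  if (is.null(liveTimeS)) liveTimeS <- events@durationS
  energySpectrum(edges, counts, liveTimeS)
}

#' Add a time-corrected background to a spectrum
#'
#' Each background bin is rescaled to the target live time and resampled:
#' the added counts are `Poisson(bg_counts * t_target / t_bg)` per bin, so
#' the addition carries the counting noise a background acquired over the
#' target's duration would have.
#'
#' @param target,background [EnergySpectrum-class] on the same grid.
#' @param seed integer seed.
#' @return an [EnergySpectrum-class] with the background realisation added.
#' @export
addTimeCorrectedBackground <- function(target, background, seed = 1) {
  checkSameGrid(target, background)
  lambda <- specCounts(background) * target@liveTimeS / background@liveTimeS
  add <- withSeed(subSeed(seed, "bg:add"),
                  stats::rpois(length(lambda), lambda))
  energySpectrum(binEdges(target), specCounts(target) + add,
                 target@liveTimeS)
}

#' Normalise a spectrum to the total counts of a reference
#'
#' Rescales every bin by one global factor so the totals agree; the shape
#' is untouched. Used when the two spectra being compared are known to
#' have inconsistent absolute normalisations.
#'
#' @param spectrum spectrum to rescale.
#' @param reference spectrum supplying the target total.
#' @return rescaled [EnergySpectrum-class].
#' @export
normaliseTotal <- function(spectrum, reference) {
  tot <- sum(specCounts(spectrum))
  stopIfNot(tot > 0, "cannot normalise a zero-total spectrum")
  energySpectrum(binEdges(spectrum),
                 specCounts(spectrum) * sum(specCounts(reference)) / tot,
                 spectrum@liveTimeS)
}

#' Per-bin percentage residuals between simulated and experimental spectra
#'
#' Residual per bin is `100 * (sim - exp) / exp` computed on count-rate
#' densities. The statistical uncertainty propagates the Poisson noise of
#' both raw bin counts in quadrature. Bins with zero experimental counts
#' are excluded (returned as NA) and counted in `nExcluded`.
#'
#' @param sim,exp [EnergySpectrum-class] on the same grid.
#' @return a [ResidualSeries-class].
#' @export
percentageResiduals <- function(sim, exp) {
  checkSameGrid(sim, exp)
  Ns <- specCounts(sim)
  Ne <- specCounts(exp)
  if (all(Ne == 0)) stop("experimental spectrum is all zero")
  sRate <- Ns / sim@liveTimeS
  eRate <- Ne / exp@liveTimeS
  ok <- Ne > 0
  resid <- sig <- rep(NA_real_, length(Ns))
  resid[ok] <- 100 * (sRate[ok] - eRate[ok]) / eRate[ok]
  # Poisson: var(N) = N; use max(N, 1) for empty simulated bins so the
  # residual there still carries a finite uncertainty
  sig[ok] <- 100 * (1 / eRate[ok]) *
    sqrt(pmax(Ns[ok], 1) / sim@liveTimeS^2 +
         (sRate[ok] / eRate[ok])^2 * Ne[ok] / exp@liveTimeS^2)
  new("ResidualSeries",
      binCentresKeV = binCentres(sim), residualPercent = resid,
      sigmaPercent = ifelse(is.na(sig), 0, sig),
      nExcluded = sum(!ok))
}

setMethod("show", "ResidualSeries", function(object) {
  ok <- !is.na(object@residualPercent)
  cat(sprintf(
    "ResidualSeries: %d usable bins (%d excluded), range [%.3g, %.3g]%%\n",
    sum(ok), object@nExcluded,
    if (any(ok)) min(object@residualPercent[ok]) else NA,
    if (any(ok)) max(object@residualPercent[ok]) else NA))
})

#' Window-weighted mean of percentage residuals
#'
#' Inverse-variance weighted mean of the usable residual bins whose
#' centres fall inside the window, with uncertainty
#' `1 / sqrt(sum(1 / sigma_i^2))`.
#'
#' @param residuals a [ResidualSeries-class].
#' @param window an [EnergyWindow-class].
#' @param weights optional explicit weights overriding inverse-variance.
#' @return a [ValueWithUncertainty-class], percent.
#' @export
windowWeightedMean <- function(residuals, window, weights = NULL) {
  sel <- inWindow(residuals@binCentresKeV, window) &
    !is.na(residuals@residualPercent)
  if (!any(sel)) stop("no usable residual bins inside window ",
                      window@label)
  x <- residuals@residualPercent[sel]
  s <- residuals@sigmaPercent[sel]
  if (!is.null(weights)) {
    w <- weights[sel]
    return(vu(sum(w * x) / sum(w), sqrt(sum(w^2 * s^2)) / sum(w)))
  }
  weightedMeanVU(x, s)
}
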
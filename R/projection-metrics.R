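# Image-domain validation metrics: event binning into projection stacks,
# sensitivity (counts per second per MBq) with full uncertainty
# propagation, per-projection sinogram ratios against a 3-sigma band, peak
# signal-to-noise ratio with a shifted-self baseline, and Gaussian profile
# FWHM with uncertainties on both axes.

#' Bin detected events into a projection stack
#'
#' Maps each in-window event to its pixel (origin at the detector face
#' centre, pixel (0,0) top-left, half-open pixel bins) and counts it in
#' its projection. Out-of-field events are counted and reported via
#' `attr(, "nOutOfField")`; window gating is half-open \[lo, hi).
#'
#' @param events a [DetectedEvents-class].
#' @param template a [ProjectionStack-class] supplying the geometry.
#' @param window optional [EnergyWindow-class]; `NULL` keeps all energies.
#' @return a [ProjectionStack-class] with `attr(, "nOutOfField")`.
#' @export
binEventsToStack <- function(events, template, window = NULL) {
  d <- dim(template@pixels)
  nproj <- d[1]; nr <- d[2]; nc <- d[3]
  ev <- events@events
  if (!is.null(window)) ev <- ev[inWindow(ev$energy_keV, window), ]
  ps <- template@pixelSizeMm
  col <- floor(ev$x_mm / ps + nc / 2)
  row <- floor(ev$y_mm / ps + nr / 2)
  inField <- col >= 0 & col < nc & row >= 0 & row < nr
  nOut <- sum(!inField)
  idx <- 1L + ev$projection_index[inField] +
    as.integer(row[inField]) * nproj +
    as.integer(col[inField]) * nproj * nr
  counts <- tabulate(idx, nbins = nproj * nr * nc)
  if (any(counts > 65535L)) {
    warning("pixel counts exceed 65535; clamped to the 16-bit maximum")
    counts <- pmin(counts, 65535L)
  }
  out <- projectionStack(array(counts, dim = c(nproj, nr, nc)),
                         pixelSizeMm = ps,
                         timePerProjectionS = template@timePerProjectionS,
                         nHeads = template@nHeads,
                         projectionsPerHead = template@projectionsPerHead)
  attr(out, "nOutOfField") <- nOut
  out
}

#' Per-projection total counts of a stack
#'
#' @param stack a [ProjectionStack-class].
#' @return numeric vector of length nProjections.
#' @export
projectionTotals <- function(stack) {
  apply(stack@pixels, 1, function(m) sum(as.numeric(m)))
}

#' Sensitivity of an acquisition
#'
#' `S = c / (A * T)` in counts/(s x MBq), with
#' `(sS/S)^2 = (sc/c)^2 + (sA/A)^2 + effBandRel^2` where `sc = sqrt(c)`
#' (Poisson) and `effBandRel` is the window-averaged relative uncertainty
#' of the applied efficiency correction -- zero for experimental images,
#' where no correction was applied.
#'
#' @param counts total image counts `c`.
#' @param activity [ValueWithUncertainty-class], MBq.
#' @param timeS total acquisition time in seconds.
#' @param effBandRel relative efficiency-correction uncertainty averaged
#'   over the energy window (0 for experimental data).
#' @param window window label.
#' @param source `"simulation"` or `"experiment"`.
#' @return a [SensitivityResult-class].
#' @export
sensitivity <- function(counts, activity, timeS, effBandRel = 0,
                        window = "", source = "simulation") {
  stopIfNot(counts >= 0, "counts must be >= 0")
  stopIfNot(activity@value > 0, "activity must be > 0")
  stopIfNot(timeS > 0, "time must be > 0")
  S <- counts / (activity@value * timeS)
  rel2 <- (if (counts > 0) 1 / counts else 0) +
    (activity@sigma / activity@value)^2 + effBandRel^2
  new("SensitivityResult", S = vu(S, S * sqrt(rel2)),
      window = as.character(window), source = source)
}

setMethod("show", "SensitivityResult", function(object) {
  cat(sprintf("SensitivityResult [%s, %s]: %s counts/(s x MBq)\n",
              object@window, object@source, formatVU(object@S)))
})

#' Simulation / experiment sensitivity ratio
#'
#' Relative uncertainties added in quadrature.
#'
#' @param sim,exp [SensitivityResult-class] (or bare
#'   [ValueWithUncertainty-class]) for the same window.
#' @return a [ValueWithUncertainty-class].
#' @examples
#' sensitivityRatio(vu(36.33, 0.73), vu(37.39, 0.33))  # 0.972 +- 0.021
#' @export
sensitivityRatio <- function(sim, exp) {
  simS <- if (is(sim, "SensitivityResult")) sim@S else sim
  expS <- if (is(exp, "SensitivityResult")) exp@S else exp
  stopIfNot(expS@value > 0, "experimental sensitivity must be > 0")
  vuRatio(simS, expS)
}

#' Compare simulated and experimental sinograms
#'
#' Per-projection count totals are ratioed (simulation divided by the
#' sensitivity-ratio value first, so sensitivity discrepancies are
#' validated separately), each with its Poisson standard uncertainty;
#' projections whose |ratio - 1| exceeds three times the sensitivity-ratio
#' sigma are flagged; the weighted mean ratio uses inverse-variance
#' weights. Projections with zero experimental counts are excluded.
#'
#' @param simStack,expStack [ProjectionStack-class] of identical shape (or
#'   numeric per-projection totals).
#' @param ratio [ValueWithUncertainty-class] sensitivity ratio used to
#'   normalise the simulation.
#' @param normalise divide the simulated totals by `uValue(ratio)` (default
#'   TRUE; set FALSE if already normalised).
#' @return a [SinogramComparison-class].
#' @export
sinogramCompare <- function(simStack, expStack, ratio = vu(1, 0),
                            normalise = TRUE) {
  s <- if (is(simStack, "ProjectionStack")) projectionTotals(simStack) else
    as.numeric(simStack)
  e <- if (is(expStack, "ProjectionStack")) projectionTotals(expStack) else
    as.numeric(expStack)
  stopIfNot(length(s) == length(e), "stacks must have the same shape")
  sN <- if (normalise) s / ratio@value else s
  ok <- e > 0
  r <- sig <- rep(NA_real_, length(e))
  r[ok] <- sN[ok] / e[ok]
  # Poisson sigma from the raw counts of both stacks (floor of one count
  # on the simulated side so empty projections keep a finite uncertainty)
  scale <- if (normalise) ratio@value else 1
  sig[ok] <- sqrt(pmax(s[ok], 1) / (scale * e[ok])^2 + r[ok]^2 / e[ok])
  # inverse-variance weights use the variance predicted under agreement
  # (simulated counts at their expectation scale * e); weights built from
  # the observed per-projection sigmas would correlate with the ratio
  # noise and bias the mean low at small counts
  w <- e[ok] * scale / (1 + scale)
  m <- sum(w * r[ok]) / sum(w)
  sig0 <- (1 / scale + 1) / e[ok]
  wm <- vu(m, 1 / sqrt(sum(1 / sig0)))
  flagged <- !is.na(r) & abs(r - 1) > 3 * ratio@sigma
  new("SinogramComparison", ratio = r, sigma = ifelse(is.na(sig), 0, sig),
      flagged = flagged, weightedMean = wm, bandSigma = ratio@sigma,
      nExcluded = sum(!ok))
}

setMethod("show", "SinogramComparison", function(object) {
  cat(sprintf(
    paste0("SinogramComparison: weighted mean ratio %s, %d/%d projections ",
           "flagged beyond 3 sigma (%d excluded)\n"),
    formatVU(object@weightedMean), sum(object@flagged, na.rm = TRUE),
    length(object@ratio), object@nExcluded))
})

#' Peak signal-to-noise ratio between two images
#'
#' `PSNR = 20 log10(maxF / sqrt(MSE))` with `MSE` the mean squared pixel
#' difference. Identical images give `Inf` (the documented sentinel for
#' zero MSE). The default `maxF` of 32768 is the conventional ceiling for
#' unsigned 16-bit nuclear-medicine projections.
#'
#' @param f,g numeric matrices/arrays of identical shape.
#' @param maxF maximum possible pixel value (default 32768).
#' @return PSNR in dB.
#' @export
psnr <- function(f, g, maxF = 32768) {
  stopIfNot(identical(dim(f), dim(g)), "images must have the same shape")
  mse <- mean((as.numeric(f) - as.numeric(g))^2)
  if (mse == 0) return(Inf)
  20 * log10(maxF / sqrt(mse))
}

# Pooled squared differences of one slice against itself shifted by one
# pixel along each in-plane axis (edge-cropped overlap, no wrap-around).
shiftedSelfMSE <- function(img, shift) {
  nr <- nrow(img); nc <- ncol(img)
  dx <- abs(shift[1]); dy <- abs(shift[2])
  stopIfNot(dx < nc && dy < nr, "shift exceeds image bounds")
  if (dx == 0 && dy == 0) return(0)
  d2 <- c()
  if (dx > 0)
    d2 <- c(d2, as.numeric(img[, seq_len(nc - dx)] -
                             img[, seq_len(nc - dx) + dx])^2)
  if (dy > 0)
    d2 <- c(d2, as.numeric(img[seq_len(nr - dy), ] -
                             img[seq_len(nr - dy) + dy, ])^2)
  mean(d2)
}

# Weighted mean +- weighted standard deviation over slices, excluding
# infinite entries.
aggregatePsnr <- function(values, weights) {
  fin <- is.finite(values)
  nInf <- sum(!fin)
  v <- values[fin]; w <- weights[fin]
  if (!length(v)) {
    out <- vu(Inf, 0)
  } else {
    if (all(w == 0)) w <- rep(1, length(v))
    m <- sum(w * v) / sum(w)
    out <- vu(m, sqrt(sum(w * (v - m)^2) / sum(w)))
  }
  attr(out, "nInfinite") <- nInf
  out
}

#' Shifted-self PSNR baseline of an experimental stack
#'
#' Because PSNR is not an absolute quantity, each slice is compared to
#' itself translated by one pixel along each in-plane axis (squared
#' differences of the two single-axis shifts pooled, overlap region only,
#' no wrap-around) to give the level of self-similarity the simulated
#' images should reach. Slices are aggregated as a weighted mean +- the
#' weighted standard deviation, each slice weighted by its total counts;
#' infinite (zero-MSE) slices are excluded and counted in
#' `attr(, "nInfinite")`.
#'
#' @param expStack a [ProjectionStack-class] (or a matrix for one slice).
#' @param shift length-2 pixel shift per axis (default `c(1, 1)`).
#' @param maxF maximum possible pixel value.
#' @return a [ValueWithUncertainty-class] (dB); per-slice values in
#'   `attr(, "perSlice")`.
#' @export
psnrReference <- function(expStack, shift = c(1, 1), maxF = 32768) {
  slices <- if (is.matrix(expStack)) list(expStack) else
    lapply(seq_len(dim(expStack@pixels)[1]),
           function(p) expStack@pixels[p, , ])
  perSlice <- vapply(slices, function(m) {
    mse <- shiftedSelfMSE(m, shift)
    if (mse == 0) Inf else 20 * log10(maxF / sqrt(mse))
  }, numeric(1))
  weights <- vapply(slices, function(m) sum(as.numeric(m)), numeric(1))
  out <- aggregatePsnr(perSlice, weights)
  attr(out, "perSlice") <- perSlice
  out
}

#' Slice-wise PSNR between two stacks, aggregated
#'
#' PSNR computed independently for each projection slice and aggregated as
#' a weighted mean +- weighted standard deviation, each slice weighted by
#' its experimental total counts.
#'
#' @param simStack,expStack [ProjectionStack-class] of identical shape.
#' @param maxF maximum possible pixel value.
#' @return a [ValueWithUncertainty-class] (dB); per-slice values in
#'   `attr(, "perSlice")`.
#' @export
stackPsnr <- function(simStack, expStack, maxF = 32768) {
  ds <- dim(simStack@pixels); de <- dim(expStack@pixels)
  stopIfNot(identical(ds, de), "stacks must have the same shape")
  perSlice <- vapply(seq_len(ds[1]), function(p)
    psnr(simStack@pixels[p, , ], expStack@pixels[p, , ], maxF), numeric(1))
  weights <- vapply(seq_len(ds[1]), function(p)
    sum(as.numeric(expStack@pixels[p, , ])), numeric(1))
  out <- aggregatePsnr(perSlice, weights)
  attr(out, "perSlice") <- perSlice
  out
}

#' FWHM of a point-source image from a Gaussian profile fit
#'
#' Extracts a 1-pixel-wide profile through the maximum-count pixel along
#' the requested axis and fits a Gaussian with uncertainties on both axes:
#' ordinate sigma `sqrt(counts)` (Poisson) and abscissa sigma of half a
#' pixel, combined by the iterated effective-variance scheme
#' (`sigma_eff^2 = sigma_y^2 + f'(x)^2 sigma_x^2`), the standard
#' orthogonal-distance treatment for nonlinear fits. FWHM is
#' `2 sqrt(2 ln 2) * sigma_fit` in mm with its fit-derived uncertainty.
#'
#' @param image numeric matrix (rows = y, cols = x).
#' @param axis `"x"` (profile along a row) or `"y"`.
#' @param pixelSizeMm pixel size in mm.
#' @return a [ValueWithUncertainty-class], FWHM in mm.
#' @export
profileFwhm <- function(image, axis = c("x", "y"), pixelSizeMm = 4.2578) {
  axis <- match.arg(axis)
  stopIfNot(is.matrix(image), "image must be a matrix")
  if (all(image == 0)) stop("fit error: image is all zero")
  peak <- which(image == max(image), arr.ind = TRUE)[1, ]
  prof <- if (axis == "x") image[peak[1], ] else image[, peak[2]]
  n <- length(prof)
  if (which.max(prof) %in% c(1L, n))
    stop("fit error: profile peak lies on the image border")
  pos <- (seq_len(n) - 0.5 - n / 2) * pixelSizeMm
  sigY <- sqrt(pmax(prof, 1))
  sigX <- pixelSizeMm / 2
  start <- list(A = max(prof), mu = pos[which.max(prof)],
                s = pixelSizeMm * 2, b0 = min(prof))
  fit <- NULL
  w <- 1 / sigY^2
  for (iter in 1:4) {
    refit <- tryCatch(
      minpack.lm::nlsLM(
        prof ~ A * exp(-(pos - mu)^2 / (2 * s^2)) + b0,
        start = start, weights = w,
        lower = c(A = 0, mu = min(pos), s = pixelSizeMm / 10, b0 = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(refit, "error")) {
      # a refit restarted at an already-converged optimum can degenerate;
      # keep the previous iteration in that case
      if (is.null(fit))
        stop("fit error: profile fit did not converge (",
             conditionMessage(refit), ")")
      break
    }
    fit <- refit
    cf <- stats::coef(fit)
    start <- as.list(cf)
    dfdx <- cf[["A"]] * abs(pos - cf[["mu"]]) / cf[["s"]]^2 *
      exp(-(pos - cf[["mu"]])^2 / (2 * cf[["s"]]^2))
    w <- 1 / (sigY^2 + (dfdx * sigX)^2)
  }
  cf <- stats::coef(fit)
  # the weights are absolute uncertainties (Poisson counts, half-pixel
  # abscissa), so the parameter covariance is taken unscaled rather than
  # rescaled by the residual variance
  sm <- summary(fit)
  seS <- sqrt(sm$cov.unscaled["s", "s"])
  k <- 2 * sqrt(2 * log(2))
  vu(k * abs(cf[["s"]]), k * seS)
}
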
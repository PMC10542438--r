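# Derivation and application of the energy-dependent intrinsic-efficiency
# correction. The absolute efficiency at each calibration line is
# epsilon = N / (A * I_gamma) with its uncertainty propagated in quadrature
# from the net count rate, activity and emission intensity. Ratios of
# experimental to simulated efficiency are fitted with a log-quadratic
# a + b ln(E) + c ln^2(E) above the lowest calibration energy and a linear
# piece below it anchored to zero at 2 keV; the fit uncertainty is the
# spread of a perturbation-refit ensemble; the correction is applied to
# event lists by event-by-event Poisson sampling.

#' Fit a photopeak with a Gaussian plus linear local background
#'
#' Least-squares fit of `A * exp(-(x - mu)^2 / (2 s^2)) + b0 + b1 x` to the
#' spectrum bins inside the fit window. The net count rate is the Gaussian
#' area divided by the live time; its uncertainty comes from the fit
#' covariance of (A, s) by the delta method.
#'
#' @param spectrum an [EnergySpectrum-class].
#' @param window an [EnergyWindow-class] or numeric `c(lo, hi)` keV interval
#'   containing at least 8 bins.
#' @return list with `netRate` ([ValueWithUncertainty-class], counts/s),
#'   `centreKeV`, `sigmaKeV`, and the `nls` fit object.
#' @export
fitPhotopeak <- function(spectrum, window) {
  if (is(window, "EnergyWindow")) window <- windowBounds(window)
  x <- binCentres(spectrum)
  sel <- x >= window[[1]] & x < window[[2]]
  if (sum(sel) < 8L) stop("fit window must contain at least 8 bins")
  x <- x[sel]
  y <- specCounts(spectrum)[sel]
  if (all(y == 0)) stop("fit error: all counts in the window are zero")
  if (stats::sd(y) == 0) stop("fit error: flat spectrum in the window")
  x0 <- mean(x)
  start <- list(A = max(y) - stats::median(y),
                mu = x[which.max(y)],
                s = (window[[2]] - window[[1]]) / 8,
                b0 = stats::median(y), b1 = 0)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * exp(-(x - mu)^2 / (2 * s^2)) + b0 + b1 * (x - x0),
      start = start,
      lower = c(A = 0, mu = window[[1]], s = 1e-3, b0 = -Inf, b1 = -Inf),
      upper = c(A = Inf, mu = window[[2]], s = Inf, b0 = Inf, b1 = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("fit error: photopeak fit did not converge (",
                             conditionMessage(e), ")"))
  cf <- stats::coef(fit)
  w <- binWidth(spectrum)
  area <- cf[["A"]] * abs(cf[["s"]]) * sqrt(2 * pi) / w
  V <- stats::vcov(fit)[c("A", "s"), c("A", "s")]
  grad <- c(abs(cf[["s"]]), cf[["A"]]) * sqrt(2 * pi) / w
  sigmaArea <- sqrt(max(0, drop(t(grad) %*% V %*% grad)))
  list(netRate = vu(area / spectrum@liveTimeS,
                    sigmaArea / spectrum@liveTimeS),
       centreKeV = cf[["mu"]], sigmaKeV = abs(cf[["s"]]), fit = fit)
}

#' Absolute detection efficiency from a net count rate
#'
#' `epsilon = N / (A * I_gamma)` with the standard quadrature propagation
#' for uncorrelated variables:
#' `sigma_eps = eps * sqrt((sN/N)^2 + (sA/A)^2 + (sI/I)^2)`.
#' Units must be consistent (N in counts/s, A in decays/s, I as a
#' fraction gives a dimensionless efficiency).
#'
#' @param netRate,activity,intensity [ValueWithUncertainty-class] inputs.
#' @param energyKeV the gamma-line energy the point belongs to.
#' @param label source label.
#' @return an [EfficiencyPoint-class].
#' @export
absoluteEfficiency <- function(netRate, activity, intensity, energyKeV,
                               label = "") {
  stopIfNot(activity@value > 0, "activity must be > 0")
  stopIfNot(intensity@value > 0, "intensity must be > 0")
  eps <- netRate@value / (activity@value * intensity@value)
  rel2 <- (if (netRate@value != 0) (netRate@sigma / netRate@value)^2 else 0) +
    (activity@sigma / activity@value)^2 +
    (intensity@sigma / intensity@value)^2
  sig <- if (netRate@value != 0) abs(eps) * sqrt(rel2) else
    netRate@sigma / (activity@value * intensity@value)
  new("EfficiencyPoint", energyKeV = as.numeric(energyKeV),
      epsilon = vu(eps, sig), label = as.character(label))
}

#' Absolute efficiency of one calibration line
#'
#' Convenience wrapper: fits the photopeak of a [CalibrationPoint-class] in
#' a window of `+- nSigma` expected blur widths around the line and applies
#' the efficiency definition with activity converted to decays/s and
#' intensity to a fraction.
#'
#' @param point a [CalibrationPoint-class].
#' @param model the [DigitiserModel-class] describing the expected blur
#'   (sets the fit window width).
#' @param nSigma half-width of the fit window in blur sigmas (default 4).
#' @return an [EfficiencyPoint-class].
#' @export
calibrationEfficiency <- function(point, model, nSigma = 4) {
  sig <- energyBlurSigma(model, point@energyKeV)
  half <- max(nSigma * sig, 4.5 * binWidth(point@spectrum))
  pk <- fitPhotopeak(point@spectrum,
                     c(point@energyKeV - half, point@energyKeV + half))
  absoluteEfficiency(pk$netRate,
                     vu(point@activityKBq@value * 1e3,
                        point@activityKBq@sigma * 1e3),
                     vu(point@intensityPercent@value / 100,
                        point@intensityPercent@sigma / 100),
                     point@energyKeV, point@isotope)
}

# Coerce a list of EfficiencyPoint (or a data.frame) to the internal
# data.frame form: energy_keV, value, sigma, label.
asEfficiencyFrame <- function(points) {
  if (is.data.frame(points)) {
    stopIfNot(all(c("energy_keV", "value", "sigma") %in% names(points)),
              "need columns energy_keV, value, sigma")
    if (is.null(points$label)) points$label <- ""
    return(points[, c("energy_keV", "value", "sigma", "label")])
  }
  data.frame(
    energy_keV = vapply(points, function(p) p@energyKeV, numeric(1)),
    value = vapply(points, function(p) p@epsilon@value, numeric(1)),
    sigma = vapply(points, function(p) p@epsilon@sigma, numeric(1)),
    label = vapply(points, function(p) p@label, character(1)))
}

#' Experimental / simulated efficiency ratios
#'
#' Pairs experimental and simulated efficiency points on energy (and label)
#' and forms their ratio with relative uncertainties added in quadrature.
#'
#' @param expPoints,simPoints lists of [EfficiencyPoint-class] (or
#'   data.frames with columns energy_keV, value, sigma) measured at the
#'   same energies.
#' @return data.frame with columns `energy_keV`, `ratio`, `sigma`, `label`.
#' @export
correctionRatios <- function(expPoints, simPoints) {
  ex <- asEfficiencyFrame(expPoints)
  si <- asEfficiencyFrame(simPoints)
  idx <- vapply(seq_len(nrow(ex)), function(i) {
    j <- which(abs(si$energy_keV - ex$energy_keV[i]) < 1e-6)
    if (length(j) != 1L)
      stop("pairing error: no unique simulated point at ",
           ex$energy_keV[i], " keV")
    j
  }, integer(1))
  si <- si[idx, ]
  r <- vapply(seq_len(nrow(ex)), function(i)
    uValue(vuRatio(vu(ex$value[i], ex$sigma[i]),
                   vu(si$value[i], si$sigma[i]))), numeric(1))
  s <- vapply(seq_len(nrow(ex)), function(i)
    uSigma(vuRatio(vu(ex$value[i], ex$sigma[i]),
                   vu(si$value[i], si$sigma[i]))), numeric(1))
  data.frame(energy_keV = ex$energy_keV, ratio = r, sigma = s,
             label = ex$label)
}

logQuadratic <- function(a, b, c, energyKeV) {
  le <- log(energyKeV)
  a + b * le + c * le^2
}

# Build an EfficiencyCorrection from log-quadratic coefficients, deriving
# the linear piece through (anchor, 0) and (breakpoint, logquad(breakpoint)).
correctionFromCoefficients <- function(a, b, c, breakpointKeV, anchorKeV,
                                       ensemble = matrix(numeric(0), 0, 3)) {
  vb <- logQuadratic(a, b, c, breakpointKeV)
  slope <- vb / (breakpointKeV - anchorKeV)
  new("EfficiencyCorrection", a = a, b = b, c = c,
      breakpointKeV = breakpointKeV, slope = slope,
      intercept = -anchorKeV * slope, anchorKeV = anchorKeV,
      ensemble = ensemble)
}

#' Construct an efficiency correction from explicit coefficients
#'
#' Builds the piecewise correction from known coefficients, e.g. ones
#' published for a particular camera. If `slope`/`intercept` are omitted
#' the linear piece is derived by joining (anchorKeV, 0) to the value of
#' the log-quadratic at the breakpoint; if given, they are used verbatim
#' (the two pieces are then allowed to be discontinuous at the breakpoint,
#' as printed rounded coefficients typically are).
#'
#' @param a,b,c log-quadratic coefficients of `a + b ln(E) + c ln^2(E)`.
#' @param breakpointKeV switch-over energy (default 46).
#' @param anchorKeV energy where the linear piece vanishes (default 2).
#' @param slope,intercept optional explicit linear-piece coefficients.
#' @return an [EfficiencyCorrection-class].
#' @examples
#' corr <- efficiencyCorrection(-3.755, 1.702, -0.168,
#'                              slope = 0.0067, intercept = -0.0134)
#' evaluateCorrection(corr, c(2, 46, 140))
#' @export
efficiencyCorrection <- function(a, b, c, breakpointKeV = 46, anchorKeV = 2,
                                 slope = NULL, intercept = NULL) {
  if (is.null(slope) != is.null(intercept))
    stop("give both slope and intercept, or neither")
  if (is.null(slope))
    return(correctionFromCoefficients(a, b, c, breakpointKeV, anchorKeV))
  new("EfficiencyCorrection", a = a, b = b, c = c,
      breakpointKeV = breakpointKeV, slope = slope, intercept = intercept,
      anchorKeV = anchorKeV)
}

#' Fit the efficiency-correction function to ratio points
#'
#' Weighted least squares of `a + b ln(E) + c ln^2(E)` against the
#' efficiency ratios (weights `1/sigma^2`), with a linear low-energy piece
#' through (anchorKeV, 0) and the log-quadratic value at the breakpoint.
#'
#' @param ratioPoints data.frame from [correctionRatios()] (columns
#'   `energy_keV`, `ratio`, `sigma`).
#' @param breakpointKeV switch-over energy; default the lowest point energy.
#' @param anchorKeV energy where the correction is fixed to zero (default 2).
#' @param weighted use `1/sigma^2` weights (default TRUE; automatically
#'   disabled when any sigma is zero).
#' @return an [EfficiencyCorrection-class].
#' @export
fitCorrection <- function(ratioPoints, breakpointKeV = NULL, anchorKeV = 2,
                          weighted = TRUE) {
  pts <- ratioPoints[ratioPoints$energy_keV > 0, ]
  if (is.null(breakpointKeV)) breakpointKeV <- min(pts$energy_keV)
  use <- pts[pts$energy_keV >= breakpointKeV, ]
  if (length(unique(use$energy_keV)) < 4L)
    stop("underdetermined: need >= 4 points at distinct energies at or ",
         "above the breakpoint")
  le <- log(use$energy_keV)
  w <- if (weighted && all(use$sigma > 0)) 1 / use$sigma^2 else
    rep(1, nrow(use))
  fit <- stats::lm(use$ratio ~ le + I(le^2), weights = w)
  cf <- unname(stats::coef(fit))
  correctionFromCoefficients(cf[1], cf[2], cf[3], breakpointKeV, anchorKeV)
}

#' Evaluate the piecewise efficiency correction
#'
#' Linear piece below the breakpoint, log-quadratic at and above it, both
#' clipped below at zero.
#'
#' @param corr an [EfficiencyCorrection-class].
#' @param energyKeV positive energies (vectorised), keV.
#' @return correction values.
#' @export
evaluateCorrection <- function(corr, energyKeV) {
  stopIfNot(all(energyKeV > 0), "energyKeV must be > 0")
  lin <- corr@intercept + corr@slope * energyKeV
  quad <- logQuadratic(corr@a, corr@b, corr@c, energyKeV)
  pmax(ifelse(energyKeV < corr@breakpointKeV, lin, quad), 0)
}

#' @describeIn evaluateCorrection `predict` method for fitted corrections.
#' @param object an [EfficiencyCorrection-class].
#' @param newdata numeric energies in keV.
#' @param ... ignored.
#' @export
setMethod("predict", "EfficiencyCorrection",
          function(object, newdata, ...) evaluateCorrection(object, newdata))

setMethod("show", "EfficiencyCorrection", function(object) {
  cat(sprintf(
    paste0("EfficiencyCorrection: %.4g + %.4g ln(E) + %.4g ln^2(E) for ",
           "E >= %g keV;\n  %.4g + %.4g E below (zero at %g keV); ",
           "%d refit samples\n"),
    object@a, object@b, object@c, object@breakpointKeV, object@intercept,
    object@slope, object@anchorKeV, nrow(object@ensemble)))
})

#' Perturbation-refit uncertainty band of the correction fit
#'
#' Each ratio point is perturbed by a normal deviate with its own standard
#' uncertainty and the correction refitted; repeated `nRefits` times
#' (default 1000). The per-energy band sigma is the sample standard
#' deviation of the refitted curve values. Non-convergent refits are
#' counted and excluded; more than 5 percent of failures is an error.
#'
#' @inheritParams fitCorrection
#' @param nRefits number of perturbation refits (default 1000).
#' @param seed integer seed; the band is deterministic under a fixed seed.
#' @return the fitted [EfficiencyCorrection-class] with its `ensemble` slot
#'   filled; query the band with [bandSigma()]. The number of failed refits
#'   is in `attr(, "nFailed")`.
#' @export
fitUncertaintyBand <- function(ratioPoints, nRefits = 1000, seed = 1,
                               breakpointKeV = NULL, anchorKeV = 2,
                               weighted = TRUE) {
  corr <- fitCorrection(ratioPoints, breakpointKeV, anchorKeV, weighted)
  pts <- ratioPoints[ratioPoints$energy_keV >= corr@breakpointKeV, ]
  le <- log(pts$energy_keV)
  X <- cbind(1, le, le^2)
  w <- if (weighted && all(pts$sigma > 0)) 1 / pts$sigma^2 else
    rep(1, nrow(pts))
  ens <- withSeed(subSeed(seed, "band"), {
    out <- matrix(NA_real_, nRefits, 3)
    for (i in seq_len(nRefits)) {
      yi <- pts$ratio + stats::rnorm(nrow(pts), 0, pts$sigma)
      cf <- tryCatch(stats::lm.wfit(X, yi, w)$coefficients,
                     error = function(e) rep(NA_real_, 3))
      out[i, ] <- cf
    }
    out
  })
  ok <- stats::complete.cases(ens)
  nFailed <- sum(!ok)
  if (nFailed > 0.05 * nRefits)
    stop("band error: ", nFailed, " of ", nRefits, " refits failed")
  corr@ensemble <- ens[ok, , drop = FALSE]
  validObject(corr)
  attr(corr, "nFailed") <- nFailed
  corr
}

#' Per-energy sigma of the correction uncertainty band
#'
#' Sample standard deviation, across the perturbation-refit ensemble, of
#' the full piecewise correction evaluated at each query energy (the linear
#' piece is re-derived for every ensemble member).
#'
#' @param corr an [EfficiencyCorrection-class] with a refit ensemble (see
#'   [fitUncertaintyBand()]).
#' @param energyKeV positive query energies, keV.
#' @return per-energy band standard deviations.
#' @export
bandSigma <- function(corr, energyKeV) {
  stopIfNot(nrow(corr@ensemble) > 0,
            "no refit ensemble: run fitUncertaintyBand() first")
  stopIfNot(all(energyKeV > 0), "energyKeV must be > 0")
  vals <- apply(corr@ensemble, 1, function(cf) {
    ci <- correctionFromCoefficients(cf[1], cf[2], cf[3],
                                     corr@breakpointKeV, corr@anchorKeV)
    evaluateCorrection(ci, energyKeV)
  })
  if (is.null(dim(vals))) return(stats::sd(vals))
  apply(vals, 1, stats::sd)
}

#' Apply the efficiency correction to an event list
#'
#' In `"poisson"` mode (the default, and the faithful event-by-event
#' reading of Poisson resampling) each event is replicated
#' `k ~ Poisson(eps_cor(E))` times, which also generalises to corrections
#' above one. In `"thin"` mode each event is kept with probability
#' `min(eps_cor(E), 1)`; corrections above one are clamped with a warning.
#' Expected output count is `sum(eps_cor(E_i))` in both modes when the
#' correction never exceeds one.
#'
#' @param events a [DetectedEvents-class].
#' @param corr an [EfficiencyCorrection-class].
#' @param mode `"poisson"` or `"thin"`.
#' @param seed integer seed; deterministic under a fixed seed.
#' @return a corrected [DetectedEvents-class].
#' @export
applyCorrection <- function(events, corr, mode = c("poisson", "thin"),
                            seed = 1) {
  mode <- match.arg(mode)
  ev <- events@events
  eff <- evaluateCorrection(corr, ev$energy_keV)
  out <- withSeed(subSeed(seed, paste0("apply:", mode)), {
    if (mode == "poisson") {
      k <- stats::rpois(nrow(ev), eff)
      ev[rep.int(seq_len(nrow(ev)), k), , drop = FALSE]
    } else {
      if (any(eff > 1)) {
        warning("correction exceeds 1 for ", sum(eff > 1),
                " event(s) in thin mode; clamped to 1")
        eff <- pmin(eff, 1)
      }
      ev[stats::runif(nrow(ev)) < eff, , drop = FALSE]
    }
  })
  rownames(out) <- NULL
  detectedEvents(out, events@nProjections, events@durationS)
}

#' Serialise an efficiency correction as structured text
#'
#' YAML with the coefficients, breakpoint, anchor, linear piece and (when
#' present) the perturbation-refit ensemble, so a correction can be fitted
#' once and reused.
#'
#' @param corr an [EfficiencyCorrection-class].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
writeCorrection <- function(corr, path) {
  yaml::write_yaml(list(
    a = corr@a, b = corr@b, c = corr@c,
    breakpoint_keV = corr@breakpointKeV, anchor_keV = corr@anchorKeV,
    slope = corr@slope, intercept = corr@intercept,
    ensemble = if (nrow(corr@ensemble)) apply(corr@ensemble, 1, as.list)
               else list()), path, precision = 15)
  invisible(path)
}

#' Read an efficiency correction written by [writeCorrection()]
#'
#' @param path YAML path.
#' @return an [EfficiencyCorrection-class].
#' @export
readCorrection <- function(path) {
  stopIfNot(file.exists(path), paste("correction file not found:", path))
  y <- yaml::read_yaml(path)
  ens <- if (length(y$ensemble))
    do.call(rbind, lapply(y$ensemble, function(r) unlist(r, use.names = FALSE)))
  else matrix(numeric(0), 0, 3)
  new("EfficiencyCorrection", a = y$a, b = y$b, c = y$c,
      breakpointKeV = y$breakpoint_keV, anchorKeV = y$anchor_keV,
      slope = y$slope, intercept = y$intercept, ensemble = ens)
}
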
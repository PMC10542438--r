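# Synthetic-data generators: every input the validation pipeline consumes
# can be produced here with known ground truth -- calibration-ampoule
# spectra, dual-head phantom acquisitions with radioactive decay,
# point-source planar images, and background acquisitions. The generators
# emulate the statistical structure the analysis assumes (Poisson counting,
# Gaussian digitiser blurring, decay, per-head sensitivity), not photon
# transport.

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))  # sigma = FWHM / 2.3548

#' Create a digitiser blurring model
#'
#' @param energyResolutionFwhmAtRef FWHM fraction at the reference energy
#'   (default 0.095).
#' @param referenceEnergyKeV reference energy in keV (default 140).
#' @param spatialFwhmMm intrinsic spatial FWHM in mm (default 3.2).
#' @return a [DigitiserModel-class].
#' @export
digitiserModel <- function(energyResolutionFwhmAtRef = 0.095,
                           referenceEnergyKeV = 140, spatialFwhmMm = 3.2) {
  new("DigitiserModel",
      energyResolutionFwhmAtRef = energyResolutionFwhmAtRef,
      referenceEnergyKeV = referenceEnergyKeV,
      spatialFwhmMm = spatialFwhmMm)
}

#' Energy resolution at an arbitrary energy
#'
#' Extrapolates the reference FWHM fraction with the inverse square-root
#' law `r(E) = r(E_ref) * sqrt(E_ref / E)`, the conventional default for
#' NaI digitiser models.
#'
#' @param model a [DigitiserModel-class].
#' @param energyKeV positive energy (vectorised), keV.
#' @return FWHM fraction(s) at `energyKeV`.
#' @examples
#' energyResolutionAt(digitiserModel(), 140)  # 0.095
#' energyResolutionAt(digitiserModel(), 35)   # 0.19
#' @export
energyResolutionAt <- function(model, energyKeV) {
  stopIfNot(all(energyKeV > 0), "energyKeV must be > 0")
  model@energyResolutionFwhmAtRef *
    sqrt(model@referenceEnergyKeV / energyKeV)
}

# Gaussian energy-blur sigma in keV at energy E.
energyBlurSigma <- function(model, energyKeV) {
  energyKeV * energyResolutionAt(model, energyKeV) * FWHM_TO_SIGMA
}

# Compton electron edge for incident photon energy E (keV): the maximum
# energy transferred in a single scatter, E - E / (1 + 2E/511).
comptonEdge <- function(energyKeV) {
  energyKeV - energyKeV / (1 + 2 * energyKeV / 511)
}

# Expected continuum counts per bin for one line: a gently descending
# plateau from near zero up to the Compton edge, truncated there. The
# validation metrics are agnostic to the exact shape; this just puts
# realistic counts under and below each photopeak.
continuumExpected <- function(edges, energyKeV, totalCounts) {
  ec <- comptonEdge(energyKeV)
  lo <- pmax(edges[-length(edges)], 0)
  hi <- pmin(edges[-1], ec)
  wid <- pmax(hi - lo, 0)
  mid <- (lo + hi) / 2
  dens <- ifelse(wid > 0, 1 + 0.5 * (ec - mid) / ec, 0) * wid
  if (sum(dens) == 0) return(rep(0, length(wid)))
  totalCounts * dens / sum(dens)
}

# Expected Gaussian photopeak counts per bin.
peakExpected <- function(edges, centreKeV, sigmaKeV, totalCounts) {
  p <- diff(stats::pnorm(edges, mean = centreKeV, sd = sigmaKeV))
  totalCounts * p
}

#' Generate a synthetic calibration-ampoule acquisition
#'
#' Emulates a static no-collimator acquisition of a traceable calibration
#' source: each gamma line contributes a Gaussian photopeak whose expected
#' area is `A * I_gamma * eff(E) * liveTime` (the defining relation of
#' absolute efficiency, inverted), plus a scatter continuum below its
#' Compton edge; every bin is Poisson-distributed about its expectation.
#'
#' @param isotope isotope label.
#' @param lines data.frame with columns `energy_keV`, `intensity_percent`,
#'   `intensity_sigma` (standard uncertainty of the intensity, percent).
#' @param activityKBq [ValueWithUncertainty-class], source activity in kBq.
#' @param curve function mapping energy (keV) to true detection efficiency
#'   in \[0, 1\].
#' @param model a [DigitiserModel-class].
#' @param liveTimeS live time in seconds (default 600).
#' @param seed integer seed; acquisitions are bit-reproducible.
#' @param binEdgesKeV spectrum grid (default 0-600 keV in 2 keV bins).
#' @param scatterFraction continuum counts as a fraction of each peak's
#'   counts (default 0.3).
#' @return a list of [CalibrationPoint-class], one per line, sharing the
#'   acquired spectrum.
#' @export
generateCalibrationAcquisition <- function(isotope, lines, activityKBq,
                                           curve, model, liveTimeS = 600,
                                           seed = 1,
                                           binEdgesKeV = seq(0, 600, by = 2),
                                           scatterFraction = 0.3) {
  stopIfNot(nrow(lines) > 0, "lines must be non-empty")
  stopIfNot(is.function(curve), "curve must be a function of energy")
  expected <- rep(0, length(binEdgesKeV) - 1L)
  aBq <- activityKBq@value * 1e3
  for (j in seq_len(nrow(lines))) {
    e <- lines$energy_keV[j]
    lambda <- aBq * (lines$intensity_percent[j] / 100) * curve(e) * liveTimeS
    if (lambda <= 0) next
    expected <- expected +
      peakExpected(binEdgesKeV, e, energyBlurSigma(model, e), lambda) +
      continuumExpected(binEdgesKeV, e, scatterFraction * lambda)
  }
  counts <- withSeed(subSeed(seed, paste0("calib:", isotope)),
                     stats::rpois(length(expected), expected))
  spec <- energySpectrum(binEdgesKeV, counts, liveTimeS)
  lapply(seq_len(nrow(lines)), function(j) {
    calibrationPoint(isotope, lines$energy_keV[j],
                     vu(lines$intensity_percent[j], lines$intensity_sigma[j]),
                     activityKBq, liveTimeS, spec)
  })
}

#' Create a phantom activity specification
#'
#' @param totalActivityMBq [ValueWithUncertainty-class], activity at
#'   acquisition start in MBq.
#' @param halfLifeS half-life in seconds (`Inf` disables decay).
#' @param headSensitivity length-2 relative head sensitivities.
#' @param lines data.frame with columns `energy_keV`, `intensity`.
#' @param scatterFraction fraction of detected events in the scatter
#'   continuum.
#' @param sensitivityCountsPerMBqS detected counts/(s x MBq) at unit head
#'   sensitivity; sets the counting statistics of the acquisition.
#' @param sourceSigmaMm in-plane Gaussian extent of the projected source.
#' @return a [PhantomActivitySpec-class].
#' @export
phantomActivitySpec <- function(totalActivityMBq, halfLifeS = 6.0067 * 3600,
                                headSensitivity = c(1, 1),
                                lines = data.frame(energy_keV = 140.5,
                                                   intensity = 1),
                                scatterFraction = 0.25,
                                sensitivityCountsPerMBqS = 37,
                                sourceSigmaMm = 60) {
  new("PhantomActivitySpec", totalActivityMBq = totalActivityMBq,
      halfLifeS = halfLifeS, headSensitivity = as.numeric(headSensitivity),
      lines = lines, scatterFraction = scatterFraction,
      sensitivityCountsPerMBqS = sensitivityCountsPerMBqS,
      sourceSigmaMm = sourceSigmaMm)
}

# Draw n event energies from the line + continuum model with digitiser
# blurring, and n in-plane positions.
sampleEventKinematics <- function(n, spec, model) {
  if (n == 0L)
    return(data.frame(energy_keV = numeric(0), x_mm = numeric(0),
                      y_mm = numeric(0)))
  lines <- spec@lines
  pick <- sample.int(nrow(lines), n, replace = TRUE,
                     prob = lines$intensity)
  e0 <- lines$energy_keV[pick]
  isScatter <- stats::runif(n) < spec@scatterFraction
  # scatter: descending triangular density on [eMin, Compton edge]
  ec <- comptonEdge(e0)
  eMin <- pmin(20, ec / 2)
  u <- stats::runif(n)
  eScat <- eMin + (ec - eMin) * (1 - sqrt(u))
  e <- ifelse(isScatter, eScat, e0)
  e <- e + stats::rnorm(n, 0, energyBlurSigma(model, e))
  e <- pmax(e, 1)
  blurSd <- model@spatialFwhmMm * FWHM_TO_SIGMA
  x <- stats::rnorm(n, 0, spec@sourceSigmaMm) + stats::rnorm(n, 0, blurSd)
  y <- stats::rnorm(n, 0, spec@sourceSigmaMm) + stats::rnorm(n, 0, blurSd)
  data.frame(energy_keV = e, x_mm = x, y_mm = y)
}

# One full realisation of a dual-head tomographic acquisition as an event
# data.frame. Both heads acquire each rotation step simultaneously.
phantomRealisation <- function(spec, template, model, shapeWeights) {
  dt <- template@timePerProjectionS
  pph <- template@projectionsPerHead
  nproj <- template@nHeads * pph
  ev <- vector("list", nproj)
  for (h in seq_len(template@nHeads)) {
    for (k in seq_len(pph) - 1L) {
      proj <- (h - 1L) * pph + k
      tk <- k * dt
      act <- spec@totalActivityMBq@value * 2^(-tk / spec@halfLifeS)
      mu <- act * spec@sensitivityCountsPerMBqS *
        spec@headSensitivity[h] * shapeWeights[proj + 1L] * dt
      n <- stats::rpois(1, mu)
      kin <- sampleEventKinematics(n, spec, model)
      kin$projection_index <- rep(proj, n)
      kin$time_s <- tk + stats::runif(n, 0, dt)
      ev[[proj + 1L]] <- kin
    }
  }
  do.call(rbind, ev)
}

#' Generate a paired synthetic phantom acquisition
#'
#' Produces (i) a "simulated" detected-event list -- the analogue of raw
#' Monte-Carlo singles output, with unit detection efficiency -- and (ii) an
#' independently seeded "experimental" realisation of the same ground truth
#' whose events are additionally thinned by the true camera-efficiency
#' curve, returned as per-window projection stacks and a total energy
#' spectrum. Both heads acquire rotation steps simultaneously, so step k of
#' head 1 (projection k) and head 2 (projection 60+k in the default
#' geometry) see the same decayed activity.
#'
#' @param spec a [PhantomActivitySpec-class].
#' @param template a [ProjectionStack-class] supplying the geometry (its
#'   pixel values are ignored).
#' @param windows list of [EnergyWindow-class] to gate the experimental
#'   stacks on.
#' @param model a [DigitiserModel-class].
#' @param trueEfficiency function mapping energy (keV) to the ground-truth
#'   camera efficiency in \[0, 1\] applied to the experimental realisation.
#' @param shapeWeights non-negative per-projection shape weights (length
#'   nProjections, one value per projection of each head block); default
#'   uniform.
#' @param seed integer seed.
#' @return list with elements `simEvents` ([DetectedEvents-class]),
#'   `expEvents` ([DetectedEvents-class], thinned), `expStacks` (named list
#'   of [ProjectionStack-class], one per window) and `expSpectrum`
#'   ([EnergySpectrum-class], 2 keV bins).
#' @export
generatePhantomAcquisition <- function(spec, template, windows, model,
                                       trueEfficiency = function(e) 1,
                                       shapeWeights = NULL, seed = 1) {
  nproj <- template@nHeads * template@projectionsPerHead
  if (is.null(shapeWeights)) shapeWeights <- rep(1, nproj)
  stopIfNot(length(shapeWeights) == nproj,
            "need one shape weight per projection")
  stopIfNot(all(shapeWeights >= 0), "shape weights must be >= 0")
  duration <- template@projectionsPerHead * template@timePerProjectionS

  sim <- withSeed(subSeed(seed, "phantom:sim"),
                  phantomRealisation(spec, template, model, shapeWeights))
  simEvents <- detectedEvents(sim, nproj, duration)

  exp_ <- withSeed(subSeed(seed, "phantom:exp"), {
    r <- phantomRealisation(spec, template, model, shapeWeights)
    keep <- stats::runif(nrow(r)) < trueEfficiency(r$energy_keV)
    r[keep, , drop = FALSE]
  })
  expEvents <- detectedEvents(exp_, nproj, duration)

  expStacks <- lapply(windows, function(w)
    binEventsToStack(expEvents, template, w))
  names(expStacks) <- vapply(windows, function(w) w@label, character(1))
  expSpectrum <- buildSpectrum(expEvents, binWidthKeV = 2,
                               rangeKeV = c(0, 600))
  list(simEvents = simEvents, expEvents = expEvents,
       expStacks = expStacks, expSpectrum = expSpectrum)
}

#' Generate a synthetic point-source planar image
#'
#' Counts are multinomially distributed over the pixel grid under a 2-D
#' Gaussian whose FWHM adds the collimator resolution and the intrinsic
#' spatial blur in quadrature; the image total equals `totalCounts`
#' exactly, emulating a count-terminated static acquisition.
#'
#' @param positionMm length-2 source position (x, y) in mm, origin at the
#'   detector face centre.
#' @param collimatorFwhmMm collimator-level FWHM in mm.
#' @param model a [DigitiserModel-class] (supplies the intrinsic blur).
#' @param totalCounts total image counts (default 500000).
#' @param matrixSize length-2 image dimensions (rows, cols).
#' @param pixelSizeMm pixel size in mm.
#' @param seed integer seed.
#' @return integer matrix of counts (rows x cols).
#' @export
generatePointSource <- function(positionMm = c(0, 0), collimatorFwhmMm = 9.63,
                                model = digitiserModel(),
                                totalCounts = 500000,
                                matrixSize = c(128, 128),
                                pixelSizeMm = 4.2578, seed = 1) {
  stopIfNot(totalCounts > 0, "totalCounts must be > 0")
  fwhmEff <- sqrt(collimatorFwhmMm^2 + model@spatialFwhmMm^2)
  sig <- fwhmEff * FWHM_TO_SIGMA
  nr <- matrixSize[1]; nc <- matrixSize[2]
  xEdges <- (seq_len(nc + 1) - 1 - nc / 2) * pixelSizeMm
  yEdges <- (seq_len(nr + 1) - 1 - nr / 2) * pixelSizeMm
  if (positionMm[1] < xEdges[1] || positionMm[1] > xEdges[nc + 1] ||
      positionMm[2] < yEdges[1] || positionMm[2] > yEdges[nr + 1])
    stop("source position outside the field of view")
  px <- diff(stats::pnorm(xEdges, positionMm[1], sig))
  py <- diff(stats::pnorm(yEdges, positionMm[2], sig))
  prob <- as.vector(outer(py, px))  # row-major cell probabilities
  img <- withSeed(subSeed(seed, "pointsource"),
                  stats::rmultinom(1, size = totalCounts, prob = prob))
  matrix(as.integer(img), nrow = nr, ncol = nc)
}

#' Generate a synthetic background spectrum
#'
#' Per-bin counts are Poisson with mean `rate * duration`.
#'
#' @param rateSpectrum an [EnergySpectrum-class] whose counts are rates in
#'   counts/s per bin (live time 1 s by convention).
#' @param durationS acquisition duration in seconds.
#' @param seed integer seed.
#' @return an [EnergySpectrum-class] with live time `durationS`.
#' @export
generateBackgroundSpectrum <- function(rateSpectrum, durationS, seed = 1) {
  stopIfNot(all(specCounts(rateSpectrum) >= 0), "rates must be >= 0")
  lambda <- specCounts(rateSpectrum) / liveTime(rateSpectrum) * durationS
  counts <- withSeed(subSeed(seed, "background:spectrum"),
                     stats::rpois(length(lambda), lambda))
  energySpectrum(binEdges(rateSpectrum), counts, durationS)
}

#' Generate a synthetic background projection stack
#'
#' Every pixel is Poisson with mean `ratePerPixelPerS * timePerProjection`.
#'
#' @param template a [ProjectionStack-class] supplying the geometry.
#' @param ratePerPixelPerS background rate per pixel in counts/s.
#' @param seed integer seed.
#' @return a [ProjectionStack-class].
#' @export
generateBackgroundStack <- function(template, ratePerPixelPerS, seed = 1) {
  stopIfNot(ratePerPixelPerS >= 0, "rate must be >= 0")
  d <- dim(template@pixels)
  lambda <- ratePerPixelPerS * template@timePerProjectionS
  v <- withSeed(subSeed(seed, "background:stack"),
                stats::rpois(prod(d), lambda))
  projectionStack(array(pmin(v, 65535L), dim = d),
                  pixelSizeMm = template@pixelSizeMm,
                  timePerProjectionS = template@timePerProjectionS,
                  nHeads = template@nHeads,
                  projectionsPerHead = template@projectionsPerHead)
}
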
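# helpers: a constructed photopeak spectrum with known Gaussian area
peakSpectrum <- function(area = 1e5, centre = 140, sigma = 5.6,
                         bg = 0, liveTime = 100, poisson = FALSE,
                         seed = 1) {
  edges <- seq(100, 180, 2)
  mids <- (edges[-1] + edges[-41]) / 2
  expected <- area * (pnorm(edges[-1], centre, sigma) -
                        pnorm(edges[-41], centre, sigma)) + bg
  counts <- if (poisson) withr::with_seed(seed, rpois(40, expected)) else
    expected
  energySpectrum(edges, counts, liveTime)
}

test_that("photopeak fit recovers a known Gaussian area over background", {
  pk <- fitPhotopeak(peakSpectrum(), c(120, 160))
  expect_equal(uValue(pk$netRate), 1000, tolerance = 1e-3)
  expect_equal(pk$centreKeV, 140, tolerance = 0.05)
  expect_equal(pk$sigmaKeV, 5.6, tolerance = 0.05)
  # a constant background leaves the net rate unchanged
  pkBg <- fitPhotopeak(peakSpectrum(bg = 500), c(120, 160))
  expect_equal(uValue(pkBg$netRate), uValue(pk$netRate), tolerance = 1e-2)
  # with Poisson noise the area stays within 5 sigma of truth
  pkP <- fitPhotopeak(peakSpectrum(poisson = TRUE), c(120, 160))
  expect_lt(abs(uValue(pkP$netRate) - 1000),
            5 * max(uSigma(pkP$netRate), sqrt(1e5) / 100))
})

test_that("degenerate spectra are fit errors", {
  edges <- seq(100, 180, 2)
  zeros <- energySpectrum(edges, rep(0, 40), 100)
  expect_error(fitPhotopeak(zeros, c(120, 160)), "zero")
  flat <- energySpectrum(edges, rep(7, 40), 100)
  expect_error(fitPhotopeak(flat, c(120, 160)), "flat")
  expect_error(fitPhotopeak(peakSpectrum(), c(139, 141)), "8 bins")
})

test_that("absolute efficiency implements the quadrature propagation", {
  e1 <- absoluteEfficiency(vu(1, 0), vu(1, 0), vu(1, 0), 100)
  expect_equal(uValue(e1@epsilon), 1)
  expect_equal(uSigma(e1@epsilon), 0)
  e2 <- absoluteEfficiency(vu(100, 10), vu(50, 1), vu(0.5, 0.005), 100)
  expect_equal(uValue(e2@epsilon), 4)
  expect_equal(uSigma(e2@epsilon), 4 * sqrt(0.01 + 4e-4 + 1e-4))
  # doubling the activity halves the efficiency
  e3 <- absoluteEfficiency(vu(100, 10), vu(100, 2), vu(0.5, 0.005), 100)
  expect_equal(uValue(e3@epsilon), 2)
  expect_error(absoluteEfficiency(vu(1, 0), vu(0, 0), vu(1, 0), 100),
               "> 0")
})

test_that("efficiency ratios pair on energy and propagate in quadrature", {
  mkPts <- function(scale, sigFrac) lapply(c(60, 140, 208), function(e)
    absoluteEfficiency(vu(scale * e / 100, sigFrac * scale * e / 100),
                       vu(1, 0), vu(1, 0), e))
  same <- correctionRatios(mkPts(1, 0.01), mkPts(1, 0.01))
  expect_equal(same$ratio, rep(1, 3))
  half <- correctionRatios(mkPts(0.5, 0.01), mkPts(1, 0.01))
  expect_equal(half$ratio, rep(0.5, 3))
  expect_error(correctionRatios(mkPts(1, 0.01)[1:2], mkPts(1, 0.01)[3]),
               "pairing error")
})

test_that("the log-quadratic fit is exact on exact data", {
  e <- c(46, 60, 88, 140, 208, 356)
  y <- -3.755 + 1.702 * log(e) - 0.168 * log(e)^2
  corr <- fitCorrection(data.frame(energy_keV = e, ratio = y, sigma = 0.01))
  expect_equal(corr@a, -3.755, tolerance = 1e-6)
  expect_equal(corr@b, 1.702, tolerance = 1e-6)
  expect_equal(corr@c, -0.168, tolerance = 1e-6)
  expect_error(fitCorrection(data.frame(energy_keV = e[1:3], ratio = y[1:3],
                                        sigma = 0.01)), "underdetermined")
})

test_that("the published piecewise correction behaves as printed", {
  corr <- referenceCorrection()
  # fixed to zero at 2 keV
  expect_equal(evaluateCorrection(corr, 2), 0, tolerance = 1e-9)
  # the linear function evaluated at the 46 keV breakpoint
  expect_equal(corr@intercept + corr@slope * 46, 0.2948, tolerance = 1e-9)
  # at and above the breakpoint the log-quadratic applies
  expect_equal(evaluateCorrection(corr, 46),
               -3.755 + 1.702 * log(46) - 0.168 * log(46)^2)
  expect_equal(evaluateCorrection(corr, 140),
               -3.755 + 1.702 * log(140) - 0.168 * log(140)^2)
  # low-energy zero crossing of the log-quadratic sits near 26 keV
  root <- uniroot(function(e) -3.755 + 1.702 * log(e) - 0.168 * log(e)^2,
                  c(5, 40))$root
  expect_equal(round(root), 26)
  expect_error(evaluateCorrection(corr, -1), "> 0")
  expect_error(evaluateCorrection(corr, 0), "> 0")
})

test_that("the perturbation band matches the analytic covariance", {
  e <- c(46, 60, 88, 140, 208, 356)
  y <- -3.755 + 1.702 * log(e) - 0.168 * log(e)^2
  s <- 0.01 * (1 + e / 300)
  pts <- data.frame(energy_keV = e, ratio = y, sigma = s)
  corr <- fitUncertaintyBand(pts, nRefits = 1000, seed = 4)
  q <- c(50, 90, 150, 300)
  got <- bandSigma(corr, q)
  X <- cbind(1, log(e), log(e)^2)
  W <- diag(1 / s^2)
  covB <- solve(t(X) %*% W %*% X)
  want <- vapply(q, function(qe) {
    x <- c(1, log(qe), log(qe)^2)
    sqrt(drop(t(x) %*% covB %*% x))
  }, numeric(1))
  expect_equal(got, want, tolerance = 0.1)
})

test_that("the band is zero for exact points and scales with their sigmas", {
  e <- c(46, 60, 88, 140, 208, 356)
  y <- -3.755 + 1.702 * log(e) - 0.168 * log(e)^2
  exact <- fitUncertaintyBand(
    data.frame(energy_keV = e, ratio = y, sigma = 0), nRefits = 200,
    seed = 1, weighted = FALSE)
  expect_equal(bandSigma(exact, c(50, 150)), c(0, 0))
  b1 <- fitUncertaintyBand(data.frame(energy_keV = e, ratio = y,
                                      sigma = rep(0.01, 6)),
                           nRefits = 500, seed = 2)
  b2 <- fitUncertaintyBand(data.frame(energy_keV = e, ratio = y,
                                      sigma = rep(0.02, 6)),
                           nRefits = 500, seed = 2)
  q <- c(50, 100, 200, 340)
  expect_equal(bandSigma(b2, q) / bandSigma(b1, q), rep(2, 4),
               tolerance = 1e-6)
})

test_that("event-by-event correction has the right expectations", {
  n <- 2e5
  ev <- detectedEvents(makeEventsDF(n, nproj = 4, duration = 100, seed = 2),
                       4, 100)
  unit <- efficiencyCorrection(1, 0, 0, breakpointKeV = 10, anchorKeV = 2)
  outUnit <- applyCorrection(ev, unit, "poisson", seed = 1)
  expect_lt(abs(length(outUnit) - n), 5 * sqrt(n))
  halfC <- efficiencyCorrection(0.5, 0, 0, breakpointKeV = 10, anchorKeV = 2)
  for (mode in c("poisson", "thin")) {
    out <- applyCorrection(ev, halfC, mode, seed = 1)
    expect_lt(abs(length(out) - n / 2), 5 * sqrt(n / 2))
  }
  zero <- efficiencyCorrection(0, 0, 0, breakpointKeV = 10, anchorKeV = 2)
  expect_equal(length(applyCorrection(ev, zero, "poisson", seed = 1)), 0L)
  # determinism
  expect_identical(
    eventData(applyCorrection(ev, halfC, "poisson", seed = 7)),
    eventData(applyCorrection(ev, halfC, "poisson", seed = 7)))
})

test_that("thin mode clamps corrections above one with a warning", {
  ev <- detectedEvents(makeEventsDF(1000, seed = 3), 4, 100)
  big <- efficiencyCorrection(1.5, 0, 0, breakpointKeV = 10, anchorKeV = 2)
  expect_warning(out <- applyCorrection(ev, big, "thin", seed = 1),
                 "clamped")
  expect_equal(length(out), 1000L)
  # poisson mode happily amplifies
  out2 <- applyCorrection(ev, big, "poisson", seed = 1)
  expect_lt(abs(length(out2) - 1500), 5 * sqrt(1500))
})

test_that("correction preserves the efficiency-reweighted energy shape", {
  n <- 2e5
  ev <- detectedEvents(makeEventsDF(n, seed = 4), 4, 100)
  corr <- referenceCorrection()
  out <- applyCorrection(ev, corr, "poisson", seed = 2)
  breaks <- seq(50, 400, 35)
  eff <- evaluateCorrection(corr, eventData(ev)$energy_keV)
  expected <- vapply(seq_len(10), function(b) {
    sel <- eventData(ev)$energy_keV >= breaks[b] &
      eventData(ev)$energy_keV < breaks[b + 1]
    sum(eff[sel])
  }, numeric(1))
  obs <- tabulate(findInterval(eventData(out)$energy_keV, breaks),
                  nbins = 10)
  chi2 <- sum((obs - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, 10))
})

test_that("corrections serialise to structured text and back", {
  e <- c(46, 60, 88, 140, 208, 356)
  y <- truthCurve(e)
  corr <- fitUncertaintyBand(
    data.frame(energy_keV = e, ratio = y, sigma = rep(0.01, 6)),
    nRefits = 50, seed = 5)
  f <- withr::local_tempfile(fileext = ".yaml")
  writeCorrection(corr, f)
  back <- readCorrection(f)
  q <- c(10, 46, 150, 300)
  expect_equal(evaluateCorrection(back, q), evaluateCorrection(corr, q))
  expect_equal(bandSigma(back, q), bandSigma(corr, q), tolerance = 1e-6)
})

test_that("fitted corrections recover a known truth curve end to end", {
  ratios <- makeCalibrationRatios(seed = 21)
  corr <- fitUncertaintyBand(ratios, nRefits = 400, seed = 22)
  q <- seq(46, 356, 10)
  err <- evaluateCorrection(corr, q) - truthCurve(q)
  bs <- bandSigma(corr, q)
  expect_gte(mean(abs(err) <= 1.96 * bs), 0.95)
})
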
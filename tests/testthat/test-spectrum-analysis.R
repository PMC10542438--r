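test_that("event binning conserves counts with half-open bins", {
  ev <- detectedEvents(makeEventsDF(1000, seed = 5), 4, 100)
  sp <- buildSpectrum(ev, binWidthKeV = 2)
  expect_equal(sum(specCounts(sp)), 1000)
  # an event exactly at a bin edge lands in the upper bin
  one <- detectedEvents(data.frame(energy_keV = 100, x_mm = 0, y_mm = 0,
                                   projection_index = 0L, time_s = 0),
                        1, 10)
  sp1 <- buildSpectrum(one, 2, rangeKeV = c(0, 200))
  expect_equal(specCounts(sp1)[51], 1)  # bin [100, 102)
  expect_equal(specCounts(sp1)[50], 0)
  expect_error(buildSpectrum(ev, 0), "> 0")
})

test_that("pairwise rebinning equals direct coarse binning", {
  ev <- detectedEvents(makeEventsDF(2000, seed = 6), 4, 100)
  fine <- buildSpectrum(ev, 1, rangeKeV = c(0, 400))
  coarse <- buildSpectrum(ev, 2, rangeKeV = c(0, 400))
  paired <- colSums(matrix(specCounts(fine), nrow = 2))
  expect_equal(paired, specCounts(coarse))
})

test_that("time-corrected background addition is Poisson in the scaled rate", {
  edges <- seq(0, 100, 2)
  target <- energySpectrum(edges, rep(10, 50), 100)
  zero <- energySpectrum(edges, rep(0, 50), 400)
  expect_equal(specCounts(addTimeCorrectedBackground(target, zero, 1)),
               specCounts(target))
  bgHigh <- energySpectrum(edges, rep(1e4, 50), 100)
  added <- addTimeCorrectedBackground(target, bgHigh, 1)
  expect_true(all(abs(specCounts(added) - specCounts(target) - 1e4) <
                    5 * sqrt(1e4)))
  # doubling the target live time doubles the expected addition
  target2 <- energySpectrum(edges, rep(10, 50), 200)
  added2 <- addTimeCorrectedBackground(target2, bgHigh, 2)
  expect_lt(abs(sum(specCounts(added2) - specCounts(target2)) - 2e4 * 50),
            5 * sqrt(2e4 * 50))
  mism <- energySpectrum(seq(0, 100, 4), rep(1, 25), 100)
  expect_error(addTimeCorrectedBackground(target, mism, 1), "alignment")
})

test_that("total-count normalisation rescales without changing shape", {
  edges <- seq(0, 20, 2)
  a <- energySpectrum(edges, c(1, 2, 3, 4, 5, 5, 4, 3, 2, 1), 10)
  expect_equal(specCounts(normaliseTotal(a, a)), specCounts(a))
  b <- energySpectrum(edges, 2 * specCounts(a), 10)
  expect_equal(specCounts(normaliseTotal(a, b)), 2 * specCounts(a))
  zero <- energySpectrum(edges, rep(0, 10), 10)
  expect_error(normaliseTotal(zero, a), "zero-total")
  # residuals of a normalised spectrum against its reference total are
  # zero when shapes already agree
  r <- percentageResiduals(normaliseTotal(a, b), b)
  expect_equal(r@residualPercent, rep(0, 10))
})

test_that("percentage residuals compare rate densities", {
  edges <- seq(100, 180, 2)
  exp_ <- energySpectrum(edges, rep(400, 40), 100)
  simSame <- energySpectrum(edges, rep(800, 40), 200)  # same rate
  r0 <- percentageResiduals(simSame, exp_)
  expect_equal(r0@residualPercent, rep(0, 40))
  sim10 <- energySpectrum(edges, rep(440, 40), 100)
  r10 <- percentageResiduals(sim10, exp_)
  expect_equal(r10@residualPercent, rep(10, 40))
  # zero experimental bins are excluded and counted
  expHole <- energySpectrum(edges, c(0, rep(400, 39)), 100)
  rh <- percentageResiduals(sim10, expHole)
  expect_true(is.na(rh@residualPercent[1]))
  expect_equal(rh@nExcluded, 1L)
  expect_error(percentageResiduals(
    sim10, energySpectrum(edges, rep(0, 40), 100)), "all zero")
})

test_that("residual sigmas match a Poisson resampling oracle within 5%", {
  edges <- seq(0, 4, 2)
  S0 <- 400; E0 <- 500
  formulaSigma <- percentageResiduals(
    energySpectrum(edges, c(S0, S0), 1),
    energySpectrum(edges, c(E0, E0), 1))@sigmaPercent[1]
  mc <- withr::with_seed(13, {
    ns <- rpois(1e4, S0); ne <- rpois(1e4, E0)
    keep <- ne > 0
    sd(100 * (ns[keep] - ne[keep]) / ne[keep])
  })
  expect_equal(formulaSigma, mc, tolerance = 0.05)
})

test_that("window-weighted residual means behave like a weighted mean", {
  edges <- seq(100, 180, 2)
  centres <- (edges[-1] + edges[-41]) / 2
  resid <- new("ResidualSeries", binCentresKeV = centres,
               residualPercent = sin(centres / 10) * 5,
               sigmaPercent = rep(1.3, 40), nExcluded = 0L)
  w <- energyWindow("EM", 140.5, 10)
  wm <- windowWeightedMean(resid, w)
  sel <- centres >= 126.45 & centres < 154.55
  expect_equal(uValue(wm), mean(resid@residualPercent[sel]))
  expect_equal(uSigma(wm), 1.3 / sqrt(sum(sel)))
  # lies inside the range of in-window residuals
  expect_gte(uValue(wm), min(resid@residualPercent[sel]))
  expect_lte(uValue(wm), max(resid@residualPercent[sel]))
  # heterogeneous sigmas: brute-force direct sum
  resid2 <- new("ResidualSeries", binCentresKeV = centres,
                residualPercent = resid@residualPercent,
                sigmaPercent = seq(0.5, 4, length.out = 40),
                nExcluded = 0L)
  wm2 <- windowWeightedMean(resid2, w)
  wgt <- 1 / resid2@sigmaPercent[sel]^2
  expect_equal(uValue(wm2),
               sum(wgt * resid2@residualPercent[sel]) / sum(wgt))
  # single usable bin returns that bin
  narrow <- energyWindow("one", 141, 0.5)
  wm1 <- windowWeightedMean(resid2, narrow)
  iSel <- which(inWindow(centres, narrow))
  expect_equal(uValue(wm1), resid2@residualPercent[iSel])
  expect_error(windowWeightedMean(resid2, energyWindow("out", 500, 1)),
               "no usable")
})

test_that("same-truth spectra give window means consistent with zero", {
  edges <- seq(100, 180, 2)
  centres <- (edges[-1] + edges[-41]) / 2
  expected <- 5000 * exp(-(centres - 140)^2 / (2 * 6^2)) + 200
  w <- energyWindow("EM", 140.5, 10)
  hits <- 0L
  for (seed in 1:20) {
    cs <- withr::with_seed(seed, rpois(40, expected))
    ce <- withr::with_seed(seed + 100, rpois(40, expected))
    wm <- windowWeightedMean(percentageResiduals(
      energySpectrum(edges, cs, 10), energySpectrum(edges, ce, 10)), w)
    if (abs(uValue(wm)) <= 3 * uSigma(wm)) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})
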
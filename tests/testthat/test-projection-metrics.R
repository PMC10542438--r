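smallTemplate <- function(nproj = 4L, n = 16L, dt = 10) {
  projectionStack(array(0L, c(nproj, n, n)), pixelSizeMm = 10,
                  timePerProjectionS = dt, nHeads = 2L,
                  projectionsPerHead = nproj / 2L)
}

test_that("events are binned to the documented pixel convention", {
  tmpl <- smallTemplate()
  # pixel (0,0) is top-left; face centre maps to pixel (8,8) for n=16
  ev <- detectedEvents(data.frame(
    energy_keV = c(140, 140, 140), x_mm = c(1, 1, -75),
    y_mm = c(1, 1, -75), projection_index = c(2L, 2L, 0L),
    time_s = c(0, 1, 2)), 4, 40)
  st <- binEventsToStack(ev, tmpl)
  expect_equal(st@pixels[3, 9, 9], 2L)
  expect_equal(st@pixels[1, 1, 1], 1L)
  expect_equal(sum(st@pixels), 3L)
  # out-of-field events are counted, not silently dropped
  far <- detectedEvents(data.frame(
    energy_keV = 140, x_mm = 500, y_mm = 0, projection_index = 0L,
    time_s = 0), 4, 40)
  stFar <- binEventsToStack(far, tmpl)
  expect_equal(attr(stFar, "nOutOfField"), 1L)
  expect_equal(sum(stFar@pixels), 0L)
})

test_that("disjoint emission and scatter windows partition the events", {
  tmpl <- smallTemplate()
  ev <- detectedEvents(makeEventsDF(5000, nproj = 4, seed = 9), 4, 100)
  ev@events$x_mm <- pmax(pmin(ev@events$x_mm, 70), -70)
  ev@events$y_mm <- pmax(pmin(ev@events$y_mm, 70), -70)
  em <- energyWindow("EM", 140.5, 10)
  sc <- energyWindow("SC", 119.0, 5)
  stEm <- binEventsToStack(ev, tmpl, em)
  stSc <- binEventsToStack(ev, tmpl, sc)
  # brute-force per-event filter oracle
  e <- eventData(ev)$energy_keV
  expect_equal(sum(stEm@pixels), sum(e >= 126.45 & e < 154.55))
  expect_equal(sum(stSc@pixels), sum(e >= 113.05 & e < 124.95))
  both <- sum(inWindow(e, em) & inWindow(e, sc))
  expect_equal(both, 0L)
})

test_that("sensitivity implements c/(A*T) with its propagation", {
  s1 <- sensitivity(1000, vu(10, 0), 100, effBandRel = 0,
                    source = "experiment")
  expect_equal(uValue(s1@S), 1)
  expect_equal(uSigma(s1@S), sqrt(1 / 1000))
  # efficiency-band term dominates when counts are plentiful
  s2 <- sensitivity(1e6, vu(10, 0), 100, effBandRel = 0.02)
  expect_equal(uSigma(s2@S) / uValue(s2@S), sqrt(0.001^2 + 0.02^2),
               tolerance = 1e-6)
  # experimental mode: activity uncertainty dominates over Poisson
  s3 <- sensitivity(1e6, vu(10, 0.1), 100, effBandRel = 0,
                    source = "experiment")
  expect_equal(uSigma(s3@S) / uValue(s3@S), sqrt(0.01^2 + 0.001^2))
  expect_error(sensitivity(10, vu(10, 0), 0), "> 0")
  expect_error(sensitivity(10, vu(0, 0), 10), "> 0")
})

test_that("sensitivity is additive under splitting an acquisition", {
  A <- vu(10, 0)
  whole <- sensitivity(2000, A, 200)
  halves <- sensitivity(900, A, 100)
  # (c1 + c2) / (A (T1 + T2)) identical to pooled computation
  pooled <- sensitivity(900 + 1100, A, 100 + 100)
  expect_equal(uValue(pooled@S), uValue(whole@S))
})

test_that("sensitivity ratios reproduce the reference-table cells", {
  r1 <- sensitivityRatio(vu(36.33, 0.73), vu(37.39, 0.33))
  expect_equal(uValue(r1), 0.972, tolerance = 5e-4)
  expect_equal(uSigma(r1), 0.021, tolerance = 0.05)
  r2 <- sensitivityRatio(vu(8.74, 0.19), vu(7.865, 0.071))
  expect_equal(uValue(r2), 1.111, tolerance = 5e-4)
  expect_equal(uSigma(r2), 0.026, tolerance = 0.05)
  rSelf <- sensitivityRatio(vu(5, 0.1), vu(5, 0.1))
  expect_equal(uValue(rSelf), 1)
  expect_equal(uSigma(rSelf), sqrt(2) * 0.02)
  expect_error(sensitivityRatio(vu(1, 0), vu(0, 0)), "> 0")
})

test_that("sinogram comparison flags deviations beyond the 3-sigma band", {
  px <- withr::with_seed(20, array(rpois(4 * 16 * 16, 50), c(4, 16, 16)))
  st <- projectionStack(px, nHeads = 2L, projectionsPerHead = 2L)
  same <- sinogramCompare(st, st, vu(1, 0.01))
  expect_equal(same@ratio, rep(1, 4))
  expect_false(any(same@flagged))
  expect_equal(uValue(same@weightedMean), 1)

  up <- projectionStack(array(as.integer(round(px * 1.05)), dim(px)),
                        nHeads = 2L, projectionsPerHead = 2L)
  shifted <- sinogramCompare(up, st, vu(1, 0.01))
  expect_equal(shifted@ratio, rep(1.05, 4), tolerance = 0.01)
  expect_true(all(shifted@flagged))

  # weighted mean equals the count-weighted direct sum over projections
  e <- projectionTotals(st); s <- projectionTotals(up)
  expect_equal(uValue(shifted@weightedMean), sum(s) / sum(e),
               tolerance = 1e-9)
})

test_that("zero-count experimental projections are excluded", {
  px <- array(5L, c(4, 8, 8)); px[2, , ] <- 0L
  exp_ <- projectionStack(px, nHeads = 2L, projectionsPerHead = 2L)
  sim <- projectionStack(array(5L, c(4, 8, 8)), nHeads = 2L,
                         projectionsPerHead = 2L)
  cmp <- sinogramCompare(sim, exp_, vu(1, 0.01))
  expect_equal(cmp@nExcluded, 1L)
  expect_true(is.na(cmp@ratio[2]))
})

test_that("PSNR matches hand-computed cases exactly", {
  f <- matrix(0, 128, 128)
  expect_identical(psnr(f, f), Inf)
  g <- f; g[64, 64] <- 32768
  expect_equal(psnr(f, g), 20 * log10(128), tolerance = 1e-9)
  expect_equal(psnr(f, g), 42.144199, tolerance = 1e-6)
  expect_equal(psnr(f, g), psnr(g, f))
  expect_error(psnr(f, matrix(0, 64, 64)), "same shape")
  # monotone decay with uniform noise amplitude
  vals <- vapply(c(10, 100, 1000), function(a) {
    noisy <- f + withr::with_seed(30, matrix(runif(128^2, 0, a), 128))
    psnr(f, noisy)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("shifted-self PSNR baseline reproduces analytic cases", {
  expect_identical(uValue(psnrReference(matrix(7, 32, 32))), Inf)
  chk <- outer(1:32, 1:32, function(i, j) ((i + j) %% 2) * 32768)
  expect_equal(uValue(psnrReference(chk)), 0, tolerance = 1e-9)
  # a smooth image has a higher baseline than the same image plus noise
  smooth <- outer(1:32, 1:32, function(i, j)
    30000 * exp(-((i - 16)^2 + (j - 16)^2) / 100))
  noisy <- smooth + withr::with_seed(31, matrix(rpois(1024, 400), 32))
  expect_gt(uValue(psnrReference(round(smooth))),
            uValue(psnrReference(round(noisy))))
})

test_that("slice-wise stack PSNR aggregates with count weights", {
  px <- withr::with_seed(33, array(rpois(4 * 16 * 16, 100), c(4, 16, 16)))
  a <- projectionStack(px, nHeads = 2L, projectionsPerHead = 2L)
  b <- projectionStack(px + 1L, nHeads = 2L, projectionsPerHead = 2L)
  agg <- stackPsnr(b, a)
  per <- attr(agg, "perSlice")
  w <- projectionTotals(a)
  expect_equal(uValue(agg), sum(w * per) / sum(w))
  expect_identical(uValue(stackPsnr(a, a)), Inf)
})

test_that("profile FWHM recovers a noiseless sampled Gaussian exactly", {
  n <- 64; ps <- 1
  pos <- (seq_len(n) - 0.5 - n / 2) * ps
  img <- outer(exp(-pos^2 / (2 * 4.306^2)),
               exp(-pos^2 / (2 * 4.306^2))) * 1e4
  for (ax in c("x", "y")) {
    fw <- profileFwhm(img, ax, pixelSizeMm = ps)
    expect_equal(uValue(fw), 2 * sqrt(2 * log(2)) * 4.306,
                 tolerance = 1e-4)
    expect_equal(uValue(fw), 10.140, tolerance = 1e-3)
  }
  expect_error(profileFwhm(matrix(0, 16, 16), "x"), "all zero")
  border <- matrix(0, 16, 16); border[1, 1] <- 10
  expect_error(profileFwhm(border, "x"), "border")
})

test_that("profile FWHM recovers the generator ground truth within 3 sigma", {
  img <- generatePointSource(totalCounts = 500000, seed = 12)
  truth <- sqrt(9.63^2 + 3.2^2)
  for (ax in c("x", "y")) {
    fw <- profileFwhm(img, ax, pixelSizeMm = 4.2578)
    expect_lt(abs(uValue(fw) - truth), 3 * uSigma(fw))
  }
})
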
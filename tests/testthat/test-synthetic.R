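test_that("energy resolution follows the inverse square-root law", {
  m <- digitiserModel()
  expect_equal(energyResolutionAt(m, 140), 0.095)
  expect_equal(energyResolutionAt(m, 560), 0.0475)
  expect_equal(energyResolutionAt(m, 35), 0.19)
  expect_error(energyResolutionAt(m, 0), "> 0")
  expect_error(energyResolutionAt(m, -10), "> 0")
})

test_that("calibration photopeak areas are Poisson about A*I*eff*t", {
  m <- digitiserModel()
  lines <- data.frame(energy_keV = 140, intensity_percent = 89,
                      intensity_sigma = 4)
  # A * I * eff * t = 1e6: A = 1e6 / (0.89 * 0.5 * 600) Bq
  aKBq <- 1e6 / (0.89 * 0.5 * 600) / 1e3
  for (seed in 1:4) {
    cp <- generateCalibrationAcquisition(
      "Tc-99m", lines, vu(aKBq, 0), function(e) rep(0.5, length(e)),
      m, liveTimeS = 600, seed = seed, scatterFraction = 0)[[1]]
    sig <- 140 * 0.095 / 2.3548
    sel <- binCentres(cp@spectrum) >= 140 - 5 * sig &
      binCentres(cp@spectrum) < 140 + 5 * sig
    area <- sum(specCounts(cp@spectrum)[sel])
    expect_lt(abs(area - 1e6), 5 * sqrt(1e6))
  }
})

test_that("calibration spectra are reproducible and seed-sensitive", {
  m <- digitiserModel()
  lines <- data.frame(energy_keV = 140, intensity_percent = 89,
                      intensity_sigma = 4)
  gen <- function(seed) specCounts(generateCalibrationAcquisition(
    "Tc-99m", lines, vu(100, 1), function(e) rep(0.5, length(e)), m,
    seed = seed)[[1]]@spectrum)
  expect_identical(gen(3), gen(3))
  expect_false(identical(gen(3), gen(4)))
  # zero efficiency -> empty spectrum
  empty <- generateCalibrationAcquisition(
    "Tc-99m", lines, vu(100, 1), function(e) rep(0, length(e)), m,
    seed = 1)[[1]]
  expect_equal(sum(specCounts(empty@spectrum)), 0)
})

flatPhantom <- function(headSens = c(1, 1), halfLife = 1e12, seed = 5,
                        sens = 5, pph = 60L, dt = 4) {
  template <- projectionStack(array(0L, c(2L * pph, 32, 32)),
                              timePerProjectionS = dt, nHeads = 2L,
                              projectionsPerHead = pph)
  spec <- phantomActivitySpec(vu(100, 0), halfLifeS = halfLife,
                              headSensitivity = headSens,
                              sensitivityCountsPerMBqS = sens,
                              sourceSigmaMm = 20)
  generatePhantomAcquisition(spec, template, list(), digitiserModel(),
                             seed = seed)
}

projCounts <- function(events, nproj) {
  tabulate(eventData(events)$projection_index + 1L, nbins = nproj)
}

test_that("uniform weights and no decay give a flat sinogram", {
  gen <- flatPhantom()
  n <- projCounts(gen$simEvents, 120)
  mu <- mean(n)
  # chi-square about the common mean, 119 dof
  expect_lt(sum((n - mu)^2 / mu), 200)
})

test_that("a head-sensitivity imbalance appears as a step at projection 60", {
  gen <- flatPhantom(headSens = c(1, 0.9), seed = 8)
  n <- projCounts(gen$simEvents, 120)
  r <- sum(n[61:120]) / sum(n[1:60])
  expect_lt(abs(r - 0.9), 5 * 0.9 * sqrt(2 / sum(n[1:60])))
})

test_that("radioactive decay produces the 2^(-k/60) decline per head", {
  dt <- 4
  gen <- flatPhantom(halfLife = dt * 60, seed = 9)
  n <- projCounts(gen$simEvents, 120)[1:60]
  k <- 0:59
  slope <- coef(lm(log2(n) ~ k))[["k"]]
  expect_lt(abs(slope + 1 / 60), 0.002)
})

test_that("both heads acquire rotation steps simultaneously", {
  gen <- flatPhantom(halfLife = 4 * 60, seed = 10)
  n <- projCounts(gen$simEvents, 120)
  # step k of head 1 and head 2 see the same decayed activity
  r <- n[61:120] / n[1:60]
  expect_lt(abs(mean(r) - 1), 0.1)
})

test_that("point-source counts are multinomial under the blurred Gaussian", {
  img <- generatePointSource(totalCounts = 500000, seed = 3)
  expect_identical(sum(img), 500000L)
  # effective FWHM adds collimator and intrinsic blur in quadrature
  expect_equal(sqrt(9.63^2 + 3.2^2), 10.1478, tolerance = 1e-4)
  # zero blur concentrates everything in one pixel (source placed at a
  # pixel centre so no mass sits on a pixel boundary)
  tiny <- generatePointSource(positionMm = c(2.1289, 2.1289),
                              collimatorFwhmMm = 1e-9,
                              model = digitiserModel(spatialFwhmMm = 1e-9),
                              totalCounts = 1000, seed = 4)
  expect_equal(max(tiny), 1000L)
  expect_error(generatePointSource(positionMm = c(1e4, 0)),
               "field of view")
})

test_that("background generators are Poisson in rate times duration", {
  edges <- seq(0, 100, 2)
  rate <- energySpectrum(edges, rep(1, 50), 1)
  bg <- generateBackgroundSpectrum(rate, 3600, seed = 2)
  expect_true(all(abs(specCounts(bg) - 3600) < 5 * sqrt(3600)))
  # doubling the duration doubles the expected totals
  bg2 <- generateBackgroundSpectrum(rate, 7200, seed = 3)
  expect_lt(abs(sum(specCounts(bg2)) - 2 * sum(specCounts(bg))),
            5 * sqrt(2 * 7200 * 50))
  # zero rates give an empty spectrum
  zero <- generateBackgroundSpectrum(energySpectrum(edges, rep(0, 50), 1),
                                     3600, seed = 2)
  expect_equal(sum(specCounts(zero)), 0)
  tmpl <- projectionStack(array(0L, c(4, 16, 16)), nHeads = 2L,
                          projectionsPerHead = 2L, timePerProjectionS = 100)
  st <- generateBackgroundStack(tmpl, 0.5, seed = 6)
  tot <- sum(as.numeric(pixelData(st)))
  expect_lt(abs(tot - 0.5 * 100 * 4 * 256), 5 * sqrt(0.5 * 100 * 4 * 256))
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- flatPhantom(seed = 11, sens = 1, pph = 10L)
  b <- flatPhantom(seed = 11, sens = 1, pph = 10L)
  expect_identical(eventData(a$simEvents), eventData(b$simEvents))
  expect_identical(generatePointSource(seed = 5),
                   generatePointSource(seed = 5))
})
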
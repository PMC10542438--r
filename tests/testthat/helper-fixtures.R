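# Shared fixtures, all built in code.

# ground-truth efficiency-ratio curve used throughout the synthetic tests
truthCurve <- function(e) evaluateCorrection(referenceCorrection(), e)

# a small valid event table
makeEventsDF <- function(n = 10, nproj = 4, duration = 100, seed = 1) {
  withr::with_seed(seed, data.frame(
    energy_keV = runif(n, 50, 400),
    x_mm = runif(n, -200, 200),
    y_mm = runif(n, -200, 200),
    projection_index = sample(0:(nproj - 1), n, replace = TRUE),
    time_s = runif(n, 0, duration)))
}

# paired synthetic calibration acquisitions -> efficiency-ratio points,
# emulating the reference calibration campaign with a known truth curve
makeCalibrationRatios <- function(seed, simEff = 0.9) {
  model <- digitiserModel()
  lines <- refCalibrationLines()
  expPts <- list(); simPts <- list()
  for (iso in unique(lines$isotope)) {
    li <- lines[lines$isotope == iso, ]
    act <- vu(li$activity_kBq[1], li$activity_sigma[1])
    expAcq <- generateCalibrationAcquisition(
      iso, li, act, function(e) pmin(truthCurve(e) * simEff, 1), model,
      liveTimeS = li$live_time_s[1], seed = seed)
    simAcq <- generateCalibrationAcquisition(
      iso, li, act, function(e) rep(simEff, length(e)), model,
      liveTimeS = li$live_time_s[1], seed = seed + 1000L)
    expPts <- c(expPts, lapply(expAcq, calibrationEfficiency, model = model))
    simPts <- c(simPts, lapply(simAcq, calibrationEfficiency, model = model))
  }
  correctionRatios(expPts, simPts)
}

# small fast pipeline config derived from the bundled demo
smallDemoConfig <- function(seed = 42) {
  cfg <- readRunConfig(system.file("extdata", "demo_config.yaml",
                                   package = "spectval"))
  cfg$seed <- seed
  cfg$synth$calibration$n_refits <- 300
  cfg$synth$phantom$projections_per_head <- 30
  cfg$synth$phantom$matrix <- 64
  cfg$synth$phantom$sensitivity_counts_per_MBq_s <- 0.5
  cfg$synth$pointsource$total_counts <- 100000
  cfg
}
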
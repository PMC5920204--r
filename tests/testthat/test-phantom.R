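cfg <- DopplerConfig()

test_that("validation velocity grid matches the protocol", {
  g <- validationVelocityGrid()
  expect_length(g, 18)
  expect_equal(g[1], 51e-6)
  expect_equal(g[18], 400e-3)
  expect_true(all(diff(g) > 0) && all(g > 0))
})

test_that("noise calibration hits the pair-stability target and partitions", {
  cal <- calibrateNoise(0.096, cfg, snr_db = 40)
  expect_equal(cal@additive_pair_rad, 0.01)
  ## partition recombines to the target
  expect_equal(sqrt(cal@phase_jitter_rad^2 + cal@additive_pair_rad^2), 0.096)
  ## attenuation by 10 dB scales everything by sqrt(10)
  low <- attenuate(cal, 10)
  expect_equal(low@snr_db, 30)
  expect_equal(low@phase_jitter_rad, cal@phase_jitter_rad * sqrt(10))
  expect_error(calibrateNoise(0, cfg), "noiseless")
  expect_error(calibrateNoise(0.096, cfg, snr_db = 10), "unreachable")
})

test_that("simulated static scans reproduce the 0.096-rad phase stability", {
  ## >= 1e5 adjacent pairs on the static reference band
  spec <- smallPhantom(v = 0, n_alines = 12000L, n_depth = 128L, seed = 31)
  scan <- simulateMScan(spec, cfg)
  band <- phantomRegions(spec)$static_band
  expect_gte(length(band) * (nrow(samples(scan)) - 1), 1e5)
  s <- measurePhaseStability(scan, band)
  expect_equal(s, 0.096, tolerance = 0.05)
  ## in [0.091, 0.101]
  expect_gt(s, 0.091); expect_lt(s, 0.101)
})

test_that("a 10-fold SNR reduction inflates the pair phase std by sqrt(10)", {
  cal <- calibrateNoise(0.096, cfg, snr_db = 40)
  sds <- sapply(list(cal, attenuate(cal, 10)), function(cc) {
    spec <- applyCalibration(
      PhantomSpec(axial_velocity_mps = 0, n_alines = 8000L, n_depth = 64L,
                  depth_pitch_m = 8e-6, seed = 32), cc)
    measurePhaseStability(simulateMScan(spec, cfg),
                          phantomRegions(spec)$static_band)
  })
  expect_equal(sds[2] / sds[1], sqrt(10), tolerance = 0.10)
})

test_that("empirical SNR matches the configured value within 0.5 dB", {
  for (snr in c(40, 30)) {
    spec <- smallPhantom(v = 0, snr_db = snr, n_alines = 4000L,
                         n_depth = 64L, seed = 33)
    scan <- simulateMScan(spec, cfg)
    reg <- phantomRegions(spec)
    noise_px <- setdiff(seq_len(64), c(reg$tube, reg$static_band))
    est <- estimateSNR(scan, reg$static_band, noise_px)
    expect_equal(est, snr, tolerance = 0.5 / snr)
  }
})

test_that("simulation is bit-reproducible under a fixed seed", {
  s1 <- simulateMScan(smallPhantom(v = 0.01, seed = 34, n_alines = 512L), cfg)
  s2 <- simulateMScan(smallPhantom(v = 0.01, seed = 34, n_alines = 512L), cfg)
  expect_identical(samples(s1), samples(s2))
  s3 <- simulateMScan(smallPhantom(v = 0.01, seed = 35, n_alines = 512L), cfg)
  expect_false(identical(samples(s1), samples(s3)))
  expect_error(simulateMScan(PhantomSpec(axial_velocity_mps = 0.01), cfg),
               "seed")
})

test_that("parabolic profile follows v(r) = v_peak (1 - (r/R)^2)", {
  ## quiet phantom (high SNR) so per-pixel means are tight
  spec <- smallPhantom(v = 0.05, snr_db = 70, n_alines = 4096L,
                       n_depth = 64L, seed = 36)
  scan <- simulateMScan(spec, cfg)
  reg <- phantomRegions(spec)
  vm <- dopplerImage(scan, EstimatorSpec("complex_regression", 64),
                     config = cfg, depths = reg$tube)
  prof <- colMeans(axialVelocity(vm))
  ## test-side geometry oracle
  z_c <- (spec@n_depth + 1) / 2
  r <- abs(reg$tube - z_c) * spec@depth_pitch_m *
    sin(spec@doppler_angle_deg * pi / 180)
  expected <- 0.05 * (1 - (r / (spec@tube_inner_diameter_m / 2))^2)
  inner <- expected > 0.2 * 0.05   # clear of the wall, where SNR is decent
  expect_equal(prof[inner], expected[inner], tolerance = 0.05)
  ## centerline / off-center ratio matches the closed form
  j <- which(reg$tube == reg$centerline)
  k <- j - 12
  expect_equal(prof[j] / prof[k], expected[j] / expected[k],
               tolerance = 0.05)
})

test_that("simulate-then-estimate round trip recovers velocity within 2%", {
  for (v in c(1e-3, 20e-3, 300e-3)) {
    spec <- smallPhantom(v = v, snr_db = 70, n_alines = 4096L, seed = 37)
    scan <- simulateMScan(spec, cfg)
    z <- phantomRegions(spec)$centerline
    vm <- dopplerImage(scan, EstimatorSpec("complex_regression", 64),
                       config = cfg, depths = z)
    expect_equal(mean(axialVelocity(vm)), v, tolerance = 0.02)
  }
})

test_that("degenerate and boundary phantoms behave as the model predicts", {
  ## zero velocity, zero jitter, essentially noiseless: estimators return 0
  quiet <- PhantomSpec(axial_velocity_mps = 0, n_alines = 256L,
                       n_depth = 64L, depth_pitch_m = 8e-6, snr_db = 180,
                       phase_jitter_rad = 0, amplitude_cv = 0, seed = 38)
  scan <- simulateMScan(quiet, cfg)
  z <- phantomRegions(quiet)$centerline
  expect_equal(thetaRad(complexRegressionPhase(samples(scan)[1:64, z])), 0)
  expect_lt(abs(kasaiPhase(samples(scan)[1:64, z])), 1e-8)

  ## theta = pi in a uniform profile: adjacent samples alternate sign
  ## (parabolic would shift the centerline pixel off the exact peak)
  v_pi <- phaseToVelocity(pi, cfg)
  alt <- PhantomSpec(axial_velocity_mps = v_pi, n_alines = 64L,
                     n_depth = 64L, depth_pitch_m = 8e-6, snr_db = 180,
                     profile = "uniform",
                     phase_jitter_rad = 0, amplitude_cv = 0, seed = 39)
  s <- samples(simulateMScan(alt, cfg))[, phantomRegions(alt)$centerline]
  expect_equal(s[2] / s[1], -1 + 0i, tolerance = 1e-6)
  expect_equal(abs(kasaiPhase(s)), pi, tolerance = 1e-6)

  ## beyond the wrap bound: warn but still generate
  fast <- PhantomSpec(axial_velocity_mps = 0.45, n_alines = 64L,
                      n_depth = 64L, depth_pitch_m = 8e-6, seed = 40)
  expect_warning(simulateMScan(fast, cfg), "wrap")
})
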
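cfg <- DopplerConfig()

test_that("kasaiPhase is the argument of the lag-one autocorrelation sum", {
  expect_equal(kasaiPhase(c(1 + 0i, 1i)), pi / 2)
  ## constant rotation, any length
  for (m in c(2, 5, 64))
    expect_equal(kasaiPhase(toneWindow(m, 0.1)), 0.1, tolerance = 1e-12)
  ## amplitude weighting: a window whose lag-one products are 4 e^{i0.2}
  ## and 1 e^{i0.4} estimates arg(4 e^{i0.2} + e^{i0.4}) = 0.2398718
  ## (frozen direct complex-sum oracle), pulled toward the stronger pair
  w <- c(2 * exp(0i), 2 * exp(0.2i), 0.5 * exp(0.6i))
  expect_equal(kasaiPhase(w), 0.2398718, tolerance = 1e-6)
  expect_error(kasaiPhase(c(0i, 0i, 0i)), "zero")
  expect_error(kasaiPhase(1 + 0i), "2 points")
})

test_that("realign derotates by increasing multiples and preserves moduli", {
  w <- toneWindow(8, 0.31, amp = c(1, 2, 3, 4, 4, 3, 2, 1))
  expect_equal(realign(w, 0), w)
  aligned <- realign(toneWindow(16, 0.77), 0.77)
  expect_equal(aligned, rep(1 + 0i, 16), tolerance = 1e-12)
  withr::with_seed(5, {
    for (i in 1:20) {
      v <- complex(real = rnorm(12), imaginary = rnorm(12))
      th <- runif(1, -pi, pi)
      expect_equal(Mod(realign(v, th)), Mod(v), tolerance = 1e-14)
    }
  })
})

test_that("complexDispersion uses the population convention", {
  expect_equal(complexDispersion(rep(3 - 2i, 7)), 0)
  expect_equal(complexDispersion(c(1 + 0i, -1 + 0i)), 1)
  ## algebraic identity: sd^2 = mean|z|^2 - |mean z|^2
  withr::with_seed(6, {
    for (i in 1:20) {
      z <- complex(real = rnorm(9), imaginary = rnorm(9))
      expect_equal(complexDispersion(z)^2,
                   mean(Mod(z)^2) - Mod(mean(z))^2, tolerance = 1e-12)
    }
  })
})

test_that("complex regression recovers noiseless tones exactly on the grid", {
  est <- complexRegressionPhase(toneWindow(64, 0.100))
  expect_equal(thetaRad(est), 0.100, tolerance = 1e-9)
  expect_equal(deltaPhiRad(est), 6.300, tolerance = 1e-7)
  expect_equal(dispersion(est), 0, tolerance = 1e-7)
  expect_identical(nPoints(est), 64L)

  ## amplitude fluctuations do not bias the noiseless estimate
  withr::with_seed(7, {
    amps <- runif(64, 0.2, 3)
    est2 <- complexRegressionPhase(toneWindow(64, 0.250, amp = amps))
    expect_equal(thetaRad(est2), 0.250, tolerance = 1e-9)
  })

  ## static window: zero phase wins the tie over the full circle
  expect_equal(thetaRad(complexRegressionPhase(rep(1 + 2i, 16))), 0)
  ## real-valued window: the objective is symmetric in theta (the two
  ## spectral peaks interfere, so the maximum sits near but not at 0.3);
  ## the +/- tie is broken toward negative theta
  est3 <- complexRegressionPhase(cos(0.3 * (0:31)) + 0i)
  expect_lt(thetaRad(est3), 0)
  expect_equal(abs(thetaRad(est3)), 0.3, tolerance = 0.1)
  w_real <- cos(0.3 * (0:31)) + 0i
  expect_equal(complexDispersion(realign(w_real, thetaRad(est3))),
               complexDispersion(realign(w_real, -thetaRad(est3))),
               tolerance = 1e-12)
  expect_error(complexRegressionPhase(rep(0i, 8)), "zero")
})

test_that("total phase shift up to 63 pi is recovered without wrapping", {
  ## per-interval theta close to +/- pi: delta_phi = 63 theta far exceeds 2 pi
  for (th in c(3.141, -3.141, 2.5, -1.337)) {
    est <- complexRegressionPhase(toneWindow(64, th))
    expect_equal(thetaRad(est), th, tolerance = 1e-9)
    expect_equal(deltaPhiRad(est), 63 * th, tolerance = 1e-7)
  }
  ## off-grid tone: exact to grid resolution
  est <- complexRegressionPhase(toneWindow(64, 3.0004))
  expect_lt(abs(thetaRad(est) - 3.0004), 1e-3)
})

test_that("dispersion minimization equals coherent-sum maximization", {
  ## brute-force dispersion search (contract definition) against the
  ## coherent-sum fast path, on noisy and amplitude-modulated windows
  withr::with_seed(8, {
    for (i in 1:5) {
      w <- toneWindow(16, runif(1, -3, 3), amp = runif(16, 0.3, 2)) +
        0.2 * complex(real = rnorm(16), imaginary = rnorm(16))
      oracle <- bruteRegression(w)
      fast <- complexRegressionPhase(w)
      expect_identical(thetaRad(fast), oracle$theta)
      expect_equal(dispersion(fast), oracle$dispersion, tolerance = 1e-9)
    }
  })
})

test_that("regression agrees with the periodogram peak within one grid step", {
  withr::with_seed(9, {
    for (th0 in c(-2.71828, -0.08237, 0.00791, 1.23456)) {
      w <- noisyToneWindows(64, 1, th0, snr_lin = 10^(30 / 10))[, 1]
      expect_lt(abs(thetaRad(complexRegressionPhase(w)) - periodogramPeak(w)),
                1e-3 + 1e-9)
    }
  })
})

test_that("conventionalDoppler averages the first N pairs of a window", {
  scan <- MScan(cbind(toneWindow(200, 0.05)), 594e-9)
  est <- conventionalDoppler(scan, depth = 1, window_start = 1,
                             n_averages = 5)
  expect_equal(thetaRad(est), 0.05, tolerance = 1e-12)
  ## single-interval semantics
  expect_equal(deltaPhiRad(est), thetaRad(est))
  expect_identical(nPoints(est), 6L)
  expect_error(conventionalDoppler(scan, 1, window_start = 150,
                                   n_averages = 63), "bounds")
})

test_that("kasai and regression agree on high-SNR windows", {
  withr::with_seed(10, {
    for (th in c(0.1, 0.45, 1.2)) {
      w <- noisyToneWindows(64, 1, th, snr_lin = 10^(35 / 10))[, 1]
      k <- kasaiPhase(w)
      r <- thetaRad(complexRegressionPhase(w))
      expect_lt(abs(k - r), 2e-3)
    }
  })
})

test_that("N-average error follows 1/sqrt(N) under accumulating phase noise", {
  ## Long static phantom scan: the phase instability is a random walk, so
  ## adjacent-pair phases are i.i.d. across the scan and averaging N pairs
  ## reduces the error by 1/sqrt(N). Monte-Carlo over 3000 windows.
  spec <- smallPhantom(v = 0, snr_db = 60, n_alines = 64L * 3000L,
                       n_depth = 16L, seed = 21, amplitude_cv = 0)
  scan <- simulateMScan(spec, cfg)
  z <- phantomRegions(spec)$centerline
  s <- samples(scan)[, z]
  pair_sd <- sd(Arg(s[-1] * Conj(s[-length(s)])))     # N = 1 oracle
  sd5 <- sd(axialVelocity(dopplerImage(scan, EstimatorSpec("conventional_avg", 5),
                                       config = cfg, depths = z)))
  sd63 <- sd(axialVelocity(dopplerImage(scan, EstimatorSpec("conventional_avg", 63),
                                        config = cfg, depths = z)))
  pair_sd_v <- phaseToVelocity(pair_sd, cfg)
  expect_equal(sd5 / pair_sd_v, 1 / sqrt(5), tolerance = 0.10)
  expect_equal(sd63 / pair_sd_v, 1 / sqrt(63), tolerance = 0.10)
})

test_that("RMSE ordering regression < N63 < N5 under matched additive noise", {
  ## slow flow (theta below 0.02 rad) with SNR-limited additive noise only
  th <- 0.007
  withr::with_seed(22, {
    S <- noisyToneWindows(64L * 400L, 1, th, snr_lin = 100)
  })
  scan <- MScan(S, 594e-9)
  rmse <- sapply(defaultEstimators(), function(est) {
    v <- axialVelocity(dopplerImage(scan, est, config = cfg))
    sqrt(mean((v - phaseToVelocity(th, cfg))^2))
  })
  expect_lt(rmse[["cmpreg"]], rmse[["cnv63"]])
  expect_lt(rmse[["cnv63"]], rmse[["cnv5"]])
})

test_that("dopplerImage windows the scan as acquired", {
  ## 16,000 A-lines in non-overlapping 64-point windows -> 250 windows
  scan <- MScan(cbind(toneWindow(16000, 0.2)), 594e-9)
  vm <- dopplerImage(scan, EstimatorSpec("conventional_avg", 5), config = cfg)
  expect_identical(nrow(axialVelocity(vm)), 250L)
  expect_identical(windowStarts(vm), as.integer(seq(1, 15937, by = 64)))
  ## uniform rotation -> constant map at the converted velocity
  expect_equal(max(abs(axialVelocity(vm) - phaseToVelocity(0.2, cfg))), 0,
               tolerance = 1e-12)

  ## zero-velocity noiseless scan -> all-zero map (both estimators)
  static <- MScan(matrix(2 - 1i, 128, 3), 594e-9)
  for (est in list(EstimatorSpec("conventional_avg", 5),
                   EstimatorSpec("complex_regression", 64)))
    expect_true(all(axialVelocity(dopplerImage(static, est,
                                               config = cfg)) == 0))

  ## configurable stride
  vm2 <- dopplerImage(MScan(cbind(toneWindow(128, 0.1)), 594e-9),
                      EstimatorSpec("conventional_avg", 5),
                      window_length = 64, stride = 32, config = cfg)
  expect_identical(windowStarts(vm2), c(1L, 33L, 65L))

  expect_error(dopplerImage(static, EstimatorSpec("conventional_avg", 5),
                            window_length = 256, config = cfg), "exceeds")
  expect_error(dopplerImage(static, EstimatorSpec("complex_regression", 32),
                            window_length = 64, config = cfg), "n_points")
})

test_that("angle-corrected map divides by cos(Doppler angle)", {
  scan <- MScan(cbind(toneWindow(128, 0.3)), 594e-9)
  vm <- dopplerImage(scan, EstimatorSpec("conventional_avg", 5), config = cfg)
  expect_equal(absoluteVelocity(vm),
               axialVelocity(vm) / cos(80 * pi / 180))
})

test_that("complexAverage averages groups in the complex domain", {
  w <- rep(0.3 + 0.4i, 12)
  expect_equal(complexAverage(w, 4), rep(0.3 + 0.4i, 3))
  ## destructive interference of opposite phases
  expect_equal(complexAverage(c(exp(0i), exp(1i * pi)), 2), 0 + 0i,
               tolerance = 1e-15)
  expect_message(complexAverage(matrix(1 + 0i, 10, 2), 4), "dropping 2")
  expect_error(complexAverage(w, 0), ">= 1")

  ## residual noise power ~ 1/n after n-fold complex averaging
  withr::with_seed(23, {
    n <- 16L
    noise <- matrix(complex(real = rnorm(4096 * 8), imaginary = rnorm(4096 * 8)),
                    4096, 8)
    sig <- matrix(5 + 0i, 4096, 8)
    avg <- complexAverage(sig + noise, n)
    p_res <- mean(Mod(avg - (5 + 0i))^2)
    expect_equal(p_res, mean(Mod(noise)^2) / n, tolerance = 0.15)
  })

  ## MScan method rescales the A-line interval
  scan <- MScan(matrix(1 + 1i, 128, 2), 594e-9)
  avg <- complexAverage(scan, 64)
  expect_identical(dim(avg), c(2L, 2L))
  expect_equal(alineInterval(avg), 594e-9 * 64)
})
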
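## Shared fixtures and independent oracles, all built in code.

## Noiseless single tone: s_k = amp_k * exp(i (phi0 + k * theta)), k = 0..m-1
toneWindow <- function(m, theta, amp = 1, phi0 = 0) {
  amp * exp(1i * (phi0 + theta * (0:(m - 1))))
}

## Tone plus i.i.d. circular complex noise at a given linear SNR
## (unit signal amplitude). Returns an m x reps matrix of windows.
noisyToneWindows <- function(m, reps, theta, snr_lin) {
  sig <- toneWindow(m, theta)
  sig + (matrix(rnorm(m * reps), m, reps) +
         1i * matrix(rnorm(m * reps), m, reps)) * sqrt(1 / (2 * snr_lin))
}

## Brute-force dispersion-minimization oracle: evaluates the contract
## definition (realign + complexDispersion) on every grid candidate with the
## documented tie-break. Independent of the coherent-sum fast path.
bruteRegression <- function(window, grid_step = 1e-3) {
  grid <- thetaGrid(grid_step)
  disp <- vapply(grid, function(th) complexDispersion(realign(window, th)),
                 numeric(1))
  idx <- which(disp == min(disp))
  if (length(idx) > 1L) {
    cand <- grid[idx]
    idx <- idx[order(abs(cand), cand)]
  }
  list(theta = grid[idx[1L]], dispersion = disp[idx[1L]])
}

## Zero-padded periodogram peak with parabolic interpolation: the classic
## single-tone frequency estimator, used as an independent oracle.
periodogramPeak <- function(window, nfft = 2^16) {
  m <- length(window)
  p <- Mod(fft(c(window, rep(0i, nfft - m))))^2
  i <- which.max(p)
  im <- if (i == 1) nfft else i - 1
  ip <- if (i == nfft) 1 else i + 1
  denom <- p[im] - 2 * p[i] + p[ip]
  delta <- if (denom != 0) 0.5 * (p[im] - p[ip]) / denom else 0
  f <- (i - 1 + delta) / nfft          # cycles per sample
  th <- 2 * pi * f
  if (th > pi) th <- th - 2 * pi       # map to (-pi, pi]
  th
}

## Scaled-down calibrated phantom template used across evaluation tests.
## Pair phase noise follows the 1/sqrt(SNR) law anchored at 0.096 rad for
## the 40-dB high-SNR condition, so quieter phantoms (snr_db > 40) have
## proportionally less phase noise.
smallPhantom <- function(v = 0, snr_db = 40, n_alines = 2000L,
                         n_depth = 64L, seed = NA_integer_, ...) {
  cal <- calibrateNoise(0.096 * 10^((40 - snr_db) / 20), snr_db = snr_db)
  applyCalibration(
    PhantomSpec(axial_velocity_mps = v, n_alines = n_alines,
                n_depth = n_depth, depth_pitch_m = 8e-6, seed = seed, ...),
    cal)
}

defaultEstimators <- function() {
  list(cnv5 = EstimatorSpec("conventional_avg", 5),
       cnv63 = EstimatorSpec("conventional_avg", 63),
       cmpreg = EstimatorSpec("complex_regression", 64))
}
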
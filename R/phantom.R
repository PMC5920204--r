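#' @include AllClasses.R core.R estimators.R
NULL

#' Calibrate phantom noise to a target adjacent-pair phase stability
#'
#' The phantom's phase noise has two SNR-limited parts: the additive complex
#' noise contributes an adjacent-pair phase standard deviation of
#' \eqn{1/\sqrt{SNR_{lin}}}, and an accumulating (random-walk) phase
#' instability contributes its per-interval increment std. The calibration
#' solves for the increment std so that the two combine to the requested
#' target at the given SNR:
#' \deqn{\sigma_w = \sqrt{\mathrm{target}^2 - 1/SNR_{lin}}.}
#' Both parts scale with \eqn{1/\sqrt{SNR}}, so attenuating the sample power
#' (see [attenuate()]) inflates the pair phase std by exactly the square root
#' of the linear SNR reduction.
#'
#' @param target_phase_stability_rad Target adjacent-pair phase std (rad),
#'   positive.
#' @param config A [DopplerConfig-class] (its `phase_stability_rad` is the
#'   usual source of the target).
#' @param snr_db SNR (dB) at which the target must be met.
#' @return A [NoiseCalibration-class].
#' @examples
#' cal <- calibrateNoise(0.096, snr_db = 40)
#' cal
#' attenuate(cal, 10)   # 10-dB sample-power cut: pair std x sqrt(10)
#' @export
calibrateNoise <- function(target_phase_stability_rad = NULL,
                           config = DopplerConfig(), snr_db = 40) {
  if (is.null(target_phase_stability_rad))
    target_phase_stability_rad <- config@phase_stability_rad
  target <- target_phase_stability_rad
  if (length(target) != 1L || !is.finite(target) || target <= 0)
    stop("noiseless systems need no calibration: target must be > 0")
  additive <- sqrt(10^(-snr_db / 10))
  if (additive >= target)
    stop(sprintf(
      "unreachable target: additive phase noise at %.1f dB SNR (%.4g rad) already exceeds %.4g rad",
      snr_db, additive, target))
  new("NoiseCalibration",
      target_rad = target,
      snr_db = snr_db,
      phase_jitter_rad = sqrt(target^2 - additive^2),
      additive_pair_rad = additive)
}

#' Attenuate a calibrated noise condition
#'
#' Models inserting a neutral-density filter in the sample arm: the linear
#' SNR drops by `10^(db/10)` and, since both noise terms are SNR-limited,
#' the adjacent-pair phase std inflates by `10^(db/20)`.
#'
#' @param cal A [NoiseCalibration-class].
#' @param db SNR reduction in dB (>= 0); 10 dB corresponds to the 10-fold
#'   SNR cut of the low-SNR condition.
#' @return A new [NoiseCalibration-class].
#' @export
attenuate <- function(cal, db) {
  stopifnot(is(cal, "NoiseCalibration"), db >= 0)
  calibrateNoise(cal@target_rad * 10^(db / 20), snr_db = cal@snr_db - db)
}

#' Apply a noise calibration to a phantom specification
#'
#' @param spec A [PhantomSpec-class].
#' @param cal A [NoiseCalibration-class].
#' @return `spec` with `snr_db` and `phase_jitter_rad` taken from `cal`.
#' @export
applyCalibration <- function(spec, cal) {
  stopifnot(is(spec, "PhantomSpec"), is(cal, "NoiseCalibration"))
  spec@snr_db <- cal@snr_db
  spec@phase_jitter_rad <- cal@phase_jitter_rad
  validObject(spec)
  spec
}

## Depth geometry of the phantom: perpendicular distance of each depth pixel
## from the tube axis, the in-tube mask, and a static reference band above
## the tube (a strong static reflector used for phase-stability measurement).
.phantomGeometry <- function(spec) {
  z <- seq_len(spec@n_depth)
  z_c <- (spec@n_depth + 1) / 2
  sin_a <- sin(spec@doppler_angle_deg * pi / 180)
  if (sin_a == 0) sin_a <- 1  # beam along the tube axis: treat depth as radius
  r_perp <- abs(z - z_c) * spec@depth_pitch_m * sin_a
  R <- spec@tube_inner_diameter_m / 2
  in_tube <- r_perp < R
  first_tube <- if (any(in_tube)) which(in_tube)[1L] else spec@n_depth + 1L
  n_static <- min(max(2L, as.integer(round(0.08 * spec@n_depth))),
                  first_tube - 2L)
  if (n_static < 1L) n_static <- 0L
  list(r_perp = r_perp, R = R, in_tube = in_tube,
       static_band = seq_len(n_static))
}

#' Depth-pixel regions of a phantom
#'
#' Returns the 1-based depth indices of the tube cross-section and of the
#' static reference band for a given [PhantomSpec-class]; used by the
#' evaluation protocol to restrict peak extraction to the tube.
#'
#' @param spec A [PhantomSpec-class].
#' @return List with elements `tube` (depth indices inside the tube),
#'   `static_band`, and `centerline` (depth pixel nearest the tube axis).
#' @export
phantomRegions <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  geo <- .phantomGeometry(spec)
  tube <- which(geo$in_tube)
  list(tube = tube,
       static_band = geo$static_band,
       centerline = tube[which.min(geo$r_perp[tube])])
}

## Smoothed unit-variance Gaussian process of length T with correlation
## length L (in samples); independent per column for ncol columns.
.smoothedGaussian <- function(T, ncol, L) {
  X <- matrix(stats::rnorm(T * ncol), T, ncol)
  if (L <= 1) return(X)
  half <- min(ceiling(4 * L), T - 1L)
  k <- stats::dnorm(seq(-half, half), sd = L)
  k <- k / sqrt(sum(k^2))  # unit output variance
  nf <- stats::nextn(T + length(k))
  K <- stats::fft(c(k, numeric(nf - length(k))))
  pad <- rbind(X, matrix(0, nf - T, ncol))
  Y <- Re(stats::mvfft(stats::mvfft(pad) * K, inverse = TRUE)) / nf
  Y[(half + 1L):(half + T), , drop = FALSE]
}

#' Simulate a flow-phantom M-scan
#'
#' Generates a complex scan according to the phantom signal model. For depth
#' pixel z inside the tube,
#' \deqn{s_t(z) = A_t(z)\,e^{i[\varphi_0(z) + t\,\theta(z) + \epsilon_t]} + \eta_t(z),}
#' where \eqn{\theta(z) = 4\pi n \Delta T v_{ax}(z)/\lambda_0} follows the
#' chosen radial velocity profile (parabolic:
#' \eqn{v_{peak}(1 - (r/R)^2)}), \eqn{\epsilon_t} is an accumulating
#' (random-walk) phase instability shared across depth, \eqn{A_t} is a slow
#' multiplicative amplitude fluctuation with the requested coefficient of
#' variation (correlation length = beam-spot transit time, floor 3 A-lines)
#' on top of a mild radial amplitude taper that peaks on the tube axis, and
#' \eqn{\eta_t} is i.i.d. circular complex noise sized so that the
#' profile-peak signal power over the total complex noise power equals the
#' linear SNR. Pixels above the tube form a static reference band (unit
#' amplitude, constant phase); remaining out-of-tube pixels contain noise
#' only.
#'
#' A warning is raised when the center per-interval phase exceeds pi in
#' magnitude (adjacent-pair wrap regime); the scan is still generated.
#'
#' @param spec A [PhantomSpec-class]; its `seed` must be set.
#' @param config A [DopplerConfig-class].
#' @param beam_spot_m Beam spot diameter (m) used for the transit
#'   correlation length of the amplitude fluctuation.
#' @return An [MScan-class] of `n_alines` x `n_depth` samples.
#' @export
simulateMScan <- function(spec, config = DopplerConfig(),
                          beam_spot_m = 15e-6) {
  stopifnot(is(spec, "PhantomSpec"), is(config, "DopplerConfig"))
  if (is.na(spec@seed))
    stop("'spec@seed' must be set: all stochastic generation is seeded")
  geo <- .phantomGeometry(spec)
  T <- spec@n_alines
  Z <- spec@n_depth
  tube <- which(geo$in_tube)
  u2 <- (geo$r_perp[tube] / geo$R)^2
  v_ax <- if (spec@profile == "parabolic") {
    spec@axial_velocity_mps * (1 - u2)
  } else {
    rep(spec@axial_velocity_mps, length(tube))
  }
  theta <- velocityToPhase(v_ax, config)
  if (length(theta) && max(abs(theta)) > pi)
    warning(sprintf(
      "per-interval phase at tube center is %.3f rad (> pi): adjacent-pair wrap regime",
      max(abs(theta))))

  withr::with_seed(spec@seed, {
    S <- matrix(0i, T, Z)
    ## additive noise everywhere (defines the SNR at the unit-amplitude peak)
    sigma_n <- sqrt(10^(-spec@snr_db / 10) / 2)
    S[] <- (stats::rnorm(T * Z) + 1i * stats::rnorm(T * Z)) * sigma_n
    ## accumulating phase instability, common to all depths of an A-line
    eps <- if (spec@phase_jitter_rad > 0)
      cumsum(stats::rnorm(T, 0, spec@phase_jitter_rad)) else numeric(T)
    ## static reference band: unit amplitude, constant random phase
    if (length(geo$static_band)) {
      phi0 <- stats::runif(length(geo$static_band), -pi, pi)
      S[, geo$static_band] <- S[, geo$static_band] +
        exp(1i * outer(eps, phi0, `+`))
    }
    ## tube interior
    if (length(tube)) {
      phi0 <- stats::runif(length(tube), -pi, pi)
      A0 <- 1 - 0.3 * u2  # radial taper so the profile peak is the centerline
      phase <- outer(seq_len(T) - 1L, theta) + outer(eps, phi0, `+`)
      A <- matrix(rep(A0, each = T), T, length(tube))
      if (spec@amplitude_cv > 0) {
        v_abs <- angleCorrect(abs(spec@axial_velocity_mps),
                              spec@doppler_angle_deg)
        L <- if (v_abs > 0)
          max(3, beam_spot_m / v_abs / config@aline_interval_s) else Inf
        if (is.finite(L) && L < T) {
          G <- .smoothedGaussian(T, length(tube), L)
          A <- A * pmax(1 + spec@amplitude_cv * G, 0.05)
        }
      }
      S[, tube] <- S[, tube] + A * exp(1i * phase)
    }
    MScan(S, config@aline_interval_s)
  })
}

#' Measure the adjacent-pair phase stability of a scan
#'
#' Computes the Kasai phase of every adjacent A-line pair at the selected
#' depth pixels and returns the standard deviation — the empirical
#' counterpart of the configured phase stability when applied to a static
#' sample.
#'
#' @param mscan An [MScan-class].
#' @param depths Depth pixels to use (default: all).
#' @return Standard deviation of the pairwise phases (rad).
#' @export
measurePhaseStability <- function(mscan, depths = NULL) {
  stopifnot(is(mscan, "MScan"))
  S <- mscan@samples
  if (is.null(depths)) depths <- seq_len(ncol(S))
  T <- nrow(S)
  ph <- Arg(S[2:T, depths, drop = FALSE] * Conj(S[1:(T - 1), depths,
                                                  drop = FALSE]))
  stats::sd(as.vector(ph))
}

#' Empirical SNR of a simulated scan
#'
#' Signal power is the noise-corrected mean power at the signal depths;
#' noise power is the mean power at noise-only depths.
#'
#' @param mscan An [MScan-class].
#' @param signal_depths Depth pixels containing signal.
#' @param noise_depths Depth pixels containing noise only.
#' @return Estimated SNR in dB.
#' @export
estimateSNR <- function(mscan, signal_depths, noise_depths) {
  stopifnot(is(mscan, "MScan"))
  S <- mscan@samples
  p_sig <- mean(Mod(S[, signal_depths, drop = FALSE])^2)
  p_noise <- mean(Mod(S[, noise_depths, drop = FALSE])^2)
  10 * log10((p_sig - p_noise) / p_noise)
}

#' Test-grid of validation velocities
#'
#' The 18 axial velocities of the flow-phantom validation protocol, evenly
#' spread on a logarithmic scale from 51 um/s to 400 mm/s.
#'
#' @return Numeric vector of 18 strictly increasing axial speeds (m/s).
#' @examples
#' validationVelocityGrid() * 1e3   # mm/s
#' @export
validationVelocityGrid <- function() {
  c(51e-6, 84e-6, 138e-6, 374e-6, 616e-6,
    1.01e-3, 1.66e-3, 2.74e-3, 4.51e-3, 7.43e-3, 12.23e-3, 20.13e-3,
    33.13e-3, 54.53e-3, 89.74e-3, 147.69e-3, 243.05e-3, 400e-3)
}
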
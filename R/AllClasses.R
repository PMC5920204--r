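#' @import methods
NULL

## ---------------------------------------------------------------------------
## DopplerConfig
## ---------------------------------------------------------------------------

#' Acquisition and system configuration for Doppler OCT processing
#'
#' Holds the physical constants needed to convert phase shifts into
#' velocities: center wavelength \eqn{\lambda_0}, sample refractive index
#' \eqn{n}, the time interval \eqn{\Delta T} between adjacent A-lines, the
#' Doppler angle between the flow axis and the imaging beam, and the
#' phase-stability floor of the system (the standard deviation of the measured
#' adjacent-pair phase on a static sample, which sets the minimum resolvable
#' phase shift).
#'
#' @slot center_wavelength_m numeric(1), center wavelength in meters.
#' @slot refractive_index numeric(1), sample refractive index (dimensionless).
#' @slot aline_interval_s numeric(1), time between adjacent A-lines in seconds.
#' @slot doppler_angle_deg numeric(1), angle between flow axis and beam in
#'   degrees; must lie in \[0, 90).
#' @slot phase_stability_rad numeric(1), minimum resolvable adjacent-pair
#'   phase in radians; must be positive and below \eqn{\pi}.
#'
#' @seealso [DopplerConfig()], [phaseToVelocity()], [conventionalRange()]
#' @exportClass DopplerConfig
setClass("DopplerConfig",
  representation(
    center_wavelength_m = "numeric",
    refractive_index = "numeric",
    aline_interval_s = "numeric",
    doppler_angle_deg = "numeric",
    phase_stability_rad = "numeric"
  )
)

setValidity("DopplerConfig", function(object) {
  msgs <- character()
  for (sl in c("center_wavelength_m", "refractive_index", "aline_interval_s",
               "phase_stability_rad")) {
    v <- slot(object, sl)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msgs <- c(msgs, sprintf("'%s' must be a single positive finite number", sl))
  }
  a <- object@doppler_angle_deg
  if (length(a) != 1L || !is.finite(a) || a < 0 || a >= 90)
    msgs <- c(msgs, "'doppler_angle_deg' must lie in [0, 90)")
  p <- object@phase_stability_rad
  if (length(p) == 1L && is.finite(p) && p >= pi)
    msgs <- c(msgs, "'phase_stability_rad' must be below pi")
  if (length(msgs)) msgs else TRUE
})

#' Construct a DopplerConfig
#'
#' Defaults correspond to a 1.68-MHz swept-source system imaging lipid
#' solution: \eqn{\lambda_0 = 1315} nm, \eqn{n = 1.38},
#' \eqn{\Delta T = 594} ns, Doppler angle 80 degrees and a phase stability of
#' 0.096 rad.
#'
#' @param center_wavelength_m Center wavelength (m).
#' @param refractive_index Sample refractive index.
#' @param aline_interval_s Adjacent A-line interval (s).
#' @param doppler_angle_deg Doppler angle (degrees), in \[0, 90).
#' @param phase_stability_rad Adjacent-pair phase stability (rad).
#' @return A [DopplerConfig-class] object.
#' @examples
#' cfg <- DopplerConfig()
#' conventionalRange(cfg)
#' @export
DopplerConfig <- function(center_wavelength_m = 1315e-9,
                          refractive_index = 1.38,
                          aline_interval_s = 594e-9,
                          doppler_angle_deg = 80,
                          phase_stability_rad = 0.096) {
  new("DopplerConfig",
      center_wavelength_m = as.numeric(center_wavelength_m),
      refractive_index = as.numeric(refractive_index),
      aline_interval_s = as.numeric(aline_interval_s),
      doppler_angle_deg = as.numeric(doppler_angle_deg),
      phase_stability_rad = as.numeric(phase_stability_rad))
}

## ---------------------------------------------------------------------------
## VelocityRange
## ---------------------------------------------------------------------------

#' Detectable axial-velocity range
#'
#' @slot v_min numeric(1), minimum detectable axial speed (m/s).
#' @slot v_max numeric(1), maximum detectable axial speed (m/s).
#' @seealso [conventionalRange()]
#' @exportClass VelocityRange
setClass("VelocityRange",
  representation(v_min = "numeric", v_max = "numeric"))

setValidity("VelocityRange", function(object) {
  if (length(object@v_min) != 1L || length(object@v_max) != 1L)
    return("'v_min' and 'v_max' must be single numbers")
  if (!(object@v_min > 0 && object@v_max > object@v_min))
    return("must satisfy 0 < v_min < v_max")
  TRUE
})

## ---------------------------------------------------------------------------
## EstimatorSpec
## ---------------------------------------------------------------------------

.ESTIMATOR_KINDS <- c("conventional_avg", "complex_regression")

#' Specification of a Doppler phase-shift estimator
#'
#' `kind` selects either the conventional complex two-point (Kasai
#' autocorrelation) estimator averaged over `n_points` adjacent pairs, or the
#' multipoint complex-regression estimator applied to a window of `n_points`
#' A-lines.
#'
#' @slot kind character(1), one of `"conventional_avg"`, `"complex_regression"`.
#' @slot n_points integer(1), number of averaged pairs (conventional) or the
#'   regression window length m; at least 2.
#' @exportClass EstimatorSpec
setClass("EstimatorSpec",
  representation(kind = "character", n_points = "integer"))

setValidity("EstimatorSpec", function(object) {
  if (length(object@kind) != 1L || !object@kind %in% .ESTIMATOR_KINDS)
    return(sprintf("'kind' must be one of: %s",
                   paste(.ESTIMATOR_KINDS, collapse = ", ")))
  if (length(object@n_points) != 1L || is.na(object@n_points) ||
      object@n_points < 2L)
    return("'n_points' must be a single integer >= 2")
  TRUE
})

#' @rdname EstimatorSpec-class
#' @param kind Estimator kind, `"conventional_avg"` or `"complex_regression"`.
#' @param n_points Pairs averaged (conventional) or window length (regression).
#' @return An [EstimatorSpec-class] object.
#' @examples
#' EstimatorSpec("complex_regression", 64)
#' @export
EstimatorSpec <- function(kind = c("conventional_avg", "complex_regression"),
                          n_points) {
  kind <- match.arg(kind)
  new("EstimatorSpec", kind = kind, n_points = as.integer(n_points))
}

## ---------------------------------------------------------------------------
## MScan
## ---------------------------------------------------------------------------

#' Complex-valued M-scan / B-scan record
#'
#' A 2-D complex record indexed by A-line (rows, time order) and depth
#' (columns), together with the A-line interval. For B-scans an optional
#' per-A-line lateral coordinate can be attached.
#'
#' @slot samples complex matrix, A-line index x depth.
#' @slot aline_interval_s numeric(1), seconds between consecutive A-lines.
#' @slot lateral_positions numeric, per-A-line lateral coordinate in meters
#'   (length 0 for M-mode).
#' @seealso [MScan()], [dopplerImage()], [simulateMScan()]
#' @exportClass MScan
setClass("MScan",
  representation(
    samples = "matrix",
    aline_interval_s = "numeric",
    lateral_positions = "numeric"
  )
)

setValidity("MScan", function(object) {
  s <- object@samples
  if (!is.complex(s))
    return("'samples' must be a complex matrix")
  if (nrow(s) < 2L)
    return("an MScan needs at least 2 A-lines")
  if (anyNA(s) || any(!is.finite(Re(s))) || any(!is.finite(Im(s))))
    return("'samples' must be finite")
  if (length(object@aline_interval_s) != 1L || object@aline_interval_s <= 0)
    return("'aline_interval_s' must be a single positive number")
  lp <- object@lateral_positions
  if (length(lp) && length(lp) != nrow(s))
    return("'lateral_positions' must be empty or one value per A-line")
  TRUE
})

#' Construct an MScan
#'
#' @param samples Complex matrix (A-line index x depth).
#' @param aline_interval_s Interval between adjacent A-lines (s).
#' @param lateral_positions Optional per-A-line lateral coordinate (m).
#' @return An [MScan-class] object.
#' @export
MScan <- function(samples, aline_interval_s,
                  lateral_positions = numeric(0)) {
  if (!is.matrix(samples)) samples <- as.matrix(samples)
  storage.mode(samples) <- "complex"
  new("MScan", samples = samples,
      aline_interval_s = as.numeric(aline_interval_s),
      lateral_positions = as.numeric(lateral_positions))
}

## ---------------------------------------------------------------------------
## PhaseEstimate
## ---------------------------------------------------------------------------

#' Result of a per-window Doppler phase-shift estimate
#'
#' `theta_rad` is the per-interval phase (the phase accumulated over one
#' adjacent A-line interval \eqn{\Delta T}); `delta_phi_rad` is the total
#' phase shift over the window. For the complex-regression estimator
#' `delta_phi_rad = (n_points - 1) * theta_rad`; the conventional estimator
#' keeps single-interval semantics (`delta_phi_rad = theta_rad`) while
#' recording the number of A-lines used in `n_points`.
#'
#' @slot theta_rad numeric(1), per-interval phase in \[-pi, pi\].
#' @slot delta_phi_rad numeric(1), total phase shift (rad).
#' @slot dispersion numeric(1), the (minimized) standard deviation of the
#'   realigned complex points, non-negative.
#' @slot n_points integer(1), number of A-lines involved.
#' @seealso [complexRegressionPhase()], [conventionalDoppler()]
#' @exportClass PhaseEstimate
setClass("PhaseEstimate",
  representation(
    theta_rad = "numeric",
    delta_phi_rad = "numeric",
    dispersion = "numeric",
    n_points = "integer"
  )
)

setValidity("PhaseEstimate", function(object) {
  tol <- 1e-9
  if (abs(object@theta_rad) > pi + tol)
    return("'theta_rad' must lie in [-pi, pi]")
  if (object@dispersion < 0)
    return("'dispersion' must be non-negative")
  d <- object@delta_phi_rad
  multi <- (object@n_points - 1L) * object@theta_rad
  if (abs(d - multi) > tol * max(1, abs(multi)) &&
      abs(d - object@theta_rad) > tol)
    return("'delta_phi_rad' must equal theta_rad or (n_points-1)*theta_rad")
  TRUE
})

.PhaseEstimate <- function(theta, delta_phi, dispersion, n_points) {
  new("PhaseEstimate", theta_rad = theta, delta_phi_rad = delta_phi,
      dispersion = dispersion, n_points = as.integer(n_points))
}

## ---------------------------------------------------------------------------
## VelocityMap
## ---------------------------------------------------------------------------

#' Per-window, per-depth axial velocity map
#'
#' @slot axial_velocity numeric matrix (window x depth) of signed axial
#'   velocities in m/s.
#' @slot window_start_index integer, first A-line (1-based) of each window;
#'   strictly increasing.
#' @slot window_length integer(1), A-lines per window.
#' @slot estimator the [EstimatorSpec-class] that produced the map.
#' @slot config the [DopplerConfig-class] used for phase-to-velocity
#'   conversion.
#' @seealso [dopplerImage()], [absoluteVelocity()]
#' @exportClass VelocityMap
setClass("VelocityMap",
  representation(
    axial_velocity = "matrix",
    window_start_index = "integer",
    window_length = "integer",
    estimator = "EstimatorSpec",
    config = "DopplerConfig"
  )
)

setValidity("VelocityMap", function(object) {
  ws <- object@window_start_index
  if (length(ws) != nrow(object@axial_velocity))
    return("one window start per row of 'axial_velocity'")
  if (length(ws) > 1L && any(diff(ws) <= 0))
    return("'window_start_index' must be strictly increasing")
  if (any(ws < 1L))
    return("'window_start_index' must be >= 1")
  TRUE
})

## ---------------------------------------------------------------------------
## PhantomSpec
## ---------------------------------------------------------------------------

#' Specification of a simulated capillary-tube flow phantom
#'
#' Describes a lipid-solution flow phantom: a capillary tube of given inner
#' diameter crossed by the imaging beam at the Doppler angle, with a uniform
#' or parabolic axial-velocity profile, SNR-limited additive noise, an
#' accumulating (random-walk) phase instability, and slow multiplicative
#' amplitude fluctuation emulating particle transit through the beam.
#'
#' `phase_jitter_rad` is the standard deviation of the per-interval increment
#' of the accumulating phase instability; together with the additive noise at
#' `snr_db` it produces the adjacent-pair phase stability (see
#' [calibrateNoise()]).
#'
#' @slot axial_velocity_mps numeric(1), signed ground-truth axial velocity at
#'   the tube center (m/s).
#' @slot tube_inner_diameter_m numeric(1), tube inner diameter (m).
#' @slot doppler_angle_deg numeric(1), beam-to-flow angle (deg).
#' @slot profile character(1), `"parabolic"` or `"uniform"` radial profile.
#' @slot n_alines integer(1), A-lines per scan.
#' @slot n_depth integer(1), depth pixels per A-line.
#' @slot depth_pitch_m numeric(1), axial size of one depth pixel (m).
#' @slot snr_db numeric(1), signal-to-noise ratio in dB, defined as the
#'   profile-peak signal power over the total complex additive-noise power.
#' @slot phase_jitter_rad numeric(1), per-interval increment std of the
#'   accumulating phase instability (rad).
#' @slot amplitude_cv numeric(1), coefficient of variation of the slowly
#'   varying multiplicative amplitude, in \[0, 1).
#' @slot seed integer(1), RNG seed; mandatory for simulation.
#' @seealso [PhantomSpec()], [simulateMScan()], [calibrateNoise()]
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(
    axial_velocity_mps = "numeric",
    tube_inner_diameter_m = "numeric",
    doppler_angle_deg = "numeric",
    profile = "character",
    n_alines = "integer",
    n_depth = "integer",
    depth_pitch_m = "numeric",
    snr_db = "numeric",
    phase_jitter_rad = "numeric",
    amplitude_cv = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msgs <- character()
  if (object@tube_inner_diameter_m <= 0)
    msgs <- c(msgs, "'tube_inner_diameter_m' must be positive")
  if (object@n_alines < 2L || object@n_depth < 1L)
    msgs <- c(msgs, "'n_alines' must be >= 2 and 'n_depth' >= 1")
  if (object@depth_pitch_m <= 0)
    msgs <- c(msgs, "'depth_pitch_m' must be positive")
  if (!object@profile %in% c("uniform", "parabolic"))
    msgs <- c(msgs, "'profile' must be \"uniform\" or \"parabolic\"")
  if (object@amplitude_cv < 0 || object@amplitude_cv >= 1)
    msgs <- c(msgs, "'amplitude_cv' must lie in [0, 1)")
  if (object@phase_jitter_rad < 0)
    msgs <- c(msgs, "'phase_jitter_rad' must be >= 0")
  if (object@doppler_angle_deg < 0 || object@doppler_angle_deg >= 90)
    msgs <- c(msgs, "'doppler_angle_deg' must lie in [0, 90)")
  if (length(msgs)) msgs else TRUE
})

#' Construct a PhantomSpec
#'
#' Defaults emulate the validation experiment: a 300-um inner-diameter
#' capillary at ~80 deg to the beam, 16,000 x 594-pixel frames, a parabolic
#' (laminar) profile, and noise calibrated so that the adjacent-pair phase
#' stability on a static sample is 0.096 rad at the default 40-dB SNR
#' (see [calibrateNoise()]).
#'
#' @param axial_velocity_mps Ground-truth axial velocity at tube center (m/s).
#' @param tube_inner_diameter_m Tube inner diameter (m).
#' @param doppler_angle_deg Beam-to-flow angle (deg).
#' @param profile `"parabolic"` (default) or `"uniform"`.
#' @param n_alines A-lines per scan.
#' @param n_depth Depth pixels.
#' @param depth_pitch_m Axial pixel size (m).
#' @param snr_db Signal-to-noise ratio (dB) at the profile peak.
#' @param phase_jitter_rad Per-interval increment std of the accumulating
#'   phase instability (rad). The default, together with `snr_db = 40`,
#'   yields a 0.096-rad adjacent-pair phase stability.
#' @param amplitude_cv Coefficient of variation of the amplitude fluctuation.
#' @param seed Integer RNG seed (mandatory before simulation).
#' @return A [PhantomSpec-class] object.
#' @examples
#' spec <- PhantomSpec(axial_velocity_mps = 0.05, n_alines = 640,
#'                     n_depth = 64, depth_pitch_m = 8e-6, seed = 1)
#' scan <- simulateMScan(spec, DopplerConfig())
#' dim(scan)
#' @export
PhantomSpec <- function(axial_velocity_mps,
                        tube_inner_diameter_m = 300e-6,
                        doppler_angle_deg = 80,
                        profile = c("parabolic", "uniform"),
                        n_alines = 16000L,
                        n_depth = 594L,
                        depth_pitch_m = 4.2e-6,
                        snr_db = 40,
                        phase_jitter_rad = sqrt(0.096^2 - 10^(-40 / 10)),
                        amplitude_cv = 0.1,
                        seed = NA_integer_) {
  profile <- match.arg(profile)
  new("PhantomSpec",
      axial_velocity_mps = as.numeric(axial_velocity_mps),
      tube_inner_diameter_m = as.numeric(tube_inner_diameter_m),
      doppler_angle_deg = as.numeric(doppler_angle_deg),
      profile = profile,
      n_alines = as.integer(n_alines),
      n_depth = as.integer(n_depth),
      depth_pitch_m = as.numeric(depth_pitch_m),
      snr_db = as.numeric(snr_db),
      phase_jitter_rad = as.numeric(phase_jitter_rad),
      amplitude_cv = as.numeric(amplitude_cv),
      seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## NoiseCalibration
## ---------------------------------------------------------------------------

#' Phantom noise settings calibrated to a target phase stability
#'
#' @slot target_rad numeric(1), target adjacent-pair phase std (rad).
#' @slot snr_db numeric(1), calibrated SNR (dB).
#' @slot phase_jitter_rad numeric(1), per-interval increment std of the
#'   accumulating phase instability (rad).
#' @slot additive_pair_rad numeric(1), adjacent-pair phase std contributed by
#'   the additive noise alone (rad), equal to `1/sqrt(SNR_linear)`.
#' @seealso [calibrateNoise()], [attenuate()]
#' @exportClass NoiseCalibration
setClass("NoiseCalibration",
  representation(
    target_rad = "numeric",
    snr_db = "numeric",
    phase_jitter_rad = "numeric",
    additive_pair_rad = "numeric"
  )
)

## ---------------------------------------------------------------------------
## DetectionReport
## ---------------------------------------------------------------------------

#' Minimum-detectable-velocity report for one estimator and SNR condition
#'
#' @slot estimator the [EstimatorSpec-class] evaluated.
#' @slot snr_condition character(1), `"high"` or `"low"`.
#' @slot theoretical_floor_mps numeric(1), analytic detection floor (m/s).
#' @slot grid_minimum_mps numeric(1), smallest test-grid velocity at or above
#'   the floor (m/s).
#' @slot empirical_minimum_mps numeric(1), empirically detected minimum (m/s);
#'   `NA` when not measured or when nothing was detected.
#' @slot criterion character(1), description of the empirical detection
#'   criterion used (empty when not measured).
#' @seealso [detectionReport()], [gridQuantizedMinimum()], [empiricalMinimum()]
#' @exportClass DetectionReport
setClass("DetectionReport",
  representation(
    estimator = "EstimatorSpec",
    snr_condition = "character",
    theoretical_floor_mps = "numeric",
    grid_minimum_mps = "numeric",
    empirical_minimum_mps = "numeric",
    criterion = "character"
  )
)

setValidity("DetectionReport", function(object) {
  if (!object@snr_condition %in% c("high", "low"))
    return("'snr_condition' must be \"high\" or \"low\"")
  if (!is.na(object@grid_minimum_mps) &&
      object@grid_minimum_mps < object@theoretical_floor_mps)
    return("'grid_minimum_mps' must be >= 'theoretical_floor_mps'")
  TRUE
})
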
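#' @include AllClasses.R
NULL

#' Convert a per-interval Doppler phase shift to axial velocity
#'
#' Applies the standard Doppler OCT relation
#' \deqn{v = \frac{\Delta\varphi\,\lambda_0}{4\pi\,n\,\Delta T}}
#' where \eqn{\Delta\varphi} is the phase accumulated over one adjacent
#' A-line interval \eqn{\Delta T}. Multipoint estimators report a
#' per-interval phase (`theta_rad`) precisely so that this single conversion
#' applies to every estimator.
#'
#' @param delta_phi Per-interval phase shift(s) in radians; may be a vector
#'   or matrix.
#' @param config A [DopplerConfig-class].
#' @return Signed axial velocity in m/s, same shape as `delta_phi`.
#' @examples
#' cfg <- DopplerConfig()
#' phaseToVelocity(0.096, cfg) * 1e3   # ~12.26 mm/s
#' phaseToVelocity(pi, cfg) * 1e3      # ~401.05 mm/s
#' @export
phaseToVelocity <- function(delta_phi, config = DopplerConfig()) {
  stopifnot(is(config, "DopplerConfig"))
  if (any(!is.finite(delta_phi)))
    stop("'delta_phi' must be finite")
  delta_phi * config@center_wavelength_m /
    (4 * pi * config@refractive_index * config@aline_interval_s)
}

#' Convert an axial velocity to the per-interval Doppler phase shift
#'
#' Inverse of [phaseToVelocity()].
#'
#' @param v_axial Signed axial velocity (m/s); vector or matrix.
#' @inheritParams phaseToVelocity
#' @return Per-interval phase shift in radians.
#' @export
velocityToPhase <- function(v_axial, config = DopplerConfig()) {
  stopifnot(is(config, "DopplerConfig"))
  if (any(!is.finite(v_axial)))
    stop("'v_axial' must be finite")
  v_axial * (4 * pi * config@refractive_index * config@aline_interval_s) /
    config@center_wavelength_m
}

#' Correct an axial velocity for the Doppler angle
#'
#' Returns the absolute flow speed `v_axial / cos(angle)`, where the angle is
#' between the flow axis and the imaging beam.
#'
#' @param v_axial Axial velocity (m/s); vector or matrix.
#' @param doppler_angle_deg Doppler angle in degrees, strictly below 90.
#' @return Absolute velocity, same shape as `v_axial`.
#' @examples
#' angleCorrect(10e-3, 60)   # 20 mm/s
#' @export
angleCorrect <- function(v_axial, doppler_angle_deg) {
  if (length(doppler_angle_deg) != 1L || !is.finite(doppler_angle_deg) ||
      doppler_angle_deg >= 90 || doppler_angle_deg < 0)
    stop("'doppler_angle_deg' must lie in [0, 90): cosine must stay positive")
  v_axial / cos(doppler_angle_deg * pi / 180)
}

#' Detectable velocity range of the conventional two-point method
#'
#' The minimum resolvable phase is the system phase stability and the
#' maximum is \eqn{\pi} (phase-wrapping bound), so the detectable axial
#' velocities span `phaseToVelocity(phase_stability)` to
#' `phaseToVelocity(pi)`.
#'
#' @inheritParams phaseToVelocity
#' @return A [VelocityRange-class].
#' @examples
#' rng <- conventionalRange(DopplerConfig())
#' c(vMin(rng), vMax(rng)) * 1e3   # 12.26, 401.05 mm/s
#' @export
conventionalRange <- function(config = DopplerConfig()) {
  stopifnot(is(config, "DopplerConfig"))
  new("VelocityRange",
      v_min = phaseToVelocity(config@phase_stability_rad, config),
      v_max = phaseToVelocity(pi, config))
}

#' Theoretical minimum-detectable-velocity floor of an estimator
#'
#' Starting from the two-point floor `v_min = phaseToVelocity(phase
#' stability)`, averaging N adjacent-pair measurements reduces the phase
#' noise by \eqn{1/\sqrt{N}}, while the m-point complex regression divides
#' the floor by the \eqn{(m-1)}-fold longer effective measurement interval.
#' Phase noise scales with \eqn{1/\sqrt{\mathrm{SNR}}}, so a linear SNR
#' reduction by a factor F inflates the floor by \eqn{\sqrt{F}}
#' (`snr_attenuation_factor`).
#'
#' @param spec An [EstimatorSpec-class].
#' @param config A [DopplerConfig-class].
#' @param snr_attenuation_factor \eqn{\sqrt{SNR_{high}/SNR_{low}}}; 1 for the
#'   high-SNR condition, `sqrt(10)` for a 10-fold SNR reduction. Must be >= 1.
#' @return Detection-floor axial speed in m/s.
#' @examples
#' cfg <- DopplerConfig()
#' detectionFloor(EstimatorSpec("complex_regression", 64), cfg) * 1e6 # ~194 um/s
#' detectionFloor(EstimatorSpec("conventional_avg", 63), cfg) * 1e3  # ~1.54 mm/s
#' @export
detectionFloor <- function(spec, config = DopplerConfig(),
                           snr_attenuation_factor = 1) {
  stopifnot(is(spec, "EstimatorSpec"), is(config, "DopplerConfig"))
  if (length(snr_attenuation_factor) != 1L ||
      !is.finite(snr_attenuation_factor) || snr_attenuation_factor < 1)
    stop("'snr_attenuation_factor' must be a single number >= 1")
  if (spec@n_points < 2L)
    stop("'n_points' must be >= 2")
  v_base <- conventionalRange(config)@v_min
  gain <- switch(spec@kind,
    conventional_avg = sqrt(as.numeric(spec@n_points)),
    complex_regression = as.numeric(spec@n_points) - 1)
  v_base / gain * snr_attenuation_factor
}

## ---------------------------------------------------------------------------
## Config file (flat YAML)
## ---------------------------------------------------------------------------

.CONFIG_KEYS <- c(wavelength_m = "center_wavelength_m",
                  refractive_index = "refractive_index",
                  aline_interval_s = "aline_interval_s",
                  doppler_angle_deg = "doppler_angle_deg",
                  phase_stability_rad = "phase_stability_rad")

#' Read or write a DopplerConfig as a flat YAML file
#'
#' The file holds the keys `wavelength_m`, `refractive_index`,
#' `aline_interval_s`, `doppler_angle_deg`, `phase_stability_rad`. Missing
#' keys fall back to the package defaults on read.
#'
#' @param path File path.
#' @param config A [DopplerConfig-class] (for writing).
#' @return `readDopplerConfig` returns a [DopplerConfig-class];
#'   `writeDopplerConfig` returns `path` invisibly.
#' @export
readDopplerConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.list(vals))
    stop("config file must contain a flat key-value mapping")
  unknown <- setdiff(names(vals), names(.CONFIG_KEYS))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  args <- lapply(vals, as.numeric)
  names(args) <- .CONFIG_KEYS[names(vals)]
  do.call(DopplerConfig, args)
}

#' @rdname readDopplerConfig
#' @export
writeDopplerConfig <- function(config, path) {
  stopifnot(is(config, "DopplerConfig"))
  vals <- stats::setNames(
    lapply(.CONFIG_KEYS, function(sl) slot(config, sl)),
    names(.CONFIG_KEYS))
  yaml::write_yaml(vals, path)
  invisible(path)
}
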
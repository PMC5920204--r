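#' @include AllClasses.R
NULL

#' Accessors for crDoppler classes
#'
#' Small accessor generics used across the package: `samples()` returns the
#' complex A-line x depth matrix of an [MScan-class]; `alineInterval()` its
#' A-line interval in seconds; `thetaRad()`, `deltaPhiRad()` and
#' `dispersion()` the components of a [PhaseEstimate-class]; `vMin()` and
#' `vMax()` the bounds of a [VelocityRange-class]; `axialVelocity()` the
#' window x depth velocity matrix of a [VelocityMap-class].
#'
#' @param object Object to access.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' @rdname accessors
#' @export
setGeneric("alineInterval", function(object) standardGeneric("alineInterval"))

#' @rdname accessors
#' @export
setGeneric("thetaRad", function(object) standardGeneric("thetaRad"))

#' @rdname accessors
#' @export
setGeneric("deltaPhiRad", function(object) standardGeneric("deltaPhiRad"))

#' @rdname accessors
#' @export
setGeneric("dispersion", function(object) standardGeneric("dispersion"))

#' @rdname accessors
#' @export
setGeneric("nPoints", function(object) standardGeneric("nPoints"))

#' @rdname accessors
#' @export
setGeneric("vMin", function(object) standardGeneric("vMin"))

#' @rdname accessors
#' @export
setGeneric("vMax", function(object) standardGeneric("vMax"))

#' @rdname accessors
#' @export
setGeneric("axialVelocity", function(object) standardGeneric("axialVelocity"))

#' @rdname accessors
#' @export
setGeneric("windowStarts", function(object) standardGeneric("windowStarts"))

#' Angle-corrected absolute velocity of a map
#'
#' Divides the axial velocities by the cosine of the Doppler angle stored in
#' the map's configuration.
#'
#' @param object A [VelocityMap-class].
#' @return Numeric matrix of absolute velocities (m/s).
#' @export
setGeneric("absoluteVelocity",
           function(object) standardGeneric("absoluteVelocity"))

## -- methods ----------------------------------------------------------------

#' @rdname accessors
setMethod("samples", "MScan", function(object) object@samples)

#' @rdname accessors
setMethod("alineInterval", "MScan", function(object) object@aline_interval_s)

#' @describeIn accessors A-lines x depth dimensions of the scan.
#' @param x An [MScan-class].
#' @export
setMethod("dim", "MScan", function(x) dim(x@samples))

#' @rdname accessors
setMethod("thetaRad", "PhaseEstimate", function(object) object@theta_rad)

#' @rdname accessors
setMethod("deltaPhiRad", "PhaseEstimate", function(object) object@delta_phi_rad)

#' @rdname accessors
setMethod("dispersion", "PhaseEstimate", function(object) object@dispersion)

#' @rdname accessors
setMethod("nPoints", "PhaseEstimate", function(object) object@n_points)

#' @rdname accessors
setMethod("nPoints", "EstimatorSpec", function(object) object@n_points)

#' @rdname accessors
setMethod("vMin", "VelocityRange", function(object) object@v_min)

#' @rdname accessors
setMethod("vMax", "VelocityRange", function(object) object@v_max)

#' @rdname accessors
setMethod("axialVelocity", "VelocityMap", function(object) object@axial_velocity)

#' @rdname accessors
setMethod("windowStarts", "VelocityMap",
          function(object) object@window_start_index)

setMethod("absoluteVelocity", "VelocityMap", function(object) {
  angleCorrect(object@axial_velocity, object@config@doppler_angle_deg)
})

## -- show methods ------------------------------------------------------------

setMethod("show", "DopplerConfig", function(object) {
  cat("DopplerConfig\n")
  cat(sprintf("  wavelength: %.1f nm | n: %.3f | A-line interval: %.1f ns\n",
              object@center_wavelength_m * 1e9, object@refractive_index,
              object@aline_interval_s * 1e9))
  cat(sprintf("  Doppler angle: %.1f deg | phase stability: %.4g rad\n",
              object@doppler_angle_deg, object@phase_stability_rad))
  rng <- conventionalRange(object)
  cat(sprintf("  conventional two-point range: %.4g .. %.4g mm/s\n",
              rng@v_min * 1e3, rng@v_max * 1e3))
})

setMethod("show", "VelocityRange", function(object) {
  cat(sprintf("VelocityRange: %.6g .. %.6g mm/s\n",
              object@v_min * 1e3, object@v_max * 1e3))
})

setMethod("show", "EstimatorSpec", function(object) {
  cat(sprintf("EstimatorSpec: %s (n_points = %d)\n",
              object@kind, object@n_points))
})

setMethod("show", "MScan", function(object) {
  d <- dim(object@samples)
  kind <- if (length(object@lateral_positions)) "B-scan" else "M-scan"
  cat(sprintf("MScan (%s): %d A-lines x %d depth pixels, dT = %.3g ns\n",
              kind, d[1], d[2], object@aline_interval_s * 1e9))
})

setMethod("show", "PhaseEstimate", function(object) {
  cat(sprintf(
    "PhaseEstimate: theta = %.6g rad, delta_phi = %.6g rad (n = %d, dispersion = %.4g)\n",
    object@theta_rad, object@delta_phi_rad, object@n_points,
    object@dispersion))
})

setMethod("show", "VelocityMap", function(object) {
  d <- dim(object@axial_velocity)
  cat(sprintf("VelocityMap: %d windows x %d depth pixels (%s, window = %d)\n",
              d[1], d[2], object@estimator@kind, object@window_length))
  v <- range(object@axial_velocity, na.rm = TRUE)
  cat(sprintf("  axial velocity: %.4g .. %.4g mm/s\n", v[1] * 1e3, v[2] * 1e3))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec: v_axial = %.4g mm/s (%s), tube %.0f um at %.0f deg\n",
    object@axial_velocity_mps * 1e3, object@profile,
    object@tube_inner_diameter_m * 1e6, object@doppler_angle_deg))
  cat(sprintf(
    "  %d A-lines x %d px (%.2g um), SNR %.1f dB, jitter %.4g rad, CV %.2g, seed %s\n",
    object@n_alines, object@n_depth, object@depth_pitch_m * 1e6,
    object@snr_db, object@phase_jitter_rad, object@amplitude_cv,
    ifelse(is.na(object@seed), "<unset>", object@seed)))
})

setMethod("show", "NoiseCalibration", function(object) {
  cat(sprintf(
    "NoiseCalibration: target %.4g rad -> SNR %.2f dB + walk increment %.4g rad\n",
    object@target_rad, object@snr_db, object@phase_jitter_rad))
  cat(sprintf("  additive pair contribution: %.4g rad\n",
              object@additive_pair_rad))
})

setMethod("show", "DetectionReport", function(object) {
  cat(sprintf("DetectionReport: %s N=%d, %s SNR\n", object@estimator@kind,
              object@estimator@n_points, object@snr_condition))
  cat(sprintf("  theoretical floor: %.4g mm/s | grid minimum: %.4g mm/s\n",
              object@theoretical_floor_mps * 1e3,
              object@grid_minimum_mps * 1e3))
  if (!is.na(object@empirical_minimum_mps))
    cat(sprintf("  empirical minimum: %.4g mm/s [%s]\n",
                object@empirical_minimum_mps * 1e3, object@criterion))
})
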
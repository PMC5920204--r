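#' @include AllClasses.R core.R estimators.R phantom.R
NULL

.deriveSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1009 + as.numeric(i) * 99991) %% 2147483629) + 1L
}

.estimatorLabel <- function(est) {
  sprintf("%s_%d", if (est@kind == "conventional_avg") "cnv" else "cmpreg",
          est@n_points)
}

## Shared worker: simulate one phantom scan, locate the profile peak, and
## return per-window velocity estimates for each estimator.
.sweepPoint <- function(v, estimators, spec_template, config, seed,
                        window_length, stride, peak_depth = NULL) {
  spec <- spec_template
  spec@axial_velocity_mps <- v
  spec@seed <- seed
  scan <- simulateMScan(spec, config)
  if (is.null(peak_depth)) {
    tube <- phantomRegions(spec)$tube
    peak_depth <- tube[which.max(colMeans(Mod(scan@samples[, tube,
                                                           drop = FALSE])))]
  }
  lapply(estimators, function(est) {
    vm <- dopplerImage(scan, est, window_length = window_length,
                       stride = stride, config = config,
                       depths = peak_depth)
    as.vector(axialVelocity(vm))
  })
}

#' Velocity sweep over a test grid
#'
#' For each grid velocity, simulates a phantom M-scan from the template,
#' extracts the per-window estimates at the peak of the flow profile (the
#' in-tube depth pixel with the largest mean signal amplitude, or a fixed
#' `peak_depth`), and summarizes the measured velocities normalized by the
#' actual velocity: the mean normalized velocity and its standard error
#' (sample standard deviation over the square root of the number of
#' windows).
#'
#' Simulation or estimation failures at an individual velocity are caught,
#' reported as a warning, and returned as an `NA` row so the sweep
#' continues.
#'
#' @param grid Numeric vector of ground-truth axial velocities (m/s),
#'   strictly increasing; see [validationVelocityGrid()].
#' @param estimator An [EstimatorSpec-class] or a list of them (evaluated on
#'   the same simulated scans).
#' @param spec_template A [PhantomSpec-class]; its velocity and seed are
#'   overwritten per grid point.
#' @param config A [DopplerConfig-class].
#' @param seed Integer seed; per-velocity seeds are derived from it.
#' @param window_length,stride Windowing of the scan (defaults 64,
#'   non-overlapping).
#' @param peak_depth Optional fixed depth pixel for the profile peak.
#' @return A data.frame with one row per (velocity, estimator):
#'   `velocity_mps`, `estimator`, `n_points`, `mean_normalized_velocity`,
#'   `standard_error`, `n_windows`, `mean_velocity_mps`, `sd_velocity_mps`,
#'   `seed`.
#' @export
runSweep <- function(grid, estimator, spec_template, config = DopplerConfig(),
                     seed = 1L, window_length = 64L, stride = window_length,
                     peak_depth = NULL) {
  if (!length(grid)) stop("'grid' must be non-empty")
  estimators <- if (is(estimator, "EstimatorSpec")) list(estimator)
                else estimator
  stopifnot(all(vapply(estimators, is, logical(1), "EstimatorSpec")))
  labels <- vapply(estimators, .estimatorLabel, character(1))
  rows <- vector("list", length(grid) * length(estimators))
  k <- 0L
  for (i in seq_along(grid)) {
    v <- grid[i]
    sd_i <- .deriveSeed(seed, i)
    ests <- tryCatch(
      .sweepPoint(v, estimators, spec_template, config, sd_i,
                  window_length, stride, peak_depth),
      error = function(e) {
        warning(sprintf("sweep point %g m/s failed: %s", v,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    for (j in seq_along(estimators)) {
      k <- k + 1L
      if (is.null(ests)) {
        rows[[k]] <- data.frame(
          velocity_mps = v, estimator = labels[j],
          n_points = estimators[[j]]@n_points,
          mean_normalized_velocity = NA_real_, standard_error = NA_real_,
          n_windows = NA_integer_, mean_velocity_mps = NA_real_,
          sd_velocity_mps = NA_real_, seed = sd_i)
      } else {
        ve <- ests[[j]]
        norm <- if (v != 0) ve / v else rep(NA_real_, length(ve))
        rows[[k]] <- data.frame(
          velocity_mps = v, estimator = labels[j],
          n_points = estimators[[j]]@n_points,
          mean_normalized_velocity = mean(norm),
          standard_error = stats::sd(norm) / sqrt(length(ve)),
          n_windows = length(ve),
          mean_velocity_mps = mean(ve),
          sd_velocity_mps = stats::sd(ve), seed = sd_i)
      }
    }
  }
  do.call(rbind, rows)
}

#' Zero-flow noise reference for the empirical detection criterion
#'
#' Simulates the template phantom at zero velocity and returns the
#' per-window estimate statistics per estimator — the noise floor against
#' which swept velocities are compared.
#'
#' @inheritParams runSweep
#' @return A data.frame with `estimator`, `n_points`, `mean_velocity_mps`,
#'   `sd_velocity_mps`, `n_windows`, `seed`.
#' @export
zeroFlowReference <- function(estimator, spec_template,
                              config = DopplerConfig(), seed = 1L,
                              window_length = 64L, stride = window_length,
                              peak_depth = NULL) {
  estimators <- if (is(estimator, "EstimatorSpec")) list(estimator)
                else estimator
  sd0 <- .deriveSeed(seed, 0L)
  ## zero-flow scans keep the centerline as reference depth
  if (is.null(peak_depth))
    peak_depth <- phantomRegions(spec_template)$centerline
  ests <- .sweepPoint(0, estimators, spec_template, config, sd0,
                      window_length, stride, peak_depth)
  data.frame(
    estimator = vapply(estimators, .estimatorLabel, character(1)),
    n_points = vapply(estimators, function(e) e@n_points, integer(1)),
    mean_velocity_mps = vapply(ests, mean, numeric(1)),
    sd_velocity_mps = vapply(ests, stats::sd, numeric(1)),
    n_windows = vapply(ests, length, integer(1)),
    seed = sd0)
}

#' Smallest test-grid velocity at or above a detection floor
#'
#' The sampled velocity grid quantizes any theoretical floor upward to the
#' nearest grid point, which is what a sweep over the grid can actually
#' resolve.
#'
#' @param floor_mps Detection floor (m/s); must not exceed the grid maximum.
#' @param grid Numeric vector of test velocities (m/s), increasing.
#' @return The smallest grid velocity `>= floor_mps`.
#' @examples
#' gridQuantizedMinimum(194e-6, validationVelocityGrid()) * 1e6   # 374
#' @export
gridQuantizedMinimum <- function(floor_mps, grid = validationVelocityGrid()) {
  if (length(floor_mps) != 1L || !is.finite(floor_mps))
    stop("'floor_mps' must be a single finite number")
  if (floor_mps > max(grid))
    stop(sprintf("floor %.4g m/s lies above the grid maximum %.4g m/s",
                 floor_mps, max(grid)))
  min(grid[grid >= floor_mps])
}

#' Empirical minimum detectable velocity from a sweep
#'
#' A grid velocity counts as detected when (a) its mean normalized velocity
#' lies within `norm_range` and (b) the magnitude of its mean measured
#' velocity exceeds `noise_multiplier` times the zero-flow per-window
#' standard deviation of the same estimator. The empirical minimum is the
#' smallest detected velocity. The default multiplier of 1 matches the
#' convention that defines the detection floor as the velocity whose signal
#' equals the phase-noise standard deviation.
#'
#' @param sweep A sweep data.frame from [runSweep()] for a single estimator,
#'   sorted by velocity.
#' @param zero_flow_reference One row of [zeroFlowReference()] for the same
#'   estimator (or any list with `sd_velocity_mps`).
#' @param norm_range Acceptance interval for the mean normalized velocity.
#' @param noise_multiplier Multiple of the zero-flow std the mean measured
#'   velocity must exceed.
#' @return The smallest detected velocity (m/s), or `NA` if none qualifies
#'   ("none detected"); the criterion used is attached as attribute
#'   `"criterion"`.
#' @export
empiricalMinimum <- function(sweep, zero_flow_reference,
                             norm_range = c(0.5, 1.5),
                             noise_multiplier = 1) {
  if (is.unsorted(sweep$velocity_mps))
    stop("'sweep' must be sorted by velocity")
  if (length(unique(sweep$estimator)) > 1L)
    stop("'sweep' must contain a single estimator")
  noise_sd <- zero_flow_reference$sd_velocity_mps[1L]
  crit <- sprintf(
    "mean normalized velocity in [%g, %g] and |mean velocity| > %g x zero-flow std (%.4g m/s)",
    norm_range[1], norm_range[2], noise_multiplier, noise_sd)
  ok <- !is.na(sweep$mean_normalized_velocity) &
    sweep$mean_normalized_velocity >= norm_range[1] &
    sweep$mean_normalized_velocity <= norm_range[2] &
    abs(sweep$mean_velocity_mps) > noise_multiplier * noise_sd
  out <- if (any(ok)) min(sweep$velocity_mps[ok]) else {
    message("empiricalMinimum: none detected")
    NA_real_
  }
  structure(out, criterion = crit)
}

#' Detection report for one estimator and SNR condition
#'
#' Combines the analytic detection floor ([detectionFloor()]), its
#' grid-quantized value ([gridQuantizedMinimum()]) and, when supplied, an
#' empirically measured minimum.
#'
#' @param estimator An [EstimatorSpec-class].
#' @param snr_condition `"high"` or `"low"`; the low condition inflates the
#'   floor by `sqrt(10)` (10-fold linear SNR reduction).
#' @param config A [DopplerConfig-class].
#' @param grid Test velocity grid (m/s).
#' @param empirical_minimum_mps Optional measured minimum (m/s), e.g. from
#'   [empiricalMinimum()].
#' @param criterion Description of the empirical criterion used.
#' @return A [DetectionReport-class].
#' @examples
#' detectionReport(EstimatorSpec("complex_regression", 64), "high")
#' @export
detectionReport <- function(estimator, snr_condition = c("high", "low"),
                            config = DopplerConfig(),
                            grid = validationVelocityGrid(),
                            empirical_minimum_mps = NA_real_,
                            criterion = NA_character_) {
  snr_condition <- match.arg(snr_condition)
  factor <- if (snr_condition == "low") sqrt(10) else 1
  floor_mps <- detectionFloor(estimator, config, factor)
  new("DetectionReport",
      estimator = estimator,
      snr_condition = snr_condition,
      theoretical_floor_mps = floor_mps,
      grid_minimum_mps = gridQuantizedMinimum(floor_mps, grid),
      empirical_minimum_mps = as.numeric(empirical_minimum_mps),
      criterion = as.character(criterion))
}

.mode_velocity <- function(x) {
  key <- ifelse(is.na(x), "none", format(x, digits = 12))
  tab <- table(key)
  winners <- names(tab)[tab == max(tab)]
  vals <- suppressWarnings(as.numeric(winners))
  if (all(is.na(vals))) return(NA_real_)
  min(vals, na.rm = TRUE)
}

#' End-to-end minimum-detectable-velocity study
#'
#' Reproduces the full evaluation protocol on simulated phantoms: for each
#' estimator and SNR condition, sweeps the velocity grid over several seeds,
#' applies the empirical detection criterion against a per-seed zero-flow
#' reference, and compares the majority empirical minimum with the
#' grid-quantized theoretical floor.
#'
#' The default problem size is scaled down from the full acquisition
#' (2,000 A-lines giving 31 windows per scan instead of 16,000/250) to keep
#' runtimes in seconds per cell.
#'
#' @param config A [DopplerConfig-class]; its phase stability is the
#'   calibration target.
#' @param estimators List of [EstimatorSpec-class] objects.
#' @param seeds Integer vector of study seeds (one sweep per seed).
#' @param grid Velocity grid (m/s).
#' @param spec_template Scaled-down [PhantomSpec-class] template.
#' @param snr_high_db SNR (dB) of the high-SNR condition.
#' @param snr_drop_db SNR reduction (dB) of the low-SNR condition.
#' @param norm_range,noise_multiplier Passed to [empiricalMinimum()].
#' @param window_length Windowing (must match the regression estimator).
#' @return A data.frame with one row per estimator x SNR cell:
#'   `estimator`, `snr_condition`, `theoretical_floor_mps`,
#'   `grid_minimum_mps`, `empirical_minimum_mps` (majority over seeds),
#'   `agreement` (fraction of seeds whose empirical minimum equals the grid
#'   minimum), and `n_seeds`.
#' @export
detectionMinimaStudy <- function(config = DopplerConfig(),
                                 estimators = list(
                                   EstimatorSpec("conventional_avg", 5),
                                   EstimatorSpec("conventional_avg", 63),
                                   EstimatorSpec("complex_regression", 64)),
                                 seeds = 1:25,
                                 grid = validationVelocityGrid(),
                                 spec_template = PhantomSpec(
                                   axial_velocity_mps = 0,
                                   n_alines = 2000L, n_depth = 64L,
                                   depth_pitch_m = 8e-6),
                                 snr_high_db = 40,
                                 snr_drop_db = 10,
                                 norm_range = c(0.5, 1.5),
                                 noise_multiplier = 1,
                                 window_length = 64L) {
  cal_high <- calibrateNoise(config@phase_stability_rad, config,
                             snr_db = snr_high_db)
  conditions <- list(high = cal_high, low = attenuate(cal_high, snr_drop_db))
  labels <- vapply(estimators, .estimatorLabel, character(1))
  out <- list()
  for (cond in names(conditions)) {
    spec_c <- applyCalibration(spec_template, conditions[[cond]])
    mins <- matrix(NA_real_, length(seeds), length(estimators),
                   dimnames = list(NULL, labels))
    for (s in seq_along(seeds)) {
      sweep <- runSweep(grid, estimators, spec_c, config, seed = seeds[s],
                        window_length = window_length)
      zref <- zeroFlowReference(estimators, spec_c, config, seed = seeds[s],
                                window_length = window_length)
      for (j in seq_along(estimators)) {
        sw_j <- sweep[sweep$estimator == labels[j], , drop = FALSE]
        zr_j <- zref[zref$estimator == labels[j], , drop = FALSE]
        mins[s, j] <- as.numeric(
          empiricalMinimum(sw_j, zr_j, norm_range, noise_multiplier))
      }
    }
    factor <- if (cond == "low") sqrt(10) else 1
    for (j in seq_along(estimators)) {
      fl <- detectionFloor(estimators[[j]], config, factor)
      gm <- gridQuantizedMinimum(fl, grid)
      emp <- .mode_velocity(mins[, j])
      out[[length(out) + 1L]] <- data.frame(
        estimator = labels[j], snr_condition = cond,
        theoretical_floor_mps = fl, grid_minimum_mps = gm,
        empirical_minimum_mps = emp,
        agreement = mean(!is.na(mins[, j]) & mins[, j] == gm),
        n_seeds = length(seeds))
    }
  }
  do.call(rbind, out)
}
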
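#' @include AllClasses.R core.R
NULL

## Cache for the derotation matrix exp(-i * theta_grid x 0:(m-1)); building it
## costs more than a single window search, and every window of a scan reuses it.
.regCache <- new.env(parent = emptyenv())

#' Theta search grid for the complex-regression estimator
#'
#' Uniform grid of candidate per-interval phases covering the half-open
#' circle (-pi, pi]: all integer multiples of `grid_step` in (-pi, pi) plus
#' the endpoint `pi`. Excluding -pi avoids the duplicate of the +pi
#' candidate.
#'
#' @param grid_step Grid increment in radians, default 1 mrad.
#' @return Numeric vector of candidate theta values, strictly increasing.
#' @export
thetaGrid <- function(grid_step = 1e-3) {
  if (length(grid_step) != 1L || !is.finite(grid_step) ||
      grid_step <= 0 || grid_step >= pi)
    stop("'grid_step' must lie in (0, pi)")
  k <- floor(pi / grid_step)
  g <- seq.int(-k, k) * grid_step
  if (k * grid_step < pi) g <- c(g, pi)
  g
}

.derotationMatrix <- function(m, grid_step) {
  key <- sprintf("m%d_s%.17g", m, grid_step)
  val <- .regCache[[key]]
  if (is.null(val)) {
    g <- thetaGrid(grid_step)
    val <- list(grid = g, E = exp(-1i * outer(g, 0:(m - 1))))
    .regCache[[key]] <- val
  }
  val
}

#' Kasai (complex autocorrelation) per-interval phase
#'
#' The conventional Doppler OCT estimator computed directly on the complex
#' A-lines: the argument of the summed lag-one autocorrelation,
#' \deqn{\theta = \arg \sum_{k} s_{k+1}\,\overline{s_k},}
#' an amplitude-weighted average of the pairwise phase differences.
#'
#' @param window Complex vector of at least 2 samples from one depth, in
#'   A-line order.
#' @return Per-interval phase in (-pi, pi].
#' @examples
#' kasaiPhase(c(1 + 0i, 1i))                     # pi/2
#' kasaiPhase(exp(1i * 0.1 * 0:9))               # 0.1
#' @export
kasaiPhase <- function(window) {
  window <- as.complex(window)
  n <- length(window)
  if (n < 2L) stop("need at least 2 points")
  p <- window[-1L] * Conj(window[-n])
  s <- sum(p)
  if (s == 0 && all(p == 0))
    stop("undefined phase: all lag-one products are zero")
  Arg(s)
}

## Vectorized Kasai over the columns of an (N+1) x W complex matrix.
.kasaiColumns <- function(S) {
  n <- nrow(S)
  Arg(colSums(S[2:n, , drop = FALSE] * Conj(S[1:(n - 1), , drop = FALSE])))
}

#' Conventional N-average Doppler estimate on a scan window
#'
#' Applies [kasaiPhase()] to the first `n_averages` adjacent pairs of the
#' window starting at A-line `window_start` (1-based) at the given depth.
#' The result keeps single-interval semantics: `delta_phi_rad` equals
#' `theta_rad`, while `n_points` records the `n_averages + 1` A-lines used.
#'
#' @param mscan An [MScan-class].
#' @param depth Depth pixel index (1-based).
#' @param window_start First A-line of the window (1-based).
#' @param n_averages Number of adjacent pairs averaged (e.g. 5 or 63).
#' @return A [PhaseEstimate-class].
#' @export
conventionalDoppler <- function(mscan, depth, window_start, n_averages) {
  stopifnot(is(mscan, "MScan"))
  T <- nrow(mscan@samples)
  n_averages <- as.integer(n_averages)
  if (n_averages < 1L) stop("'n_averages' must be >= 1")
  if (window_start < 1L || window_start + n_averages > T)
    stop(sprintf("window [%d, %d] exceeds scan bounds (T = %d)",
                 window_start, window_start + n_averages, T))
  w <- mscan@samples[window_start:(window_start + n_averages), depth]
  theta <- kasaiPhase(w)
  .PhaseEstimate(theta, theta, complexDispersion(realign(w, theta)),
                 n_averages + 1L)
}

#' Realign a window of complex points by derotation
#'
#' Subtracts sequentially increasing multiples of `theta` from the phase of
#' each point: the k-th point (k = 0, 1, ...) is multiplied by
#' \eqn{e^{-ik\theta}}, so a noiseless window rotating by `theta` per
#' interval collapses onto its first point. Amplitudes are unchanged.
#'
#' @param window Complex vector in A-line order.
#' @param theta Per-interval phase to remove (rad).
#' @return Complex vector of realigned points.
#' @export
realign <- function(window, theta) {
  window <- as.complex(window)
  if (length(window) < 2L) stop("need at least 2 points")
  window * exp(-1i * (seq_along(window) - 1) * theta)
}

#' Dispersion (standard deviation) of a cloud of complex points
#'
#' Population convention:
#' \eqn{\sqrt{\frac{1}{m}\sum_k |z_k - \bar z|^2}} with \eqn{\bar z} the
#' complex mean. This is the objective the complex-regression estimator
#' minimizes over candidate derotation phases.
#'
#' @param points Complex vector of at least 2 points.
#' @return Non-negative scalar.
#' @export
complexDispersion <- function(points) {
  points <- as.complex(points)
  if (length(points) < 2L) stop("need at least 2 points")
  sqrt(mean(Mod(points - mean(points))^2))
}

#' Complex-regression per-interval phase of a window
#'
#' Exhaustive search over the candidate grid [thetaGrid()] for the
#' derotation phase that minimizes the dispersion of the realigned points
#' ([realign()], [complexDispersion()]). Because derotation preserves
#' moduli, the dispersion-minimizing theta is identically the theta
#' maximizing the coherent-sum magnitude
#' \eqn{|\sum_k s_k e^{-ik\theta}|}, which is what the implementation
#' evaluates (one matrix product over the whole grid). The total phase shift
#' is `delta_phi_rad = (m-1) * theta_rad` and may exceed \eqn{2\pi}: phase
#' wrapping only occurs if the *per-interval* phase exceeds \eqn{\pi}.
#'
#' Ties are broken toward the smallest `|theta|`, then toward negative
#' `theta` (preferring the slower velocity under ambiguity).
#'
#' @param window Complex vector of m >= 2 samples at one depth, in A-line
#'   order.
#' @param grid_step Search increment in radians (default 1 mrad).
#' @return A [PhaseEstimate-class] with the minimized dispersion.
#' @examples
#' w <- exp(1i * 0.1 * 0:63)
#' est <- complexRegressionPhase(w)
#' thetaRad(est)                 # 0.1
#' deltaPhiRad(est)              # 6.3, no wrap
#' @export
complexRegressionPhase <- function(window, grid_step = 1e-3) {
  window <- as.complex(window)
  m <- length(window)
  if (m < 2L) stop("need at least 2 points")
  if (all(window == 0))
    stop("undefined phase: window is identically zero")
  cache <- .derotationMatrix(m, grid_step)
  csum <- as.vector(cache$E %*% window)
  theta <- .pickTheta(Mod(csum), cache$grid)
  meanpow <- mean(Mod(window)^2)
  best <- max(Mod(csum)) / m
  disp <- sqrt(max(meanpow - best^2, 0))
  .PhaseEstimate(theta, (m - 1) * theta, disp, m)
}

## Tie-break: smallest |theta|, then negative theta.
.pickTheta <- function(magnitudes, grid) {
  idx <- which(magnitudes == max(magnitudes))
  if (length(idx) > 1L) {
    cand <- grid[idx]
    idx <- idx[order(abs(cand), cand)]
  }
  grid[idx[1L]]
}

## Batch regression over the columns of an m x W complex matrix.
## Returns per-column theta. Chunked so the G x W magnitude block stays small.
.regressionColumns <- function(S, grid_step = 1e-3, chunk = 256L) {
  m <- nrow(S)
  cache <- .derotationMatrix(m, grid_step)
  W <- ncol(S)
  theta <- numeric(W)
  for (j0 in seq.int(1L, W, by = chunk)) {
    j1 <- min(j0 + chunk - 1L, W)
    M <- Mod(cache$E %*% S[, j0:j1, drop = FALSE])
    theta[j0:j1] <- apply(M, 2L, .pickTheta, grid = cache$grid)
  }
  theta
}

#' Windowed Doppler velocity map of a scan
#'
#' Partitions the A-lines into windows of `window_length` (non-overlapping
#' when `stride = window_length`, the default) and applies the selected
#' estimator per window and depth pixel, converting the per-interval phase
#' to axial velocity with [phaseToVelocity()]. Depth pixels are processed
#' independently; no axial averaging is applied.
#'
#' For `"conventional_avg"` the estimator uses the first `n_points` adjacent
#' pairs of each window (so `n_points <= window_length - 1`); for
#' `"complex_regression"` the window length must equal the estimator's
#' `n_points`.
#'
#' @param mscan An [MScan-class].
#' @param estimator An [EstimatorSpec-class].
#' @param window_length A-lines per window (default 64).
#' @param stride Offset between window starts (default `window_length`).
#' @param config A [DopplerConfig-class].
#' @param depths Depth pixel indices to process (default all).
#' @param grid_step Search increment for the regression estimator (rad).
#' @return A [VelocityMap-class] (windows x depths).
#' @examples
#' spec <- PhantomSpec(axial_velocity_mps = 0.05, n_alines = 256,
#'                     n_depth = 48, depth_pitch_m = 8e-6, seed = 7)
#' cfg <- DopplerConfig()
#' scan <- simulateMScan(spec, cfg)
#' vm <- dopplerImage(scan, EstimatorSpec("conventional_avg", 5), config = cfg)
#' dim(axialVelocity(vm))   # 4 windows x 48 depths
#' @export
dopplerImage <- function(mscan, estimator, window_length = 64L,
                         stride = window_length, config = DopplerConfig(),
                         depths = NULL, grid_step = 1e-3) {
  stopifnot(is(mscan, "MScan"), is(estimator, "EstimatorSpec"),
            is(config, "DopplerConfig"))
  S <- mscan@samples
  T <- nrow(S)
  window_length <- as.integer(window_length)
  stride <- as.integer(stride)
  if (window_length > T)
    stop(sprintf("window_length (%d) exceeds scan length (%d)",
                 window_length, T))
  if (stride < 1L) stop("'stride' must be >= 1")
  if (estimator@kind == "complex_regression" &&
      estimator@n_points != window_length)
    stop("for complex_regression, 'window_length' must equal the estimator's n_points")
  if (estimator@kind == "conventional_avg" &&
      estimator@n_points > window_length - 1L)
    stop("conventional_avg needs n_points <= window_length - 1 pairs")
  if (is.null(depths)) depths <- seq_len(ncol(S))
  starts <- seq.int(1L, T - window_length + 1L, by = stride)
  nw <- length(starts)
  V <- matrix(NA_real_, nw, length(depths))
  if (estimator@kind == "conventional_avg") {
    N <- estimator@n_points
    for (i in seq_len(nw)) {
      idx <- starts[i]:(starts[i] + N)
      V[i, ] <- .kasaiColumns(S[idx, depths, drop = FALSE])
    }
  } else {
    for (i in seq_len(nw)) {
      idx <- starts[i]:(starts[i] + window_length - 1L)
      V[i, ] <- .regressionColumns(S[idx, depths, drop = FALSE], grid_step)
    }
  }
  new("VelocityMap",
      axial_velocity = phaseToVelocity(V, config),
      window_start_index = as.integer(starts),
      window_length = window_length,
      estimator = estimator,
      config = config)
}

#' Complex averaging of A-lines
#'
#' Averages consecutive groups of A-lines in the complex domain. With
#' densely sampled scans the structural content of neighboring A-lines is
#' nearly identical, so the complex mean suppresses noise while preserving
#' resolution; the magnitude of the averaged signal is the structural image.
#' A trailing remainder that does not fill a group is dropped with a message.
#'
#' @param x Complex matrix (A-lines x depth), complex vector, or
#'   [MScan-class].
#' @param group Number of consecutive A-lines per average (>= 1).
#' @return Same shape as the input with `floor(T / group)` averaged A-lines
#'   (an [MScan-class] in, an [MScan-class] out, with the A-line interval
#'   scaled by `group`).
#' @examples
#' complexAverage(c(1 + 0i, 1 + 0i, -1 + 0i, -1 + 0i), 2)
#' @export
complexAverage <- function(x, group) {
  group <- as.integer(group)
  if (group < 1L) stop("'group' must be >= 1")
  if (is(x, "MScan")) {
    avg <- complexAverage(x@samples, group)
    return(MScan(avg, x@aline_interval_s * group))
  }
  vec <- !is.matrix(x)
  if (vec) x <- matrix(as.complex(x), ncol = 1L)
  T <- nrow(x)
  usable <- (T %/% group) * group
  if (usable < group) stop("'group' exceeds the number of A-lines")
  if (usable < T)
    message(sprintf("complexAverage: dropping %d trailing A-line(s)",
                    T - usable))
  grp <- rep(seq_len(usable %/% group), each = group)
  out <- (rowsum(Re(x[seq_len(usable), , drop = FALSE]), grp) +
          1i * rowsum(Im(x[seq_len(usable), , drop = FALSE]), grp)) / group
  if (vec) as.vector(out) else out
}
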
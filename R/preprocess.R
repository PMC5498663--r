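#' Modal-grey background subtraction
#'
#' Subtracts the modal grey value of the whole field of view from measured
#' cell intensities, as done frame-by-frame in fluorescence image analysis.
#' The mode is the center of the most populated Freedman-Diaconis histogram
#' bin of the frame pixel distribution (ties broken towards the lowest bin),
#' which picks the background level of a bimodal frame rather than its mean.
#' Simulated trajectories are already background-free and do not need this.
#'
#' @param raw_frame_values pixel intensities of the whole field of view.
#' @param cell_values intensities measured within cell boundaries.
#' @return `cell_values` minus the modal background.
#' @export
subtract_background <- function(raw_frame_values, cell_values) {
  x <- raw_frame_values[is.finite(raw_frame_values)]
  if (length(x) == 0)
    stop("subtract_background: empty frame sample", call. = FALSE)
  h <- 2 * IQR(x) * length(x)^(-1/3)
  if (h <= 0 || diff(range(x)) == 0) {
    tab <- table(x)
    mode_val <- as.numeric(names(tab)[which.max(tab)])  # which.max: first tie
  } else {
    breaks <- seq(min(x), max(x) + h, by = h)
    counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                       nbins = length(breaks) - 1)
    i <- which.max(counts)  # lowest bin on ties
    mode_val <- (breaks[i] + breaks[i + 1]) / 2
  }
  cell_values - mode_val
}

window_idx <- function(times, window) {
  which(times >= window[1] & times <= window[2])
}

#' Baseline normalization of a trajectory
#'
#' Divides every signal value of a cell by that cell's mean signal over a
#' pre-perturbation window (default the first 240 min), so the normalized
#' window mean is exactly 1 and trajectories of different cells are
#' comparable. Applying the same normalization twice is a no-op. For cells
#' born mid-experiment the window is intersected with the observed times.
#'
#' @param x an `aid_trajectory` or `aid_population`.
#' @param window numeric length 2, baseline window in minutes.
#' @return the input with normalized signal(s).
#' @export
normalize_baseline <- function(x, window = c(0, 240)) UseMethod("normalize_baseline")

#' @export
normalize_baseline.aid_trajectory <- function(x, window = c(0, 240)) {
  idx <- window_idx(x$times, window)
  if (length(idx) < 2)
    stop("normalize_baseline: fewer than 2 samples in the baseline window",
         call. = FALSE)
  m <- mean(x$signal[idx])
  if (!is.finite(m) || m <= 0)
    stop("normalize_baseline: nonpositive window mean (corrupt input?)",
         call. = FALSE)
  x$signal <- x$signal / m
  x
}

#' @export
normalize_baseline.aid_population <- function(x, window = c(0, 240)) {
  x$trajectories <- lapply(x$trajectories, normalize_baseline, window = window)
  x
}

#' Smoothing-spline fit and derivative of a trajectory
#'
#' Fits a cubic smoothing spline to a single-cell signal (smoothing parameter
#' chosen by generalized cross-validation unless `spar` is supplied) and
#' evaluates the fitted curve and its analytic first derivative on the
#' sampling grid. The derivative alternates sign over a recovery sawtooth:
#' positive runs are synthesis, negative runs are division dilution.
#'
#' @param traj an `aid_trajectory` (>= 8 samples).
#' @param spar optional fixed smoothing parameter (passed to
#'   [stats::smooth.spline()]), for reproducibility-sensitive analyses.
#' @return object of class `aid_smooth`: `times`, `smooth`, `derivative`,
#'   the underlying `fit`, and the source trajectory's `cell_id`, `role`,
#'   `budding_times`.
#' @export
fit_smoothing_spline <- function(traj, spar = NULL) {
  stopifnot(inherits(traj, "aid_trajectory"))
  if (length(traj$times) < 8)
    stop("fit_smoothing_spline: need at least 8 samples", call. = FALSE)
  fit <- if (is.null(spar)) {
    smooth.spline(traj$times, traj$signal, cv = FALSE)
  } else {
    smooth.spline(traj$times, traj$signal, spar = spar)
  }
  structure(list(times = traj$times,
                 smooth = predict(fit, traj$times)$y,
                 derivative = predict(fit, traj$times, deriv = 1)$y,
                 fit = fit,
                 cell_id = traj$cell_id, role = traj$role,
                 budding_times = traj$budding_times),
            class = "aid_smooth")
}

#' Evaluate a fitted smoothing spline off the sampling grid
#'
#' @param x an `aid_smooth`.
#' @param t times (min).
#' @param deriv 0 for the smooth values, 1 for the first derivative.
#' @return numeric vector.
#' @export
predict_smooth <- function(x, t, deriv = 0) {
  stopifnot(inherits(x, "aid_smooth"))
  predict(x$fit, t, deriv = deriv)$y
}

#' Pointwise population statistics
#'
#' Mean, SD, SEM and t-based 95% confidence band of the signal across a
#' cohort, at every shared timepoint. All trajectories must be on one grid.
#'
#' @param pop an `aid_population` (>= 2 cells).
#' @param conf confidence level for the band.
#' @return data.frame with `time`, `mean`, `sd`, `sem`, `lo`, `hi`, `n`.
#' @export
population_stats <- function(pop, conf = 0.95) {
  stopifnot(inherits(pop, "aid_population"))
  trs <- pop$trajectories
  if (length(trs) < 2)
    stop("population_stats: need at least 2 trajectories", call. = FALSE)
  grid <- trs[[1]]$times
  same <- vapply(trs, function(tr) length(tr$times) == length(grid) &&
                   all(tr$times == grid), logical(1))
  if (!all(same))
    stop("population_stats: trajectories are not on a common time grid",
         call. = FALSE)
  sig <- vapply(trs, `[[`, numeric(length(grid)), "signal")
  n <- ncol(sig)
  m <- rowMeans(sig)
  s <- apply(sig, 1, sd)
  sem <- s / sqrt(n)
  q <- qt(1 - (1 - conf) / 2, df = n - 1)
  data.frame(time = grid, mean = m, sd = s, sem = sem,
             lo = m - q * sem, hi = m + q * sem, n = n)
}
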
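#' Autofluorescence-corrected protein component
#'
#' Converts a baseline-normalized signal to the protein-concentration scale,
#' `(signal - floor) / (1 - floor)`: 0 at the autofluorescence floor, 1 at
#' the pre-depletion baseline. Division dilutes the protein component, not
#' the additive autofluorescence, so sawtooth dilution estimators must run
#' on this scale (the constant floor offset would otherwise shrink the
#' DIFF-vs-MAX slope by roughly a factor `1 - floor`). Values can dip
#' slightly below 0 at the floor under measurement noise.
#'
#' @param x an `aid_trajectory` or `aid_population` (normalized).
#' @param floor floor ratio on the normalized scale (e.g. from
#'   [estimate_floor()] or the simulator's `af_floor`).
#' @return the input with converted signal(s).
#' @export
protein_component <- function(x, floor) UseMethod("protein_component")

#' @export
protein_component.aid_trajectory <- function(x, floor) {
  x$signal <- (x$signal - floor) / (1 - floor)
  x
}

#' @export
protein_component.aid_population <- function(x, floor) {
  if (missing(floor)) floor <- x$config$af_floor
  x$trajectories <- lapply(x$trajectories, protein_component, floor = floor)
  x
}

#' Segment post-removal division cycles and their sawtooth statistics
#'
#' During recovery after auxin removal the signal rises by synthesis within
#' each division cycle and drops at each division: a sawtooth. Cycles are
#' delimited by consecutive observed budding events, counted from the first
#' budding after removal. Because a division is a genuine discontinuity of
#' the concentration trace, smoothing is done per cycle segment (a cubic
#' smoothing spline on the samples between consecutive buddings) rather than
#' across divisions, and each division time is taken as the observed budding
#' frame minus half a sampling period (buddings are scored at the first
#' frame after the event). Within cycle i, MAX is the maximum of the
#' segment-smoothed trace up to the division ending the cycle; MIN is the
#' minimum of the smoothed trace after that MAX and up to the next cycle's
#' MAX (the trough just after the division); DIFF = MAX - following MIN.
#' The synthesis and dilution integrals are the integrals of the positive
#' and negative parts of the smoothed derivative over the cycle, the
#' division drop itself counting as dilution.
#'
#' For dilution-factor estimation the input should be on the
#' autofluorescence-corrected protein scale (see [protein_component()]).
#'
#' @param traj an `aid_trajectory` (normalized); its `budding_times` delimit
#'   the cycles.
#' @param t_removal time of auxin removal (min).
#' @param step evaluation step for extrema and integrals (min).
#' @param df degrees of freedom of the per-segment smoothing spline (capped
#'   by the segment size); within-cycle kinetics are smooth, so a small
#'   fixed df is used instead of per-segment cross-validation.
#' @return data.frame of class `aid_cycles`: one row per cycle with
#'   `cell_id`, `cycle_index`, `t_start`, `t_end`, `max_signal`, `t_max`,
#'   `min_signal`, `diff`, `synthesis_integral`, `dilution_integral`. The
#'   last cycle has `NA` for `min_signal`/`diff` (no following segment).
#'   Empty data.frame if fewer than two post-removal buddings.
#' @export
segment_cycles <- function(traj, t_removal, step = 0.5, df = 5) {
  stopifnot(inherits(traj, "aid_trajectory"))
  dt_samp <- if (length(traj$times) > 1) diff(traj$times[1:2]) else 5
  buds <- sort(traj$budding_times[traj$budding_times >= t_removal])
  buds <- buds[buds <= max(traj$times)]
  empty <- data.frame(cell_id = character(0), cycle_index = integer(0),
                      t_start = numeric(0), t_end = numeric(0),
                      max_signal = numeric(0), t_max = numeric(0),
                      min_signal = numeric(0), diff = numeric(0),
                      synthesis_integral = numeric(0),
                      dilution_integral = numeric(0))
  if (length(buds) < 2)
    return(structure(empty, class = c("aid_cycles", "data.frame")))
  tdiv <- buds - dt_samp / 2          # estimated division times
  n_cyc <- length(buds) - 1

  # per-segment smooths: segment i holds the samples in [buds[i], buds[i+1])
  seg_bounds <- c(buds, max(traj$times) + dt_samp)
  seg_fit <- vector("list", length(buds))
  for (i in seq_along(buds)) {
    sel <- traj$times >= seg_bounds[i] & traj$times < seg_bounds[i + 1]
    tt <- traj$times[sel]; y <- traj$signal[sel]
    seg_fit[i] <- list(if (length(tt) >= 4) {
      smooth.spline(tt, y, df = min(df, length(tt) - 1))
    } else if (length(tt) >= 2) {
      lm(y ~ tt)
    } else NULL)
  }
  seg_eval <- function(i, t, deriv = 0) {
    f <- seg_fit[[i]]
    if (is.null(f)) return(rep(NA_real_, length(t)))
    if (inherits(f, "smooth.spline")) return(predict(f, t, deriv = deriv)$y)
    if (deriv == 0) coef(f)[1] + coef(f)[2] * t else rep(coef(f)[2], length(t))
  }

  # synthesis makes the within-cycle trace nondecreasing during recovery, so
  # the cycle peak sits at the division ending the cycle and the trough just
  # after it; evaluating the segment smooths at the estimated division times
  # avoids the selection bias of searching noisy fitted curves for extrema
  t_max <- tdiv[-1]
  max_val <- vapply(seq_len(n_cyc), function(i) seg_eval(i, tdiv[i + 1]), 0)
  syn <- dil_within <- numeric(n_cyc)
  for (i in seq_len(n_cyc)) {
    tt <- unique(c(seq(tdiv[i], tdiv[i + 1], by = step), tdiv[i + 1]))
    d <- seg_eval(i, tt, deriv = 1)
    w <- diff(tt)
    syn[i] <- sum((pmax(d, 0)[-1] + pmax(d, 0)[-length(d)]) / 2 * w)
    dil_within[i] <- sum((pmin(d, 0)[-1] + pmin(d, 0)[-length(d)]) / 2 * w)
  }
  min_val <- vapply(seq_len(n_cyc), function(i) {
    if (is.null(seg_fit[[i + 1]])) NA_real_ else seg_eval(i + 1, tdiv[i + 1])
  }, 0)
  drop_at_div <- min_val - max_val
  out <- data.frame(cell_id = traj$cell_id,
                    cycle_index = seq_len(n_cyc),
                    t_start = tdiv[-length(tdiv)], t_end = tdiv[-1],
                    max_signal = max_val, t_max = t_max,
                    min_signal = min_val, diff = max_val - min_val,
                    synthesis_integral = syn,
                    dilution_integral = dil_within +
                      pmin(ifelse(is.na(drop_at_div), 0, drop_at_div), 0))
  structure(out, class = c("aid_cycles", "data.frame"))
}

#' Pool cycle statistics over a cohort
#'
#' @param pop a normalized `aid_population`.
#' @param t_removal auxin removal time (min).
#' @param step,df see [segment_cycles()].
#' @return pooled `aid_cycles` data.frame.
#' @export
cohort_cycles <- function(pop, t_removal, step = 0.5, df = 5) {
  out <- do.call(rbind, lapply(pop$trajectories, function(tr) {
    segment_cycles(tr, t_removal, step = step, df = df)
  }))
  structure(out, class = c("aid_cycles", "data.frame"))
}

#' Origin-constrained regression of DIFF on MAX
#'
#' The per-cycle signal drop DIFF is regressed on the peak level MAX with the
#' intercept fixed at zero, so the slope is the per-division fractional drop
#' SLOPE = DIFF/MAX. A constant dilution factor across divisions makes this
#' relation linear through the origin. The 95% CI of the slope is estimated
#' nonparametrically by a percentile bootstrap over oscillations. A
#' free-intercept variant is available for sensitivity analysis.
#'
#' @param cycles an `aid_cycles` data.frame (rows with `NA` DIFF dropped);
#'   >= 5 usable oscillations.
#' @param n_boot bootstrap iterations.
#' @param origin fix the intercept at zero (default TRUE).
#' @return list of class `aid_dilution_fit`: `slope`, `slope_ci95`,
#'   `intercept` (0 unless `origin = FALSE`), `n_oscillations`, `n_cells`,
#'   and the bootstrap slope draws.
#' @export
fit_max_diff_regression <- function(cycles, n_boot = 1000, origin = TRUE) {
  use <- cycles[is.finite(cycles$diff) & is.finite(cycles$max_signal), ,
                drop = FALSE]
  if (nrow(use) < 5)
    stop("fit_max_diff_regression: need >= 5 (MAX, DIFF) pairs", call. = FALSE)
  if (var(use$max_signal) == 0 && !origin)
    stop("fit_max_diff_regression: degenerate MAX variance", call. = FALSE)
  est <- function(d) {
    if (origin) sum(d$max_signal * d$diff) / sum(d$max_signal^2)
    else coef(lm(diff ~ max_signal, data = d))[["max_signal"]]
  }
  slope <- est(use)
  boot <- replicate(n_boot, est(use[sample(nrow(use), replace = TRUE), ]))
  ci <- unname(quantile(boot, c(0.025, 0.975), type = 7))
  structure(list(slope = slope, slope_ci95 = ci,
                 intercept = if (origin) 0 else
                   coef(lm(diff ~ max_signal, data = use))[["(Intercept)"]],
                 n_oscillations = nrow(use),
                 n_cells = length(unique(use$cell_id)),
                 boot_slopes = boot, origin = origin),
            class = "aid_dilution_fit")
}

#' Per-division dilution factor from the sawtooth slope
#'
#' MAX/MIN per division equals DIL = 1/(1 - SLOPE), with SLOPE = DIFF/MAX the
#' origin-constrained regression slope. Confidence-interval endpoints are
#' propagated through the same map.
#'
#' @param x a slope (numeric in `[0, 1)`) or an `aid_dilution_fit`.
#' @return for a numeric slope, the dilution factor; for a fit, a list with
#'   `dil`, `dil_ci95`, `slope`, `slope_ci95`, `n_oscillations`, `n_cells`.
#' @export
#' @examples
#' dilution_factor(0.5)  # 2-fold per division
dilution_factor <- function(x) {
  f <- function(s) {
    if (any(s >= 1)) stop("dilution_factor: slope >= 1 is non-physical",
                          call. = FALSE)
    1 / (1 - s)
  }
  if (is.numeric(x)) return(f(x))
  stopifnot(inherits(x, "aid_dilution_fit"))
  list(dil = f(x$slope), dil_ci95 = f(x$slope_ci95),
       slope = x$slope, slope_ci95 = x$slope_ci95,
       n_oscillations = x$n_oscillations, n_cells = x$n_cells)
}

#' @export
print.aid_dilution_fit <- function(x, ...) {
  cat(sprintf("DIFF-vs-MAX regression (%s): slope %.4f (95%% CI %.4f-%.4f), %d oscillations from %d cells\n",
              if (x$origin) "through origin" else "free intercept",
              x$slope, x$slope_ci95[1], x$slope_ci95[2],
              x$n_oscillations, x$n_cells))
  cat(sprintf("  dilution factor DIL = 1/(1-SLOPE) = %.3f\n", 1 / (1 - x$slope)))
  invisible(x)
}

cohort_mean_at <- function(pop, t) {
  vapply(pop$trajectories, function(tr) approx(tr$times, tr$signal, t)$y, 0)
}

#' Fraction of protein recovered after auxin removal
#'
#' At `t_after_removal` minutes past removal, the cohort mean normalized
#' signal m is converted to the recovered protein fraction
#' `(m - floor)/(1 - floor)` (0 at complete depletion, 1 back at baseline),
#' clipped below at 0. The CI is t-based across the per-cell fractions.
#'
#' @param pop a baseline-normalized `aid_population`.
#' @param t_after_removal minutes after removal (>= 0).
#' @param t_removal removal time (min).
#' @param floor floor ratio on the normalized scale.
#' @return list with `fraction`, `ci95`, per-cell `fractions`.
#' @export
fraction_recovered <- function(pop, t_after_removal, t_removal,
                               floor = pop$config$af_floor) {
  if (t_after_removal < 0)
    stop("fraction_recovered: time before removal", call. = FALSE)
  v <- cohort_mean_at(pop, t_removal + t_after_removal)
  fr <- pmax((v - floor) / (1 - floor), 0)
  n <- length(fr)
  half <- if (n > 1) qt(0.975, n - 1) * sd(fr) / sqrt(n) else 0
  list(fraction = pmax((mean(v) - floor) / (1 - floor), 0),
       ci95 = mean(fr) + c(-1, 1) * half, fractions = fr, n = n)
}

#' Time for the cohort mean to return to baseline
#'
#' First time after removal at which the cohort mean normalized signal
#' re-enters the baseline band `1 +/- band`. Returns 0 if the mean never
#' left the band (no depletion), `NA` if it does not recover within the
#' horizon.
#'
#' @param pop a baseline-normalized `aid_population` on a common grid.
#' @param t_removal removal time (min).
#' @param band half-width of the baseline band (fraction of baseline).
#' @return minutes after removal.
#' @export
time_to_full_recovery <- function(pop, t_removal, band = 0.05) {
  st <- population_stats(pop)
  sel <- st$time >= t_removal
  tt <- st$time[sel]; m <- st$mean[sel]
  inside <- abs(m - 1) <= band
  if (inside[1]) return(0)
  # mean is below the band after depletion; find the upward crossing
  lo <- 1 - band
  above <- m >= lo
  if (!any(above)) return(NA_real_)
  i <- which(above)[1]
  if (i == 1) return(0)
  t_cross <- tt[i - 1] + (lo - m[i - 1]) / (m[i] - m[i - 1]) * (tt[i] - tt[i - 1])
  t_cross - t_removal
}

#' Minimum auxin pulse duration for complete depletion
#'
#' For each pulse-duration cohort, every cell's minimum smoothed normalized
#' signal after auxin addition (its trough before recovery) is extracted; the
#' cohort has depleted completely if the mean trough lies inside the floor
#' band. Returns the smallest such duration, `NA` if none qualifies.
#'
#' @param samples_by_pulse named list of normalized `aid_population`s; names
#'   are the pulse durations in minutes.
#' @param t_add auxin addition time (min).
#' @param band floor band (from [floor_band()]); default from the first
#'   population's config.
#' @param spar optional fixed smoothing parameter.
#' @return list with `minimum_pulse` (min or `NA`) and the per-duration mean
#'   trough levels (`trough_means`).
#' @export
minimum_pulse_for_depletion <- function(samples_by_pulse, t_add = 240,
                                        band = NULL, spar = NULL) {
  if (length(samples_by_pulse) < 2)
    stop("minimum_pulse_for_depletion: need >= 2 pulse durations", call. = FALSE)
  band <- band %||% floor_band(samples_by_pulse[[1]]$config)
  durs <- as.numeric(names(samples_by_pulse))
  troughs <- vapply(samples_by_pulse, function(pop) {
    mins <- vapply(pop$trajectories, function(tr) {
      sm <- fit_smoothing_spline(tr, spar = spar)
      min(sm$smooth[sm$times >= t_add])
    }, 0)
    mean(mins)
  }, 0)
  ok <- durs[troughs <= band[2]]
  list(minimum_pulse = if (length(ok)) min(ok) else NA_real_,
       trough_means = setNames(troughs, durs))
}
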
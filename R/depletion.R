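#' Maximum depletion rate (most negative slope)
#'
#' The minimum of dSignal/dTime after auxin addition, i.e. the fastest
#' depletion. For a smoothing-spline fit (`aid_smooth`) the analytic spline
#' derivative is used (single-cell convention); for a raw trajectory or a
#' cohort mean trace, first differences over the sampling grid
#' (delta-signal / delta-time, the population convention) are used, each
#' difference attached to the start of its interval. Ties take the earliest
#' time.
#'
#' @param x an `aid_smooth`, an `aid_trajectory`, or a list/data.frame with
#'   `time` and `mean` (e.g. the output of [population_stats()]).
#' @param t_add time of auxin addition (min).
#' @return list with `min_slope` (1/min, <= 0 for depleting signals) and
#'   `time` (min, where it is attained).
#' @export
max_depletion_rate <- function(x, t_add) UseMethod("max_depletion_rate")

#' @export
max_depletion_rate.aid_smooth <- function(x, t_add) {
  sel <- x$times >= t_add
  if (!any(sel))
    stop("max_depletion_rate: no samples after t_add", call. = FALSE)
  d <- x$derivative[sel]; tt <- x$times[sel]
  i <- which.min(d)
  list(min_slope = d[i], time = tt[i])
}

#' @export
max_depletion_rate.aid_trajectory <- function(x, t_add) {
  finite_diff_min_slope(x$times, x$signal, t_add)
}

#' @export
max_depletion_rate.default <- function(x, t_add) {
  finite_diff_min_slope(x$time, x$mean, t_add)
}

finite_diff_min_slope <- function(times, values, t_add) {
  sel <- times >= t_add
  if (sum(sel) < 2)
    stop("max_depletion_rate: no post-addition interval", call. = FALSE)
  tt <- times[sel]; v <- values[sel]
  slopes <- diff(v) / diff(tt)
  i <- which.min(slopes)
  list(min_slope = slopes[i], time = tt[i])
}

cell_window_mean <- function(traj, window) {
  idx <- window_idx(traj$times, window)
  if (length(idx) == 0) return(NA_real_)
  mean(traj$signal[idx])
}

#' Bootstrap estimate of the complete-depletion floor ratio
#'
#' Ratio of the mean autofluorescence of non-fluorescent (wild-type) cells to
#' the mean reporter fluorescence before depletion. The ratio marks the
#' signal level of complete protein depletion on the normalized scale. The
#' 95% CI is obtained nonparametrically by resampling cells in both groups
#' (100 iterations by default): a t-quantile interval around the point
#' estimate with the bootstrap standard error, which holds its nominal
#' coverage at these small group sizes where raw percentile intervals run
#' slightly short.
#'
#' @param wildtype_cells `aid_population` of non-fluorescent cells.
#' @param gfp_cells_pre `aid_population` of reporter cells; only the
#'   pre-depletion `window` is used.
#' @param n_boot bootstrap iterations.
#' @param window time window over which per-cell means are taken (min).
#' @return list of class `aid_floor`: `mean_ratio`, `ci95_low`, `ci95_high`,
#'   `n_boot`, per-group cell counts.
#' @export
estimate_floor <- function(wildtype_cells, gfp_cells_pre, n_boot = 100,
                           window = c(0, 240)) {
  wt <- vapply(wildtype_cells$trajectories, cell_window_mean, 0, window = window)
  gf <- vapply(gfp_cells_pre$trajectories, cell_window_mean, 0, window = window)
  wt <- wt[is.finite(wt)]; gf <- gf[is.finite(gf)]
  if (length(wt) == 0 || length(gf) == 0)
    stop("estimate_floor: empty group", call. = FALSE)
  if (mean(gf) <= 0)
    stop("estimate_floor: nonpositive reporter mean", call. = FALSE)
  ratio <- mean(wt) / mean(gf)
  boot <- replicate(n_boot, {
    mean(sample(wt, replace = TRUE)) / mean(sample(gf, replace = TRUE))
  })
  half <- qt(0.975, df = length(wt) + length(gf) - 2) * sd(boot)
  ci <- ratio + c(-1, 1) * half
  structure(list(mean_ratio = ratio, ci95_low = ci[1], ci95_high = ci[2],
                 n_boot = n_boot, n_wildtype = length(wt), n_gfp = length(gf)),
            class = "aid_floor")
}

#' @export
print.aid_floor <- function(x, ...) {
  cat(sprintf("Complete-depletion floor ratio: %.3f (95%% CI %.3f-%.3f, %d bootstrap iterations)\n",
              x$mean_ratio, x$ci95_low, x$ci95_high, x$n_boot))
  invisible(x)
}

#' Per-cell depletion completeness ratio
#'
#' Mean signal in a window well after auxin addition divided by the mean
#' signal before addition (defaults 500-740 min over 0-240 min). A ratio at
#' the floor level indicates complete depletion; ratios above it, incomplete
#' degradation.
#'
#' @param traj an `aid_trajectory`.
#' @param before,after the two windows (min).
#' @return the ratio (single number, >= 0).
#' @export
completeness_ratio <- function(traj, before = c(0, 240), after = c(500, 740)) {
  b <- cell_window_mean(traj, before)
  a <- cell_window_mean(traj, after)
  if (!is.finite(b) || !is.finite(a))
    stop("completeness_ratio: empty window", call. = FALSE)
  if (b <= 0)
    stop("completeness_ratio: nonpositive pre-addition mean", call. = FALSE)
  a / b
}

#' Cohort summary of completeness ratios
#'
#' @param pop an `aid_population`.
#' @inheritParams completeness_ratio
#' @return list with per-cell `ratios`, `mean`, and t-based `ci95`.
#' @export
cohort_completeness <- function(pop, before = c(0, 240), after = c(500, 740)) {
  r <- vapply(pop$trajectories, completeness_ratio, 0,
              before = before, after = after)
  n <- length(r)
  half <- if (n > 1) qt(0.975, n - 1) * sd(r) / sqrt(n) else 0
  list(ratios = r, mean = mean(r), ci95 = mean(r) + c(-1, 1) * half, n = n)
}

#' Time to reach the complete-depletion floor
#'
#' First time (linear interpolation between samples) at which the trace
#' enters the floor band, measured from auxin addition. `NA` if the floor is
#' never reached. Smoothed traces are recommended to avoid noise-spike
#' crossings.
#'
#' @param x an `aid_smooth` or `aid_trajectory` on the normalized scale.
#' @param t_add time of auxin addition/arrival (min).
#' @param band floor band, `c(lo, hi)` as from [floor_band()].
#' @return minutes from `t_add` to first entry, or `NA`.
#' @export
time_to_floor <- function(x, t_add, band) {
  tt <- x$times
  v <- if (inherits(x, "aid_smooth")) x$smooth else x$signal
  sel <- tt >= t_add
  tt <- tt[sel]; v <- v[sel]
  unname(first_crossing(tt, v, band[2]) - t_add)
}

# first time v drops to <= level, linearly interpolated; NA if never
first_crossing <- function(tt, v, level) {
  below <- v <= level
  if (!any(below)) return(NA_real_)
  i <- which(below)[1]
  if (i == 1) return(tt[1])
  tt[i - 1] + (v[i - 1] - level) / (v[i - 1] - v[i]) * (tt[i] - tt[i - 1])
}

#' Per-cell depletion summary table
#'
#' Combines the per-cell minimum slope (spline derivative), time to the
#' floor band, and completeness ratio into one table.
#'
#' @param pop a baseline-normalized `aid_population`.
#' @param t_add auxin addition time (min).
#' @param before,after completeness windows (min).
#' @param band floor band; default from the population's config.
#' @param spar optional fixed smoothing parameter.
#' @return data.frame with one row per cell.
#' @export
depletion_summary <- function(pop, t_add = 240, before = c(0, 240),
                              after = c(500, 740),
                              band = floor_band(pop$config), spar = NULL) {
  rows <- lapply(pop$trajectories, function(tr) {
    sm <- fit_smoothing_spline(tr, spar = spar)
    ms <- max_depletion_rate(sm, t_add)
    cr <- tryCatch(completeness_ratio(tr, before, after),
                   error = function(e) NA_real_)
    data.frame(cell_id = tr$cell_id, role = tr$role,
               min_slope = ms$min_slope, t_min_slope = ms$time,
               time_to_floor = time_to_floor(sm, t_add, band),
               completeness_ratio = cr)
  })
  do.call(rbind, rows)
}

#' Two-phase exponential decay dose-response fit
#'
#' Fits `y(x) = P (1 - f e^(-K1 x) - (1 - f) e^(-K2 x))` to (concentration,
#' minimum slope) pairs, with the y-intercept constrained to zero by
#' construction. The fast fraction is kept in `[0, 1]` and the rate
#' constants nonnegative; the label-swap symmetry is broken by reporting
#' `K1 >= K2`.
#'
#' @param conc auxin concentrations (mM), >= 5 values.
#' @param rate minimum slopes (1/min) at those concentrations.
#' @return object of class `aid_dose_fit` with `model`, `parameters`
#'   (`P`, `f`, `K1`, `K2`), `rss`, `converged`, and `fitted(x)` access via
#'   [predict_dose()].
#' @export
fit_rate_dose_response <- function(conc, rate) {
  if (length(conc) < 5)
    stop("fit_rate_dose_response: need >= 5 concentrations", call. = FALSE)
  if (all(rate == 0)) {
    return(structure(list(model = "two_phase_decay",
                          parameters = c(P = 0, f = 0.5, K1 = 50, K2 = 5),
                          rss = 0, converged = TRUE),
                     class = "aid_dose_fit"))
  }
  df <- data.frame(x = conc, y = rate)
  start <- list(P = rate[which.max(conc)], f = 0.5, K1 = 50, K2 = 5)
  fit <- tryCatch(
    nlsLM(y ~ P * (1 - f * exp(-K1 * x) - (1 - f) * exp(-K2 * x)),
          data = df, start = start,
          lower = c(P = -Inf, f = 0, K1 = 0, K2 = 0),
          upper = c(P = Inf, f = 1, K1 = Inf, K2 = Inf),
          control = nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(model = "two_phase_decay", parameters = NULL,
                          rss = NA_real_, converged = FALSE,
                          diagnostics = conditionMessage(fit)),
                     class = "aid_dose_fit"))
  }
  p <- coef(fit)
  if (p["K1"] < p["K2"]) {   # canonical order: K1 fast
    p[c("K1", "K2")] <- p[c("K2", "K1")]
    p["f"] <- 1 - p["f"]
  }
  structure(list(model = "two_phase_decay", parameters = p,
                 rss = sum(residuals(fit)^2), converged = TRUE),
            class = "aid_dose_fit")
}

#' Constrained log-logistic completeness dose-response fit
#'
#' Fits `ratio(x) = base + (1 - base) / (1 + 10^((log10 x - log10 EC50) h))`
#' to (concentration, completeness ratio) pairs: a decreasing log-dose curve
#' with variable slope. The top asymptote is fixed at 1 (no depletion at
#' zero dose) and the base at the supplied floor ratio (complete depletion
#' at saturating dose); only log10(EC50) and the Hill slope h are free.
#'
#' @param conc auxin concentrations (mM), > 0, >= 5 values.
#' @param ratio completeness ratios.
#' @param base fixed lower asymptote, in (0, 1) (the floor ratio).
#' @return an `aid_dose_fit` with parameters `log10_ec50`, `hill`, plus the
#'   fixed `base`.
#' @export
fit_completeness_dose_response <- function(conc, ratio, base) {
  if (length(conc) < 5)
    stop("fit_completeness_dose_response: need >= 5 concentrations",
         call. = FALSE)
  if (base <= 0 || base >= 1)
    stop("fit_completeness_dose_response: base must be in (0, 1)",
         call. = FALSE)
  df <- data.frame(lx = log10(conc), y = ratio)
  fit <- tryCatch(
    nlsLM(y ~ base + (1 - base) / (1 + 10^((lx - le) * h)),
          data = df, start = list(le = median(df$lx), h = 1),
          lower = c(le = -Inf, h = 0),
          control = nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(model = "log_logistic", parameters = NULL,
                          base = base, rss = NA_real_, converged = FALSE,
                          diagnostics = conditionMessage(fit)),
                     class = "aid_dose_fit"))
  }
  p <- coef(fit)
  structure(list(model = "log_logistic",
                 parameters = c(log10_ec50 = unname(p["le"]),
                                hill = unname(p["h"])),
                 base = base, rss = sum(residuals(fit)^2), converged = TRUE),
            class = "aid_dose_fit")
}

#' Evaluate a fitted dose-response curve
#'
#' @param fit an `aid_dose_fit`.
#' @param x concentrations (mM).
#' @return fitted values.
#' @export
predict_dose <- function(fit, x) {
  stopifnot(inherits(fit, "aid_dose_fit"))
  if (!isTRUE(fit$converged)) stop("dose fit did not converge", call. = FALSE)
  p <- fit$parameters
  if (fit$model == "two_phase_decay") {
    p["P"] * (1 - p["f"] * exp(-p["K1"] * x) -
                (1 - p["f"]) * exp(-p["K2"] * x))
  } else {
    fit$base + (1 - fit$base) /
      (1 + 10^((log10(x) - p["log10_ec50"]) * p["hill"]))
  }
}

#' @export
print.aid_dose_fit <- function(x, ...) {
  cat(sprintf("Dose-response fit (%s): %s\n", x$model,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  if (!is.null(x$parameters)) print(signif(x$parameters, 4))
  invisible(x)
}

#' Intercellular variability slope
#'
#' Change of the pointwise population SD of the normalized signal per time
#' interval over the depletion window. A positive mean slope means the SD is
#' rising (cells respond at different times: a variable response); a negative
#' one means the response is uniform and variability collapses towards the
#' floor.
#'
#' @param pop a normalized `aid_population` on a common grid (>= 2 cells).
#' @param window analysis window (min), typically the ~120 min after auxin
#'   addition.
#' @return list with `times` (interval starts), `slopes` (delta-SD/delta-t),
#'   and `mean_slope` (the summary sign).
#' @export
variability_slope <- function(pop, window) {
  st <- population_stats(pop)
  idx <- window_idx(st$time, window)
  if (length(idx) < 2)
    stop("variability_slope: window too narrow", call. = FALSE)
  tt <- st$time[idx]; s <- st$sd[idx]
  slopes <- diff(s) / diff(tt)
  list(times = tt[-length(tt)], slopes = slopes, mean_slope = mean(slopes))
}

#' Mother-daughter depletion delay
#'
#' Per-cell time to half depletion: the first crossing (linear interpolation)
#' of the midpoint between the normalized baseline (1) and the floor. The
#' delay estimate is the Hodges-Lehmann median of all daughter-minus-mother
#' differences, with a Wilcoxon rank-sum test p-value.
#'
#' @param pop an `aid_population` containing both roles (>= 3 cells each);
#'   trajectories are normalized internally per cell over their observed
#'   pre-addition samples.
#' @param t_add auxin addition/arrival time (min).
#' @param floor floor level on the normalized scale; default from config.
#' @return list with `delay` (min), `p_value`, per-role crossing times.
#' @export
compare_mother_daughter <- function(pop, t_add = 240,
                                    floor = pop$config$af_floor) {
  roles <- vapply(pop$trajectories, `[[`, "", "role")
  if (sum(roles == "mother") < 3 || sum(roles == "daughter") < 3)
    stop("compare_mother_daughter: need >= 3 cells per role", call. = FALSE)
  thr <- (1 + floor) / 2
  cross <- vapply(pop$trajectories, function(tr) {
    trn <- normalize_baseline(tr, window = c(min(tr$times), t_add))
    sel <- trn$times >= t_add
    first_crossing(trn$times[sel], trn$signal[sel], thr) - t_add
  }, 0)
  tm <- cross[roles == "mother"]; td <- cross[roles == "daughter"]
  tm <- tm[is.finite(tm)]; td <- td[is.finite(td)]
  if (length(tm) < 3 || length(td) < 3)
    stop("compare_mother_daughter: too few cells reach half depletion",
         call. = FALSE)
  delay <- median(outer(td, tm, "-"))
  pw <- suppressWarnings(wilcox.test(td, tm))
  list(delay = delay, p_value = pw$p.value,
       mother_times = tm, daughter_times = td)
}
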
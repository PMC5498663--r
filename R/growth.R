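#' Single-cell growth rates from budding events
#'
#' The single-cell doubling time DT is the interval between two consecutive
#' budding events; the growth rate is GR = ln(2)/DT. Rates are attached to
#' the midpoint of their interval for time-resolved analyses.
#'
#' @param budding_times budding event times of one cell (min).
#' @param cell_id optional identifier.
#' @return data.frame of class `aid_growth`: `cell_id`, `t_mid`, `dt_min`,
#'   `gr_per_min`; empty with < 2 events.
#' @export
#' @examples
#' growth_rates_from_budding(c(0, 100, 200))$gr_per_min  # ln(2)/100 each
growth_rates_from_budding <- function(budding_times, cell_id = "cell1") {
  bt <- sort(budding_times)
  if (length(bt) < 2) {
    out <- data.frame(cell_id = character(0), t_mid = numeric(0),
                      dt_min = numeric(0), gr_per_min = numeric(0))
    return(structure(out, class = c("aid_growth", "data.frame")))
  }
  dt <- diff(bt)
  out <- data.frame(cell_id = cell_id,
                    t_mid = (bt[-1] + bt[-length(bt)]) / 2,
                    dt_min = dt, gr_per_min = log(2) / dt)
  structure(out, class = c("aid_growth", "data.frame"))
}

#' Pool growth records over a population
#'
#' @param pop an `aid_population`.
#' @return pooled `aid_growth` data.frame over all cells.
#' @export
cohort_growth <- function(pop) {
  out <- do.call(rbind, lapply(pop$trajectories, function(tr) {
    growth_rates_from_budding(tr$budding_times, tr$cell_id)
  }))
  structure(out, class = c("aid_growth", "data.frame"))
}

#' One-phase exponential association fit of growth-rate recovery
#'
#' Fits `GR(t) = plateau + (y0 - plateau) e^(-K t)` to (time, growth rate)
#' pairs after auxin removal, with the plateau fixed to the average growth
#' rate of unperturbed control cells. If the data start at the plateau the
#' rate constant is unidentifiable and the fit is flagged.
#'
#' @param time times since removal (min), >= 4 points.
#' @param gr growth rates (1/min).
#' @param plateau fixed asymptote (1/min).
#' @return list of class `aid_recovery_fit`: `K`, `K_se`, `y0`, `plateau`,
#'   `rss`, `converged`, `identifiable`.
#' @export
fit_growth_recovery <- function(time, gr, plateau) {
  if (length(time) < 4)
    stop("fit_growth_recovery: need >= 4 points", call. = FALSE)
  df <- data.frame(t = time, y = gr)
  # deficit relative to plateau; near-zero initial deficit -> unidentifiable K
  y0_guess <- mean(df$y[df$t <= quantile(df$t, 0.2)])
  if (abs(y0_guess - plateau) < 0.02 * abs(plateau)) {
    return(structure(list(K = NA_real_, K_se = NA_real_, y0 = y0_guess,
                          plateau = plateau, rss = NA_real_,
                          converged = TRUE, identifiable = FALSE),
                     class = "aid_recovery_fit"))
  }
  fit <- tryCatch(
    nlsLM(y ~ plateau + (y0 - plateau) * exp(-K * t), data = df,
          start = list(y0 = y0_guess, K = 0.005),
          lower = c(y0 = -Inf, K = 1e-6),
          control = nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    return(structure(list(K = NA_real_, K_se = NA_real_, y0 = NA_real_,
                          plateau = plateau, rss = NA_real_,
                          converged = FALSE, identifiable = NA,
                          diagnostics = conditionMessage(fit)),
                     class = "aid_recovery_fit"))
  }
  s <- summary(fit)$coefficients
  structure(list(K = coef(fit)[["K"]], K_se = s["K", "Std. Error"],
                 y0 = coef(fit)[["y0"]], plateau = plateau,
                 rss = sum(residuals(fit)^2), converged = TRUE,
                 identifiable = TRUE),
            class = "aid_recovery_fit")
}

#' Time for the fitted recovery curve to approach the plateau
#'
#' @param fit an `aid_recovery_fit`.
#' @param frac closeness criterion as a fraction of the plateau (default 5%).
#' @return minutes since removal at which the fitted curve is within
#'   `frac * plateau` of the plateau (0 if it starts there).
#' @export
time_to_plateau <- function(fit, frac = 0.05) {
  stopifnot(inherits(fit, "aid_recovery_fit"))
  if (!isTRUE(fit$identifiable)) return(0)
  deficit0 <- abs(fit$plateau - fit$y0)
  target <- frac * abs(fit$plateau)
  if (deficit0 <= target) return(0)
  log(deficit0 / target) / fit$K
}

#' @export
print.aid_recovery_fit <- function(x, ...) {
  if (isTRUE(x$identifiable)) {
    cat(sprintf("Growth recovery: K = %.4g/min (SE %.2g), y0 = %.4g, plateau = %.4g/min\n",
                x$K, x$K_se, x$y0, x$plateau))
  } else if (!isTRUE(x$converged)) {
    cat("Growth recovery: fit did not converge:", x$diagnostics, "\n")
  } else {
    cat("Growth recovery: data at plateau, rate constant unidentifiable\n")
  }
  invisible(x)
}

#' Kruskal-Wallis omnibus test with Dunn's all-pairs post-test
#'
#' Compares per-cycle growth-rate distributions across conditions with the
#' Kruskal-Wallis rank test, followed by Dunn's z post-test for all pairs
#' (tie-corrected, Bonferroni-adjusted by default), annotated with the usual
#' significance stars (p < 0.05 *, < 0.01 **, < 0.001 ***).
#'
#' @param records_by_group named list of numeric vectors (>= 2 groups with
#'   >= 3 values each), e.g. growth rates per condition.
#' @param p_adjust p-value adjustment method for the pairwise tests.
#' @return list with `kruskal` (htest) and `pairwise` (data.frame with
#'   `group1`, `group2`, `z`, `p`, `p_adj`, `stars`).
#' @export
compare_groups <- function(records_by_group, p_adjust = "bonferroni") {
  if (length(records_by_group) < 2)
    stop("compare_groups: need >= 2 groups", call. = FALSE)
  n_i <- lengths(records_by_group)
  if (any(n_i < 3)) stop("compare_groups: each group needs >= 3 values",
                         call. = FALSE)
  kw <- kruskal.test(records_by_group)
  x <- unlist(records_by_group, use.names = FALSE)
  g <- rep(names(records_by_group), n_i)
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  pairs <- combn(names(records_by_group), 2)
  res <- apply(pairs, 2, function(p2) {
    i <- p2[1]; j <- p2[2]
    se <- sqrt((N * (N + 1) / 12 - tie_term) * (1 / n_i[[i]] + 1 / n_i[[j]]))
    z <- (rbar[[i]] - rbar[[j]]) / se
    c(z = z, p = 2 * pnorm(-abs(z)))
  })
  padj <- pmin(p.adjust(res["p", ], method = p_adjust), 1)
  stars <- cut(padj, c(-Inf, 0.001, 0.01, 0.05, Inf),
               labels = c("***", "**", "*", "ns"))
  list(kruskal = kw,
       pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                             z = res["z", ], p = res["p", ], p_adj = padj,
                             stars = as.character(stars)))
}

#' Percent growth-rate reduction relative to a reference condition
#'
#' `100 (1 - mean GR_condition / mean GR_reference)` for each condition.
#'
#' @param records_by_group named list of growth-rate vectors.
#' @param reference name of the reference group.
#' @return named numeric vector of percent reductions (reference = 0).
#' @export
growth_reduction_summary <- function(records_by_group, reference) {
  if (!reference %in% names(records_by_group))
    stop("growth_reduction_summary: unknown reference group", call. = FALSE)
  ref <- mean(records_by_group[[reference]])
  if (!is.finite(ref) || ref <= 0)
    stop("growth_reduction_summary: nonpositive reference growth rate",
         call. = FALSE)
  vapply(records_by_group, function(v) 100 * (1 - mean(v) / ref), 0)
}
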
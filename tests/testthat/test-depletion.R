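test_that("minimum slope: finite differences on the grid, ties earliest", {
  tt <- seq(0, 300, by = 5)
  flat <- make_traj(rep(1, length(tt)))
  expect_equal(max_depletion_rate(flat, 0)$min_slope, 0)
  # normalized exponential decay starting at t_add = 100: first-interval
  # finite difference is -(1 - e^(-k dt))/dt
  k <- 0.25
  sig <- ifelse(tt < 100, 1, exp(-k * (tt - 100)))
  ms <- max_depletion_rate(make_traj(sig), t_add = 100)
  expect_equal(ms$min_slope, -(1 - exp(-k * 5)) / 5, tolerance = 1e-12)
  expect_equal(ms$time, 100)
  expect_error(max_depletion_rate(flat, 400), "post-addition")
})

test_that("floor ratio estimator and its bootstrap behave on known groups", {
  wt <- make_pop(lapply(1:13, function(i)
    make_traj(rep(0.288, 50), cell_id = paste0("w", i))))
  gf <- make_pop(lapply(1:15, function(i)
    make_traj(rep(1, 50), cell_id = paste0("g", i))))
  set.seed(6)
  fl <- estimate_floor(wt, gf, n_boot = 100)
  expect_equal(fl$mean_ratio, 0.288, tolerance = 1e-12)
  expect_equal(fl$ci95_low, 0.288, tolerance = 1e-9)
  same <- estimate_floor(gf, gf, n_boot = 50)
  expect_equal(same$mean_ratio, 1)
  expect_error(estimate_floor(make_pop(list()), gf), "empty")
})

test_that("completeness ratio compares post- to pre-addition windows", {
  tt_n <- 160
  flat <- make_traj(rep(2, tt_n))
  expect_equal(completeness_ratio(flat), 1)
  sig <- c(rep(1, 49), rep(0.3, tt_n - 49))
  expect_equal(completeness_ratio(make_traj(sig)), 0.3, tolerance = 1e-12)
  expect_error(completeness_ratio(make_traj(rep(1, 30))), "empty window")
})

test_that("two-phase decay fit recovers generating parameters exactly-ish", {
  x <- c(5e-4, 0.005, 0.01, 0.025, 0.05, 0.1, 0.25, 0.5)
  truth <- c(P = -0.14, f = 0.6, K1 = 50, K2 = 5)
  y <- truth["P"] * (1 - truth["f"] * exp(-truth["K1"] * x) -
                       (1 - truth["f"]) * exp(-truth["K2"] * x))
  fit <- fit_rate_dose_response(x, y)
  expect_true(fit$converged)
  expect_equal(unname(fit$parameters[names(truth)]), unname(truth),
               tolerance = 0.01)
  expect_equal(unname(predict_dose(fit, 0)), 0)  # constrained intercept
  z <- fit_rate_dose_response(x, rep(0, length(x)))
  expect_equal(unname(z$parameters["P"]), 0)
  expect_equal(z$rss, 0)
  expect_error(fit_rate_dose_response(x[1:3], y[1:3]), ">= 5")
})

test_that("constrained log-logistic fit recovers EC50 and slope", {
  x <- c(5e-4, 0.0025, 0.005, 0.01, 0.025, 0.05, 0.1, 0.25, 0.5)
  base <- 0.288; ec50 <- 0.02; h <- 1.5
  y <- base + (1 - base) / (1 + 10^((log10(x) - log10(ec50)) * h))
  fit <- fit_completeness_dose_response(x, y, base = base)
  expect_true(fit$converged)
  expect_equal(10^fit$parameters[["log10_ec50"]], ec50, tolerance = 0.02)
  expect_equal(fit$parameters[["hill"]], h, tolerance = 0.02)
  expect_equal(unname(predict_dose(fit, 1e6)), base, tolerance = 1e-4)
  expect_equal(unname(predict_dose(fit, 1e-9)), 1, tolerance = 1e-4)
  expect_error(fit_completeness_dose_response(x, y, base = 1.2), "base")
})

test_that("variability slope is negative at saturating and positive at low auxin", {
  ident <- make_pop(lapply(1:5, function(i)
    make_traj(rep(1, 100), cell_id = paste0("c", i))))
  vs0 <- variability_slope(ident, window = c(0, 400))
  expect_equal(vs0$mean_slope, 0)
  cfg <- sim_config()
  vs_at <- function(conc, seed) {
    sch <- schedule_step(conc, t_on = 240, horizon = 420)
    pop <- normalize_baseline(simulate_experiment(cfg, sch, 15, seed = seed))
    variability_slope(pop, window = c(240, 360))$mean_slope
  }
  expect_lt(vs_at(0.5, 31), 0)
  expect_gt(vs_at(0.025, 32), 0)
})

test_that("mother-daughter comparison is null when kinetics are identical", {
  cfg <- sim_config(daughter_delay = 0)
  sch <- schedule_step(0.5, t_on = 240, horizon = 460)
  pop <- simulate_experiment(cfg, sch, 15, n_daughters = 15, seed = 33)
  md <- compare_mother_daughter(pop, t_add = 240)
  # onset delays are Gamma(2, mean 10): the null estimate scatters by a few
  # minutes at this cohort size
  expect_lt(abs(md$delay), 7.5)
  expect_gt(md$p_value, 0.05)
  expect_error(compare_mother_daughter(
    simulate_experiment(cfg, sch, 5, seed = 1), 240), "per role")
})

test_that("daughter onset delay is recovered across delay settings", {
  sch <- schedule_step(0.5, t_on = 240, horizon = 460)
  for (d in c(5, 10, 40)) {
    cfg <- sim_config(daughter_delay = d)
    pop <- simulate_experiment(cfg, sch, 12, n_daughters = 6, seed = 40 + d)
    md <- compare_mother_daughter(pop, t_add = 240)
    expect_equal(md$delay, d, tolerance = 5 / max(d, 5))
  }
})

test_that("|minimum slope| increases monotonically with concentration", {
  cfg <- sim_config()
  concs <- c(5e-4, 0.005, 0.025, 0.05, 0.1, 0.25, 0.5)
  mins <- vapply(seq_along(concs), function(i) {
    sch <- schedule_step(concs[i], t_on = 240, horizon = 420)
    pop <- normalize_baseline(simulate_experiment(cfg, sch, 20, seed = 50 + i))
    st <- population_stats(pop)
    abs(max_depletion_rate(st, 240)$min_slope)
  }, 0)
  expect_gt(cor(concs, mins, method = "spearman"), 0.9)
})

test_that("floor entry and completeness agree on complete vs incomplete depletion", {
  cfg <- cfg_default()
  band <- floor_band(cfg)
  for (conc in c(0.5, 0.005)) {
    sch <- schedule_step(conc, t_on = 240, horizon = 760)
    pop <- normalize_baseline(simulate_experiment(cfg, sch, 8,
                                                  seed = round(1000 * conc)))
    ds <- depletion_summary(pop, t_add = 240)
    complete <- is.finite(ds$time_to_floor)
    in_band <- ds$completeness_ratio <= band[2] * 1.05
    if (conc == 0.5) expect_true(all(complete) && all(in_band))
    else expect_true(!any(complete) && !any(in_band))
  }
})
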
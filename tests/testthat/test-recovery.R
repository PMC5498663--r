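test_that("cycles are delimited by consecutive buddings", {
  tt <- seq(0, 200, by = 5)
  tr <- new_trajectory("c", tt, rep(1, length(tt)),
                       budding_times = c(0, 100, 200))
  cyc <- segment_cycles(tr, t_removal = 0)
  expect_identical(nrow(cyc), 2L)
  expect_equal(cyc$t_end - cyc$t_start, c(100, 100))
  none <- segment_cycles(new_trajectory("c", tt, rep(1, length(tt))), 0)
  expect_identical(nrow(none), 0L)
})

test_that("noiseless sawtooth: integrals, drop factor and DIL are exact", {
  sw <- make_sawtooth(d = 1.25)
  cyc <- segment_cycles(sw$traj, t_removal = 0)
  expect_identical(nrow(cyc), 4L)
  ok <- is.finite(cyc$diff)
  # synthesis = rise of the cycle, dilution = -(drop at its division)
  rises <- (sw$m * (1.4 - 1))[1:4]
  expect_equal(cyc$synthesis_integral, rises, tolerance = 1e-7)
  expect_equal(cyc$dilution_integral, -(cyc$diff), tolerance = 1e-7)
  # synthesis + dilution = net change across the cycle
  net <- sw$m[2:5] - sw$m[1:4]
  expect_equal(cyc$synthesis_integral + cyc$dilution_integral, net,
               tolerance = 1e-6)
  fit <- fit_max_diff_regression(cyc[rep(1:4, 2), ], n_boot = 50)
  expect_equal(fit$slope, 1 - 1 / 1.25, tolerance = 1e-8)
  expect_equal(dilution_factor(fit)$dil, 1.25, tolerance = 1e-8)
})

test_that("dilution factor algebra and guards", {
  expect_equal(dilution_factor(0), 1)
  expect_equal(dilution_factor(0.5), 2)
  expect_error(dilution_factor(1.2), "non-physical")
  # DIFF orthogonal to MAX: slope ~ 0, DIL ~ 1
  set.seed(12)
  cyc <- data.frame(cell_id = "c", max_signal = runif(40, 0.5, 1.5),
                    diff = rnorm(40, 0, 0.01))
  fit <- fit_max_diff_regression(cyc, n_boot = 100)
  expect_lt(abs(fit$slope), 0.02)
  expect_equal(dilution_factor(fit)$dil, 1, tolerance = 0.03)
  expect_error(fit_max_diff_regression(cyc[1:3, ]), ">= 5")
})

test_that("dilution estimator recovers the generative factor across settings", {
  sch <- schedule_pulse(0.5, t_on = 240, duration = 120, horizon = 1100)
  for (d in c(1.1, 1.2, 1.5, 2.0)) {
    cfg <- sim_config(dil_factor = d)
    # off-default dilution shifts the baseline cycle average, and with it the
    # autofluorescence floor on the normalized scale
    fl <- cfg$af_floor /
      (cfg$af_floor + (1 - cfg$af_floor) * cycle_fixed_point(cfg)$mean)
    pop <- normalize_baseline(simulate_experiment(cfg, sch, 19,
                                                  seed = round(100 * d)))
    cyc <- cohort_cycles(protein_component(pop, fl), t_removal = 360)
    est <- dilution_factor(fit_max_diff_regression(cyc, n_boot = 300))
    expect_equal(est$dil, d, tolerance = 0.05 * d)
    expect_true(est$dil_ci95[1] <= d && d <= est$dil_ci95[2])
  }
})

test_that("per-cycle drop factor is uncorrelated with the peak level", {
  # measurement noise enters both MAX and MAX/MIN of an oscillation, so the
  # raw correlation under noise mixes errors-in-variables with any real
  # association; the noise-free cohort isolates the generative claim of a
  # constant dilution factor across divisions
  cfg <- sim_config(noise_cv = 0)
  sch <- schedule_pulse(0.5, t_on = 240, duration = 120, horizon = 1100)
  pop <- normalize_baseline(simulate_experiment(cfg, sch, 19, seed = 77))
  cyc <- cohort_cycles(protein_component(pop, cfg$af_floor), t_removal = 360)
  cyc <- cyc[is.finite(cyc$diff), ]
  rho <- cor(cyc$max_signal, cyc$max_signal / cyc$min_signal,
             method = "spearman")
  expect_lt(abs(rho), 0.15)
  # the drop factor itself is the configured one, cycle after cycle
  expect_equal(mean(cyc$max_signal / cyc$min_signal), cfg$dil_factor,
               tolerance = 0.01)
})

test_that("recovered fraction maps floor to 0 and baseline to 1", {
  at_floor <- make_pop(lapply(1:5, function(i)
    make_traj(rep(0.288, 100), cell_id = paste0("f", i))))
  expect_equal(fraction_recovered(at_floor, 0, t_removal = 240)$fraction, 0)
  at_base <- make_pop(lapply(1:5, function(i)
    make_traj(rep(1, 100), cell_id = paste0("b", i))))
  expect_equal(fraction_recovered(at_base, 60, t_removal = 240)$fraction, 1)
  expect_error(fraction_recovered(at_base, -10, 240), "before removal")
})

test_that("time to full recovery: trivial and closed-form checks", {
  never <- make_pop(lapply(1:3, function(i)
    make_traj(rep(1, 200), cell_id = paste0("n", i))))
  expect_equal(time_to_full_recovery(never, t_removal = 240), 0)
  # division-free deterministic recovery matches the analytic inversion of
  # dC/dt = k_syn (1 - C/c_cap); without divisions the baseline sits at c_cap
  cfg <- cfg_quiet(t_div_median = 1e7, onset_m_max = 0)
  sch <- schedule_pulse(0.5, t_on = 240, duration = 120, horizon = 1700,
                        delivery = "instant")
  pop <- normalize_baseline(simulate_experiment(cfg, sch, 3, seed = 1))
  ttfr <- time_to_full_recovery(pop, t_removal = 360)
  k <- cfg$k_syn_max / cfg$c_cap
  lam <- k + degradation_rate(0.5, cfg)
  c_rem <- cfg$k_syn_max / lam
  s_base <- cfg$af_floor + (1 - cfg$af_floor) * cfg$c_cap
  c_target <- (0.95 * s_base - cfg$af_floor) / (1 - cfg$af_floor)
  analytic <- -log((cfg$c_cap - c_target) / (cfg$c_cap - c_rem)) / k
  expect_equal(ttfr, analytic, tolerance = 5 / analytic)
})

test_that("minimum depleting pulse shrinks when degradation is faster", {
  run <- function(cfg, seed0) {
    pops <- lapply(c(10, 20), function(dur) {
      sch <- schedule_pulse(0.5, t_on = 240, duration = dur, horizon = 500)
      normalize_baseline(simulate_experiment(cfg, sch, 12, seed = seed0 + dur))
    })
    names(pops) <- c(10, 20)
    minimum_pulse_for_depletion(pops, t_add = 240)$minimum_pulse
  }
  expect_equal(run(sim_config(), 300), 20)
  expect_equal(run(sim_config(k_deg_max = 0.5), 400), 10)
})
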
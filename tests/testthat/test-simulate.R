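test_that("simulated protein component matches the closed-form ODE solution", {
  cfg <- cfg_ode()
  sch <- schedule_step(0.5, t_on = 0, horizon = 200)
  set.seed(1)
  tr <- simulate_cell(cfg, sch, "mother")
  lam <- cfg$k_syn_max / cfg$c_cap +
    degradation_rate(effective_auxin(0.5, sch$ph, cfg), cfg)
  cinf <- cfg$k_syn_max / lam
  analytic <- cinf + (tr$signal[1] - cinf) * exp(-lam * (tr$times - tr$times[1]))
  expect_lt(max(abs(tr$signal - analytic)), 1e-9)
})

test_that("noise-free signals never drop below the autofluorescence floor", {
  cfg <- cfg_quiet()
  sch <- schedule_step(0.5, t_on = 120, horizon = 500)
  pop <- simulate_experiment(cfg, sch, n_mothers = 5, seed = 5)
  for (tr in pop$trajectories)
    expect_gte(min(tr$signal), cfg$af_floor - 1e-12)
})

test_that("identical seeds reproduce identical cohorts", {
  cfg <- sim_config()
  sch <- schedule_pulse(0.5, horizon = 700)
  a <- simulate_experiment(cfg, sch, 3, n_daughters = 2, seed = 42)
  b <- simulate_experiment(cfg, sch, 3, n_daughters = 2, seed = 42)
  expect_identical(a$trajectories, b$trajectories)
})

test_that("unperturbed cycling sits on the periodic fixed point", {
  # no degradation, no noise, fixed cycle length; a newborn daughter divides
  # exactly on the sampling grid, so troughs are sampled exactly
  cfg <- cfg_quiet(t_div_cv = 0, k_deg_max = 0, af_floor = 0)
  sch <- schedule_none(horizon = 600)
  set.seed(3)
  tr <- simulate_cell(cfg, sch, "daughter", birth = 0)
  fp <- cycle_fixed_point(cfg)
  expect_equal(tr$budding_times, c(100, 200, 300, 400, 500, 600))
  troughs <- tr$signal[tr$times %in% c(100, 300, 500)]
  expect_equal(troughs, rep(fp$min, 3), tolerance = 1e-9)
  # peak/trough of the underlying cycle are dil_factor apart
  expect_equal(fp$max / fp$min, cfg$dil_factor, tolerance = 1e-12)
  expect_lte(max(tr$signal), fp$max + 1e-9)
})

test_that("saturating auxin drives an exponential collapse onto the floor", {
  cfg <- cfg_quiet(t_div_median = 1e7, onset_m_max = 0)
  sch <- schedule_step(0.5, t_on = 0, horizon = 300)
  set.seed(2)
  tr <- simulate_cell(cfg, sch, "mother")
  lam <- cfg$k_syn_max / cfg$c_cap + degradation_rate(0.5, cfg)
  # late signal sits at the floor + residual steady state
  cinf <- cfg$k_syn_max / lam
  expect_equal(tail(tr$signal, 1),
               cfg$af_floor + (1 - cfg$af_floor) * cinf, tolerance = 1e-6)
  # log-linear decay of the protein component at rate lambda
  prot <- (tr$signal - cfg$af_floor) / (1 - cfg$af_floor) - cinf
  sel <- tr$times <= 20
  slope <- coef(lm(log(prot[sel]) ~ tr$times[sel]))[2]
  expect_equal(unname(slope), -lam, tolerance = 1e-6)
})

test_that("baseline cohorts are stationary at 1 after normalization", {
  cfg <- sim_config()
  pop <- simulate_experiment(cfg, schedule_none(horizon = 480), 20, seed = 8)
  pn <- normalize_baseline(pop)
  st <- population_stats(pn)
  win <- st$mean[st$time >= 240 & st$time <= 480]
  expect_equal(mean(win), 1, tolerance = 0.03)
})

test_that("expected time to the floor decreases with auxin concentration", {
  cfg <- sim_config()
  mean_ttf <- vapply(c(0.05, 0.1, 0.5), function(conc) {
    sch <- schedule_step(conc, t_on = 240, horizon = 600)
    pop <- normalize_baseline(simulate_experiment(cfg, sch, 10, seed = 91))
    ds <- depletion_summary(pop, t_add = 240, after = c(500, 600))
    mean(ds$time_to_floor, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(mean_ttf) < 0))
})

test_that("NAA and IAA at equal dose give indistinguishable depletion", {
  cfg <- sim_config()
  ttf <- lapply(c("IAA", "NAA"), function(cmp) {
    sch <- schedule_step(0.05, t_on = 240, horizon = 700, compound = cmp)
    pop <- normalize_baseline(simulate_experiment(cfg, sch, 20,
                                                  seed = 70 + nchar(cmp)))
    depletion_summary(pop, t_add = 240, after = c(600, 700))$time_to_floor
  })
  expect_gt(suppressWarnings(wilcox.test(ttf[[1]], ttf[[2]])$p.value), 0.05)
})

test_that("cohort wrapper validates inputs and builds mixed cohorts", {
  cfg <- sim_config()
  sch <- schedule_step(0.5, t_on = 240, horizon = 400)
  expect_error(simulate_experiment(cfg, sch, 0, 0), "at least one")
  pop <- simulate_experiment(cfg, sch, 2, n_daughters = 2, seed = 9)
  roles <- vapply(pop$trajectories, `[[`, "", "role")
  expect_identical(sum(roles == "daughter"), 2L)
  # daughters are born shortly before auxin arrival
  births <- vapply(pop$trajectories, `[[`, 0, "birth")
  expect_true(all(births[roles == "daughter"] == 240 - 3 * cfg$sample_period))
})
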
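test_that("growth rates derive from inter-budding doubling times", {
  gr <- growth_rates_from_budding(c(0, 100, 200))
  expect_equal(gr$dt_min, c(100, 100))
  expect_equal(gr$gr_per_min, rep(log(2) / 100, 2))
  expect_equal(gr$t_mid, c(50, 150))
  expect_equal(growth_rates_from_budding(c(0, log(2)))$gr_per_min, 1)
  expect_identical(nrow(growth_rates_from_budding(50)), 0L)
  # GR/DT round trip
  dts <- c(80, 100, 123.4)
  expect_equal(log(2) / growth_rates_from_budding(cumsum(c(0, dts)))$gr_per_min,
               dts)
})

test_that("one-phase association fit recovers the rate constant", {
  plateau <- 0.007
  tt <- seq(0, 1200, by = 25)
  noiseless <- plateau + (0.0035 - plateau) * exp(-0.006 * tt)
  fit <- fit_growth_recovery(tt, noiseless, plateau)
  expect_true(fit$identifiable)
  expect_equal(fit$K, 0.006, tolerance = 0.01)
  set.seed(13)
  for (K in c(0.003, 0.006, 0.012)) {
    t2 <- runif(100, 0, 1200)
    y <- plateau + (0.0035 - plateau) * exp(-K * t2) + rnorm(100, 0, 3e-4)
    f2 <- fit_growth_recovery(t2, y, plateau)
    expect_equal(f2$K, K, tolerance = 0.1)
  }
  flat <- fit_growth_recovery(tt, rep(plateau, length(tt)) * exp(rnorm(length(tt), 0, 1e-4)),
                              plateau)
  expect_false(isTRUE(flat$identifiable))
  expect_equal(flat$y0, plateau, tolerance = 0.02)
  expect_equal(time_to_plateau(flat), 0)
  expect_error(fit_growth_recovery(1:3, 1:3, 1), ">= 4")
})

test_that("group comparison: omnibus + Dunn post-test with star thresholds", {
  set.seed(14)
  a <- rnorm(40, 0.007, 5e-4)
  same <- compare_groups(list(g1 = a, g2 = a + 0, g3 = sample(a)))
  expect_gt(same$kruskal$p.value, 0.05)
  expect_true(all(same$pairwise$stars == "ns"))
  shifted <- compare_groups(list(ctrl = a, low = a * 0.65))
  expect_lt(shifted$kruskal$p.value, 0.001)
  expect_identical(shifted$pairwise$stars, "***")
  expect_error(compare_groups(list(a = a)), ">= 2 groups")
  expect_error(compare_groups(list(a = a, b = 1)), ">= 3 values")
})

test_that("percent growth reduction is 0 at reference and dose-monotone", {
  g <- list(ref = c(0.007, 0.0071), x = c(0.005, 0.0048))
  out <- growth_reduction_summary(g, "ref")
  expect_equal(out[["ref"]], 0)
  expect_gt(out[["x"]], 25)
  expect_error(growth_reduction_summary(g, "nope"), "unknown reference")
  cfg <- sim_config()
  reds <- vapply(c(5e-4, 0.01, 0.1), function(conc) {
    sch <- schedule_step(conc, t_on = 0, horizon = 700)
    gi <- cohort_growth(simulate_experiment(cfg, sch, 10,
                                            seed = round(conc * 1e5)))
    schc <- schedule_none(horizon = 700)
    gc_ <- cohort_growth(simulate_experiment(cfg, schc, 10, seed = 2))
    growth_reduction_summary(list(ctrl = gc_$gr_per_min,
                                  trt = gi$gr_per_min), "ctrl")[["trt"]]
  }, 0)
  expect_true(all(diff(reds) > 0))
})
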
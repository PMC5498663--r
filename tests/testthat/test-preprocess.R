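test_that("modal-grey background subtraction picks the mode, not the mean", {
  expect_equal(subtract_background(rep(7, 100), 12), 5)
  # bimodal frame dominated by a background peak near 10
  set.seed(4)
  frame <- c(rnorm(900, 10, 0.3), rnorm(100, 50, 0.3))
  expect_equal(subtract_background(frame, 20), 10, tolerance = 0.5)
  expect_error(subtract_background(numeric(0), 1), "empty")
})

test_that("baseline normalization divides by the window mean and is idempotent", {
  tr <- make_traj(rep(5, 60))
  expect_equal(normalize_baseline(tr)$signal, rep(1, 60))
  tr2 <- make_traj(c(rep(2, 49), rep(3, 11)))  # window [0,240] mean 2
  expect_equal(tail(normalize_baseline(tr2)$signal, 1), 1.5)
  set.seed(11)
  tr3 <- make_traj(runif(60, 0.5, 2))
  once <- normalize_baseline(tr3)
  expect_equal(normalize_baseline(once)$signal, once$signal, tolerance = 1e-12)
  expect_error(normalize_baseline(make_traj(rep(0, 60))), "window mean")
})

test_that("spline derivative is exact on lines and accurate on exponentials", {
  tt <- seq(0, 300, by = 5)
  lin <- make_traj(2 + 0.01 * tt)
  sm <- fit_smoothing_spline(lin)
  expect_lt(max(abs(sm$derivative - 0.01)), 1e-6)
  k <- 0.02
  ex <- make_traj(exp(-k * tt))
  sme <- fit_smoothing_spline(ex)
  mid <- tt >= 50 & tt <= 250
  rel <- abs(sme$derivative[mid] - (-k * exp(-k * tt[mid]))) /
    (k * exp(-k * tt[mid]))
  expect_lt(max(rel), 0.02)
  expect_error(fit_smoothing_spline(make_traj(1:5)), "at least 8")
})

test_that("spline derivative integrates back to the smooth values", {
  tt <- seq(0, 300, by = 5)
  tr <- make_traj(1 + 0.5 * sin(tt / 60))
  sm <- fit_smoothing_spline(tr)
  fine <- seq(0, 300, by = 0.05)
  d <- predict_smooth(sm, fine, deriv = 1)
  s <- predict_smooth(sm, fine)
  cumint <- c(0, cumsum((d[-1] + d[-length(d)]) / 2 * diff(fine)))
  expect_lt(max(abs(cumint - (s - s[1]))), 1e-6)
})

test_that("population statistics are pointwise and grid-checked", {
  tr <- make_traj(rep(1, 50))
  pop <- make_pop(list(tr, tr, tr))
  st <- population_stats(pop)
  expect_true(all(st$sd == 0))
  pop2 <- make_pop(list(make_traj(rep(0, 50)), make_traj(rep(2, 50))))
  st2 <- population_stats(pop2)
  expect_true(all(st2$mean == 1))
  expect_true(all(abs(st2$sd - sqrt(2)) < 1e-12))
  short <- make_traj(rep(1, 30))
  expect_error(population_stats(make_pop(list(tr, short))), "common time grid")
  # SD of copies of one trajectory plus iid noise recovers the noise level
  set.seed(21)
  base <- 1 + 0.5 * sin(seq(0, 245, by = 5) / 40)
  noisy <- lapply(seq_len(50), function(i)
    make_traj(base + rnorm(length(base), 0, 0.1), cell_id = paste0("c", i)))
  stn <- population_stats(make_pop(noisy))
  expect_equal(mean(stn$sd), 0.1, tolerance = 0.15)
})
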
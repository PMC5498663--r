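#' Floor band of complete depletion
#'
#' Signal levels indistinguishable from cellular autofluorescence:
#' `af_floor` plus/minus two measurement-noise standard deviations
#' (noise SD at the floor = `noise_cv * af_floor`). A trajectory "reaches the
#' floor" when it first enters this band.
#'
#' @param config an [sim_config()].
#' @return numeric of length 2, `c(lo, hi)` on the baseline-normalized scale.
#' @export
floor_band <- function(config = sim_config()) {
  half <- 2 * config$noise_cv * config$af_floor
  c(lo = config$af_floor - half, hi = config$af_floor + half)
}

lnorm_sdlog <- function(cv) sqrt(log(1 + cv^2))

# growth-defect fraction r(t) on a grid: instantaneous rise while auxin is
# present, exponential relaxation (rate growth_recovery_k) after removal
relaxed_reduction <- function(r_inst, tg, k_rec) {
  if (all(r_inst == 0) || k_rec == 0) {
    if (k_rec == 0) return(cummax(r_inst)) else return(r_inst)
  }
  # r(t) = max_{s<=t} r_inst(s) e^{-k (t - s)}, computed via cummax
  ekt <- k_rec * (tg - tg[1])
  pmax(r_inst, exp(-ekt + log(cummax(pmax(r_inst, 1e-300) * exp(ekt - max(ekt))))
                   + max(ekt)))
}

# division times of one cell by integrating cycle progress at rate
# (1 - r(t))/t_div_median; each cycle needs a lognormal(median 1, cv) amount
# of progress. Returns continuous event times.
draw_divisions <- function(birth, horizon, tg, r, config, phase0) {
  dt <- diff(tg)
  rate <- (1 - r) / config$t_div_median
  prog <- c(0, cumsum((rate[-length(rate)] + rate[-1]) / 2 * dt))
  total <- prog[length(prog)]
  sdlog <- lnorm_sdlog(config$t_div_cv)
  draw_len <- function(n) if (sdlog == 0) rep(1, n) else rlnorm(n, 0, sdlog)
  lens <- draw_len(ceiling(total * 2) + 5)
  lens[1] <- lens[1] * (1 - phase0)   # partial first cycle for mothers
  thr <- cumsum(lens)
  while (thr[length(thr)] < total) {  # extremely unlikely; top up
    lens2 <- draw_len(5)
    thr <- c(thr, thr[length(thr)] + cumsum(lens2))
  }
  thr <- thr[thr <= total]
  if (length(thr) == 0) return(numeric(0))
  idx <- findInterval(thr, prog, rightmost.closed = TRUE)
  # linear interpolation of the crossing time
  frac <- (thr - prog[idx]) / pmax(prog[idx + 1] - prog[idx], 1e-300)
  tg[idx] + frac * dt[idx]
}

#' Simulate one single-cell fluorescence trajectory
#'
#' Forward model of a degron-tagged reporter in a dividing yeast cell. The
#' protein component C follows the linear ODE
#' `dC/dt = k_syn_max (1 - C/c_cap) - k_deg(A_eff(t - tau)) C`, solved in
#' closed form on every interval of constant coefficients; divisions drop C
#' by `dil_factor` instantaneously. Each cell sees the auxin profile delayed
#' by its own onset lag tau ~ Gamma(shape 2, dose-dependent mean), plus
#' `daughter_delay` for daughters. Division timing integrates cycle progress
#' at rate `(1 - r(t))/t_div_median` with lognormal cycle-length variation,
#' where the growth defect r(t) rises instantaneously with auxin+light and
#' relaxes at `growth_recovery_k` after removal. The emitted signal is
#' `(af_floor + (1 - af_floor) C)` times lognormal measurement noise, sampled
#' every `sample_period` minutes.
#'
#' Cells start at the periodic steady state of the unperturbed division cycle
#' ([cycle_fixed_point()]); mothers at a uniformly drawn cycle phase,
#' daughters (born at `birth`) at the post-division trough.
#'
#' Uses the current R RNG stream; seed via [set.seed()] or use
#' [simulate_experiment()] for reproducible cohorts.
#'
#' @param config an [sim_config()].
#' @param schedule an [auxin_schedule()].
#' @param role `"mother"` or `"daughter"`.
#' @param cell_id identifier stored in the trajectory.
#' @param birth time the cell appears (min; daughters are typically born just
#'   before auxin arrival).
#' @param reporter if `FALSE`, simulate a non-fluorescent (wild-type) cell:
#'   the signal is autofluorescence plus noise only.
#' @return object of class `aid_trajectory`: list with `cell_id`, `role`,
#'   `times`, `signal`, `budding_times` (grid-aligned observation times),
#'   `schedule_id`, `birth`.
#' @export
simulate_cell <- function(config, schedule, role = c("mother", "daughter"),
                          cell_id = "cell1", birth = 0, reporter = TRUE) {
  role <- match.arg(role)
  stopifnot(inherits(config, "aid_sim_config"), inherits(schedule, "aid_schedule"))
  dt_samp <- config$sample_period
  horizon <- schedule$horizon
  t0 <- ceiling(birth / dt_samp) * dt_samp
  times <- seq(t0, horizon, by = dt_samp)
  if (length(times) < 2) stop("horizon too short for the sampling grid")

  # --- cell-specific onset delay ------------------------------------------
  segs <- schedule$segments
  a_max <- if (nrow(segs)) max(segs$conc) else 0
  phase0 <- if (role == "mother") runif(1) else 0
  if (a_max > 0) {
    m <- config$onset_m_max * config$onset_ec50 / (a_max + config$onset_ec50)
    tau <- rgamma(1, shape = 2, scale = m / 2)
  } else tau <- 0
  if (role == "daughter") tau <- tau + config$daughter_delay

  # --- growth defect and division events ----------------------------------
  tg <- seq(birth, horizon, by = 0.5)
  if (tg[length(tg)] < horizon) tg <- c(tg, horizon)
  compound <- if (nrow(segs)) segs$compound[1] else "IAA"
  r_inst <- growth_reduction(profile_eval(schedule, tg), schedule$light_on,
                             compound, config)
  r <- relaxed_reduction(r_inst, tg, config$growth_recovery_k)
  div_times <- draw_divisions(birth, horizon, tg, r, config, phase0)

  # --- protein component: closed form per constant-coefficient piece -------
  fp <- cycle_fixed_point(config)
  k_basal <- config$k_syn_max / config$c_cap
  C0 <- if (reporter) {
    if (role == "mother") {
      config$c_cap + (fp$min - config$c_cap) *
        exp(-k_basal * phase0 * config$t_div_median)
    } else fp$min
  } else 0

  C_samp <- numeric(length(times))
  if (reporter) {
    knots <- profile_knots(schedule) + tau
    knots <- knots[knots > birth & knots < horizon]
    pieces <- sort(unique(c(birth, horizon, knots, div_times)))
    # subdivide pieces where the (shifted) profile varies, for ramp accuracy
    sub <- vector("list", length(pieces) - 1)
    for (i in seq_len(length(pieces) - 1)) {
      a <- pieces[i]; b <- pieces[i + 1]
      ca <- profile_eval(schedule, a - tau); cb <- profile_eval(schedule, b - tau)
      cm <- profile_eval(schedule, (a + b) / 2 - tau)
      sub[[i]] <- if (abs(ca - cb) > 1e-12 || abs(cm - (ca + cb) / 2) > 1e-12) {
        seq(a, b, by = min(0.5, b - a))
      } else a
    }
    bounds <- sort(unique(c(unlist(sub), horizon)))
    is_div <- bounds %in% div_times
    Ccur <- C0
    for (i in seq_len(length(bounds) - 1)) {
      if (is_div[i]) Ccur <- Ccur / config$dil_factor
      a <- bounds[i]; b <- bounds[i + 1]
      A <- profile_eval(schedule, (a + b) / 2 - tau)
      kdeg <- degradation_rate(effective_auxin(A, schedule$ph, config), config)
      lam <- k_basal + kdeg
      Cinf <- if (lam > 0) config$k_syn_max / lam else 0
      sel <- which(times >= a & times < b)
      if (length(sel))
        C_samp[sel] <- Cinf + (Ccur - Cinf) * exp(-lam * (times[sel] - a))
      Ccur <- Cinf + (Ccur - Cinf) * exp(-lam * (b - a))
    }
    C_samp[length(times)] <- Ccur  # sample at the horizon
  }

  clean <- config$af_floor + (1 - config$af_floor) * C_samp
  if (config$noise_cv > 0) {
    s <- lnorm_sdlog(config$noise_cv)
    signal <- clean * rlnorm(length(clean), meanlog = -s^2 / 2, sdlog = s)
  } else signal <- clean

  bud_obs <- unique(ceiling(div_times / dt_samp) * dt_samp)
  bud_obs <- bud_obs[bud_obs >= times[1] & bud_obs <= horizon]

  structure(list(cell_id = cell_id, role = role, times = times,
                 signal = signal, budding_times = bud_obs,
                 schedule_id = schedule$schedule_id, birth = birth),
            class = "aid_trajectory")
}

#' Construct a single-cell trajectory object
#'
#' Validating constructor for externally supplied data (simulated
#' trajectories come from [simulate_cell()]).
#'
#' @param cell_id identifier.
#' @param times sample times (min), strictly increasing on a fixed grid.
#' @param signal fluorescence values (>= 0 on the raw scale).
#' @param budding_times observed budding event times (within the time range).
#' @param role `"mother"` or `"daughter"`.
#' @param schedule_id condition label.
#' @param birth birth time (min).
#' @return an `aid_trajectory`.
#' @export
new_trajectory <- function(cell_id, times, signal, budding_times = numeric(0),
                           role = "mother", schedule_id = "schedule1",
                           birth = times[1]) {
  stopifnot(length(times) == length(signal), length(times) >= 2)
  if (any(diff(times) <= 0))
    stop("new_trajectory: times must be strictly increasing", call. = FALSE)
  if (length(unique(round(diff(times), 9))) > 1)
    stop("new_trajectory: times must lie on a fixed grid", call. = FALSE)
  if (length(budding_times) &&
      (min(budding_times) < min(times) || max(budding_times) > max(times)))
    stop("new_trajectory: budding_times outside the time range", call. = FALSE)
  structure(list(cell_id = cell_id, role = role, times = times,
                 signal = signal, budding_times = sort(budding_times),
                 schedule_id = schedule_id, birth = birth),
            class = "aid_trajectory")
}

#' Bundle trajectories into a population object
#'
#' @param trajectories list of `aid_trajectory` objects.
#' @param config optional [sim_config()].
#' @param schedule optional [auxin_schedule()].
#' @return an `aid_population`.
#' @export
new_population <- function(trajectories, config = NULL, schedule = NULL) {
  stopifnot(all(vapply(trajectories, inherits, TRUE, "aid_trajectory")))
  structure(list(trajectories = trajectories, config = config,
                 schedule = schedule), class = "aid_population")
}

#' @export
print.aid_trajectory <- function(x, ...) {
  cat(sprintf("AID trajectory '%s' (%s): %d samples, %g-%g min, %d buddings\n",
              x$cell_id, x$role, length(x$times), min(x$times), max(x$times),
              length(x$budding_times)))
  invisible(x)
}

#' Simulate a cohort of single-cell trajectories
#'
#' Wrapper over [simulate_cell()] generating independent mother and daughter
#' cells sharing one auxin schedule. Daughters are born shortly (three
#' sampling periods) before auxin first arrives, mimicking newborns retained
#' in the microfluidic device at the medium switch. For `pump` delivery the
#' per-experiment delivery lag is drawn here (Normal(50, 5) min). The whole
#' cohort is reproducible for a fixed `seed`.
#'
#' @param config an [sim_config()].
#' @param schedule an [auxin_schedule()].
#' @param n_mothers,n_daughters cohort composition (total >= 1).
#' @param reporter `FALSE` simulates non-fluorescent wild-type cells.
#' @param seed RNG seed; defaults to `config$seed`.
#' @return object of class `aid_population`: list with `trajectories`,
#'   `config`, `schedule`.
#' @export
#' @examples
#' pop <- simulate_experiment(sim_config(), schedule_step(0.5, horizon = 400),
#'                            n_mothers = 3, seed = 7)
#' length(pop$trajectories)
simulate_experiment <- function(config, schedule, n_mothers,
                                n_daughters = 0, reporter = TRUE,
                                seed = config$seed) {
  stopifnot(inherits(config, "aid_sim_config"), inherits(schedule, "aid_schedule"))
  n_mothers <- as.integer(n_mothers); n_daughters <- as.integer(n_daughters)
  if (n_mothers + n_daughters < 1)
    stop("simulate_experiment: need at least one cell", call. = FALSE)
  set.seed(seed)
  if (schedule$delivery == "pump" && is.null(schedule$pump_lag))
    schedule$pump_lag <- rnorm(1, 50, 5)
  arr <- first_arrival(schedule)
  d_birth <- if (is.finite(arr)) {
    max(0, arr - 3 * config$sample_period)
  } else 0
  trajs <- vector("list", n_mothers + n_daughters)
  for (i in seq_len(n_mothers)) {
    trajs[[i]] <- simulate_cell(config, schedule, "mother",
                                cell_id = sprintf("m%02d", i),
                                reporter = reporter)
  }
  for (j in seq_len(n_daughters)) {
    trajs[[n_mothers + j]] <- simulate_cell(config, schedule, "daughter",
                                            cell_id = sprintf("d%02d", j),
                                            birth = d_birth,
                                            reporter = reporter)
  }
  structure(list(trajectories = trajs, config = config, schedule = schedule),
            class = "aid_population")
}

#' @export
print.aid_population <- function(x, ...) {
  roles <- vapply(x$trajectories, `[[`, "", "role")
  cat(sprintf("AID population: %d cells (%d mothers, %d daughters), schedule '%s'\n",
              length(roles), sum(roles == "mother"), sum(roles == "daughter"),
              x$schedule$schedule_id))
  invisible(x)
}

#' Convert a population to a long-format data frame
#'
#' One row per cell per timepoint, the on-disk trajectory dialect: columns
#' `cell_id`, `role`, `time_min`, `signal`, `budding` (0/1 flag at the frame
#' where a budding was observed), `schedule_id`.
#'
#' @param pop an `aid_population`.
#' @return data.frame in long format.
#' @export
as_trajectory_frame <- function(pop) {
  stopifnot(inherits(pop, "aid_population"))
  do.call(rbind, lapply(pop$trajectories, function(tr) {
    data.frame(cell_id = tr$cell_id, role = tr$role, time_min = tr$times,
               signal = tr$signal,
               budding = as.integer(tr$times %in% tr$budding_times),
               schedule_id = tr$schedule_id)
  }))
}
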
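# deterministic configuration variants used across tests
cfg_default <- function(...) sim_config(...)

cfg_quiet <- function(...) sim_config(noise_cv = 0, ...)

# noise-free, division-free, delay-free: pure ODE dynamics
cfg_ode <- function(...) {
  sim_config(noise_cv = 0, af_floor = 0, t_div_median = 1e7,
             onset_m_max = 0, ...)
}

# a trajectory carrying an arbitrary signal on a 5-min grid
make_traj <- function(signal, dt = 5, t0 = 0, budding = numeric(0),
                      cell_id = "c1", role = "mother") {
  times <- seq(t0, by = dt, length.out = length(signal))
  new_trajectory(cell_id, times, signal, budding_times = budding, role = role)
}

make_pop <- function(trajs, config = sim_config()) {
  new_population(trajs, config = config)
}

# builds a noiseless piecewise-linear sawtooth on the 5-min grid: divisions
# 2.5 min before each budding frame, constant peak-to-trough drop factor d
make_sawtooth <- function(d = 1.25, m1 = 0.5, rise = 1.4,
                          buds = seq(100, 500, by = 100), dt = 5,
                          horizon = 600) {
  tdiv <- c(buds, horizon + dt) - dt / 2
  m <- numeric(length(tdiv)); m[1] <- m1
  s <- numeric(length(tdiv))
  for (j in seq_along(tdiv)) {
    s[j] <- m[j] * (rise - 1) / 100
    if (j < length(tdiv)) m[j + 1] <- (m[j] + s[j] * (tdiv[j + 1] - tdiv[j])) / d
  }
  tt <- seq(0, horizon, by = dt)
  seg <- findInterval(tt, tdiv)
  sig <- ifelse(seg == 0, m1, m[pmax(seg, 1)] + s[pmax(seg, 1)] * (tt - tdiv[pmax(seg, 1)]))
  list(traj = new_trajectory("saw", tt, sig, budding_times = buds),
       m = m, s = s, tdiv = tdiv)
}
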
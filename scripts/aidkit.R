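#!/usr/bin/env Rscript
# Thin command-line front end over the aidkit package.
#
#   Rscript scripts/aidkit.R simulate --schedule FILE --n-mothers N [--n-daughters N]
#                                     [--seed S] --out FILE
#   Rscript scripts/aidkit.R deplete  --in FILE --t-add T [--out FILE]
#   Rscript scripts/aidkit.R recover  --in FILE --t-removal T [--out FILE]
#   Rscript scripts/aidkit.R growth   --in FILE [--out FILE]
#   Rscript scripts/aidkit.R report   --in FILE --t-add T [--t-removal T] [--out FILE]
#
# Schedule files are the flat key = value sidecars written by write_schedule().
# Simulator defaults are those of sim_config(); see ?sim_config.

suppressPackageStartupMessages(library(aidkit))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) == 0) stop("usage: aidkit.R <simulate|deplete|recover|growth|report> ...")
cmd <- args[1]; args <- args[-1]
get_arg <- function(flag, default = NULL) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
num <- function(x) if (is.null(x)) NULL else as.numeric(x)

cfg <- sim_config()

if (cmd == "simulate") {
  sch <- read_schedule(get_arg("--schedule"))
  pop <- simulate_experiment(cfg, sch,
                             n_mothers = as.integer(get_arg("--n-mothers", "20")),
                             n_daughters = as.integer(get_arg("--n-daughters", "0")),
                             seed = as.integer(get_arg("--seed", cfg$seed)))
  write_trajectories(pop, get_arg("--out", "trajectories.csv"))
  cat("wrote", get_arg("--out", "trajectories.csv"), "\n")
} else if (cmd == "deplete") {
  pop <- read_trajectories(get_arg("--in"), config = cfg)
  pop <- normalize_baseline(pop)
  ds <- depletion_summary(pop, t_add = num(get_arg("--t-add", "240")))
  out <- get_arg("--out", "depletion_summary.csv")
  write.csv(ds, out, row.names = FALSE)
  cat("wrote", out, "\n")
} else if (cmd == "recover") {
  pop <- read_trajectories(get_arg("--in"), config = cfg)
  pop <- normalize_baseline(pop)
  cyc <- cohort_cycles(protein_component(pop, cfg$af_floor),
                       t_removal = num(get_arg("--t-removal")))
  est <- dilution_factor(fit_max_diff_regression(cyc))
  out <- get_arg("--out", "cycle_stats.csv")
  write.csv(as.data.frame(cyc), out, row.names = FALSE)
  cat("wrote", out, "\n")
  cat(sprintf("SLOPE %.4f (95%% CI %.4f-%.4f), DIL %.3f (95%% CI %.3f-%.3f), %d oscillations / %d cells\n",
              est$slope, est$slope_ci95[1], est$slope_ci95[2],
              est$dil, est$dil_ci95[1], est$dil_ci95[2],
              est$n_oscillations, est$n_cells))
} else if (cmd == "growth") {
  pop <- read_trajectories(get_arg("--in"), config = cfg)
  gr <- cohort_growth(pop)
  out <- get_arg("--out", "growth_records.csv")
  write.csv(as.data.frame(gr), out, row.names = FALSE)
  cat("wrote", out, "\n")
  cat(sprintf("mean GR %.5g/min over %d cycles from %d cells\n",
              mean(gr$gr_per_min), nrow(gr), length(unique(gr$cell_id))))
} else if (cmd == "report") {
  pop <- read_trajectories(get_arg("--in"), config = cfg)
  rep <- run_report(pop,
                    t_add = num(get_arg("--t-add", "240")),
                    t_removal = num(get_arg("--t-removal")),
                    n_boot = as.integer(get_arg("--n-boot", "100")),
                    seed = as.integer(get_arg("--seed", "1")),
                    out = get_arg("--out"))
  print(rep)
} else {
  stop("unknown subcommand: ", cmd)
}
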
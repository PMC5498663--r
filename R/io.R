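TRAJ_COLS <- c("cell_id", "role", "time_min", "signal", "budding", "schedule_id")

#' Write trajectories to the long-format CSV dialect
#'
#' Columns `cell_id`, `role`, `time_min`, `signal`, `budding` (0/1 at the
#' frame where a budding was observed), `schedule_id`. Schedule metadata can
#' be written alongside with [write_schedule()].
#'
#' @param pop an `aid_population`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(pop, path) {
  df <- as_trajectory_frame(pop)
  df$signal <- formatC(df$signal, digits = 17, format = "g")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read trajectories from the long-format CSV dialect
#'
#' Validates the header and, per cell, the time grid (strictly increasing,
#' fixed sampling period) and signal nonnegativity; malformed rows are
#' reported with their line numbers.
#'
#' @param path CSV path.
#' @param config optional [sim_config()] to attach to the population.
#' @param schedule optional [auxin_schedule()] to attach.
#' @return an `aid_population`.
#' @export
read_trajectories <- function(path, config = NULL, schedule = NULL) {
  if (!file.exists(path))
    stop("read_trajectories: no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    stop("read_trajectories: empty file", call. = FALSE)
  missing_cols <- setdiff(TRAJ_COLS, names(df))
  if (length(missing_cols))
    stop("read_trajectories: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(df$time_min) | !is.finite(df$signal) |
                 df$signal < 0 | !df$budding %in% c(0, 1))
  if (length(bad))
    stop("read_trajectories: malformed rows at line(s) ",
         paste(head(bad + 1, 10), collapse = ", "), call. = FALSE)
  trajs <- lapply(split(df, df$cell_id)[unique(df$cell_id)], function(d) {
    d <- d[order(d$time_min), , drop = FALSE]
    tt <- d$time_min
    if (any(diff(tt) <= 0))
      stop("read_trajectories: non-increasing times for cell ", d$cell_id[1],
           call. = FALSE)
    steps <- unique(round(diff(tt), 9))
    if (length(steps) > 1)
      stop("read_trajectories: irregular time grid for cell ", d$cell_id[1],
           call. = FALSE)
    structure(list(cell_id = d$cell_id[1], role = d$role[1], times = tt,
                   signal = d$signal, budding_times = tt[d$budding == 1],
                   schedule_id = d$schedule_id[1], birth = tt[1]),
              class = "aid_trajectory")
  })
  names(trajs) <- NULL
  structure(list(trajectories = trajs, config = config, schedule = schedule),
            class = "aid_population")
}

#' Write / read schedule metadata as a flat key = value sidecar
#'
#' @param schedule an [auxin_schedule()].
#' @param path sidecar file path.
#' @return `write_schedule`: `path` invisibly; `read_schedule`: an
#'   `aid_schedule`.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "aid_schedule"))
  segs <- schedule$segments
  lines <- c(
    paste0("schedule_id = ", schedule$schedule_id),
    paste0("delivery = ", schedule$delivery),
    paste0("ph = ", schedule$ph),
    paste0("light_on = ", schedule$light_on),
    paste0("horizon = ", schedule$horizon),
    if (!is.null(schedule$pump_lag)) paste0("pump_lag = ", schedule$pump_lag),
    paste0("n_segments = ", nrow(segs)))
  for (i in seq_len(nrow(segs))) {
    lines <- c(lines, sprintf("segment%d = %.10g %.10g %.10g %s", i,
                              segs$start[i], segs$end[i], segs$conc[i],
                              segs$compound[i]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_schedule
#' @param path sidecar file path.
#' @export
read_schedule <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, " = ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  get <- function(k) vals[match(k, keys)]
  n_seg <- as.integer(get("n_segments"))
  segs <- if (n_seg > 0) {
    do.call(rbind, lapply(seq_len(n_seg), function(i) {
      f <- strsplit(get(sprintf("segment%d", i)), " ")[[1]]
      data.frame(start = as.numeric(f[1]), end = as.numeric(f[2]),
                 conc = as.numeric(f[3]), compound = f[4])
    }))
  } else NULL
  lag <- get("pump_lag")
  auxin_schedule(segs, delivery = get("delivery"), ph = as.numeric(get("ph")),
                 light_on = as.logical(get("light_on")),
                 horizon = as.numeric(get("horizon")),
                 pump_lag = if (is.na(lag)) NULL else as.numeric(lag),
                 schedule_id = get("schedule_id"))
}

#' End-to-end analysis report
#'
#' Runs the analysis pipeline on a trajectory table: baseline normalization,
#' depletion summaries (per-cell minimum slopes, times to floor, completeness
#' ratios), and - when a removal time is given - the recovery analysis
#' (cycle segmentation, DIFF-vs-MAX regression, dilution factor) and growth
#' statistics. Any stage failure aborts with a stage-tagged error.
#'
#' @param pop an `aid_population` (e.g. from [read_trajectories()] or
#'   [simulate_experiment()]); must carry a config.
#' @param t_add auxin addition time (min).
#' @param t_removal auxin removal time (min), or `NULL` for sustained
#'   exposure.
#' @param before,after completeness windows (min).
#' @param n_boot bootstrap iterations for CIs.
#' @param origin origin-constrained DIFF-vs-MAX regression flag.
#' @param spar optional fixed smoothing parameter.
#' @param out optional path; if given, the summary is also written as JSON.
#' @param seed RNG seed for the bootstraps.
#' @return list of class `aid_report` with elements `depletion` (per-cell
#'   table), `completeness`, `min_slope_population`, and optionally
#'   `dilution` and `growth`, plus a `meta` block (seed, counts, windows).
#' @export
run_report <- function(pop, t_add = 240, t_removal = NULL,
                       before = c(0, 240), after = c(500, 740),
                       n_boot = 100, origin = TRUE, spar = NULL,
                       out = NULL, seed = 1L) {
  if (!inherits(pop, "aid_population") || length(pop$trajectories) == 0)
    stop("report/input: empty or invalid population", call. = FALSE)
  if (is.null(pop$config)) pop$config <- sim_config()
  set.seed(seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("report/%s: %s", name, conditionMessage(e)), call. = FALSE))
  }
  norm <- stage("preprocess", normalize_baseline(pop, window = before))
  dep <- stage("depletion", depletion_summary(norm, t_add = t_add,
                                              before = before, after = after,
                                              spar = spar))
  comp <- stage("depletion", {
    ok <- is.finite(dep$completeness_ratio)
    if (any(ok)) {
      r <- dep$completeness_ratio[ok]
      list(mean = mean(r), sd = sd(r), n = sum(ok))
    } else NULL
  })
  msl <- stage("depletion", {
    if (length(norm$trajectories) >= 2 &&
        length(unique(vapply(norm$trajectories, function(tr)
          length(tr$times), 0L))) == 1) {
      st <- population_stats(norm)
      max_depletion_rate(st, t_add)
    } else NULL
  })
  rep_out <- list(depletion = dep, completeness = comp,
                  min_slope_population = msl,
                  meta = list(n_cells = length(pop$trajectories),
                              t_add = t_add, t_removal = t_removal,
                              before = before, after = after,
                              n_boot = n_boot, seed = seed,
                              package_version = as.character(
                                utils::packageVersion("aidkit"))))
  if (!is.null(t_removal)) {
    rep_out$dilution <- stage("recovery", {
      cyc <- cohort_cycles(protein_component(norm, pop$config$af_floor),
                           t_removal)
      if (sum(is.finite(cyc$diff)) >= 5) {
        dilution_factor(fit_max_diff_regression(cyc, n_boot = max(n_boot, 200),
                                                origin = origin))
      } else NULL
    })
    rep_out$growth <- stage("growth", {
      gr <- cohort_growth(norm)
      if (nrow(gr)) list(mean_gr = mean(gr$gr_per_min),
                         n_cycles = nrow(gr)) else NULL
    })
  }
  class(rep_out) <- "aid_report"
  if (!is.null(out)) {
    json <- rep_out
    class(json) <- NULL
    write_json(json, out, auto_unbox = TRUE, digits = NA, pretty = TRUE,
               force = TRUE)
  }
  rep_out
}

#' @export
print.aid_report <- function(x, ...) {
  cat(sprintf("AID analysis report (%d cells)\n", x$meta$n_cells))
  if (!is.null(x$min_slope_population))
    cat(sprintf("  population min slope: %.4g/min at %g min\n",
                x$min_slope_population$min_slope, x$min_slope_population$time))
  if (!is.null(x$completeness))
    cat(sprintf("  completeness ratio: %.3f (sd %.3f, n %d)\n",
                x$completeness$mean, x$completeness$sd, x$completeness$n))
  if (!is.null(x$dilution))
    cat(sprintf("  dilution factor: %.3f (95%% CI %.3f-%.3f)\n",
                x$dilution$dil, x$dilution$dil_ci95[1], x$dilution$dil_ci95[2]))
  if (!is.null(x$growth))
    cat(sprintf("  mean growth rate: %.4g/min (%d cycles)\n",
                x$growth$mean_gr, x$growth$n_cycles))
  invisible(x)
}
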
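#' Auxin perturbation schedule
#'
#' Describes when and how auxin reaches the cells: a set of non-overlapping
#' exposure segments, the delivery mode, the medium pH and whether GFP
#' excitation light is applied. Delivery modes model the experimental
#' hardware:
#' \describe{
#'   \item{`instant`}{idealized step changes,}
#'   \item{`fast`}{a finely controlled perfusion switch, a 3.5-min linear
#'     ramp at every concentration change (media switch complete within
#'     3-4 min),}
#'   \item{`pump`}{syringe-pump perfusion, a per-experiment delivery lag
#'     (drawn once per experiment from Normal(50, 5) min) followed by a
#'     10-min linear ramp.}
#' }
#'
#' @param segments data.frame with columns `start`, `end` (min), `conc` (mM)
#'   and optionally `compound` ("IAA"/"NAA", default IAA); segments must be
#'   ordered and non-overlapping.
#' @param delivery one of `"pump"`, `"fast"`, `"instant"`.
#' @param ph medium pH.
#' @param light_on logical, periodic blue-light excitation applied?
#' @param horizon experiment duration (min).
#' @param pump_lag realized pump delivery lag (min); normally left `NULL` and
#'   drawn by [simulate_experiment()]; defaults to 50 when the profile is
#'   evaluated standalone.
#' @param schedule_id label written to trajectory tables.
#' @return object of class `aid_schedule`.
#' @export
#' @examples
#' sch <- schedule_pulse(conc = 0.5, t_on = 240, duration = 120)
#' auxin_profile(sch, c(239, 243.5, 360, 364))
auxin_schedule <- function(segments,
                           delivery = c("instant", "fast", "pump"),
                           ph = 5.1, light_on = TRUE, horizon = 900,
                           pump_lag = NULL, schedule_id = "schedule1") {
  delivery <- match.arg(delivery)
  if (is.null(segments) || nrow(segments) == 0) {
    segments <- data.frame(start = numeric(0), end = numeric(0),
                           conc = numeric(0), compound = character(0))
  }
  if (is.null(segments$compound)) segments$compound <- "IAA"
  stopifnot(all(c("start", "end", "conc") %in% names(segments)))
  if (any(segments$conc < 0))
    stop("auxin_schedule: concentrations must be >= 0", call. = FALSE)
  if (any(segments$end <= segments$start))
    stop("auxin_schedule: segments must have end > start", call. = FALSE)
  if (nrow(segments) > 1) {
    o <- order(segments$start)
    segments <- segments[o, , drop = FALSE]
    if (any(segments$start[-1] < segments$end[-nrow(segments)]))
      stop("auxin_schedule: segments overlap", call. = FALSE)
  }
  if (!all(segments$compound %in% c("IAA", "NAA")))
    stop("auxin_schedule: compound must be IAA or NAA", call. = FALSE)
  structure(list(segments = segments, delivery = delivery, ph = ph,
                 light_on = light_on, horizon = horizon, pump_lag = pump_lag,
                 schedule_id = schedule_id),
            class = "aid_schedule")
}

#' @rdname auxin_schedule
#' @param conc auxin concentration (mM).
#' @param t_on time of the medium switch to auxin (min).
#' @param compound `"IAA"` or `"NAA"`.
#' @param ... passed on to [auxin_schedule()].
#' @export
schedule_step <- function(conc, t_on = 240, horizon = 900, compound = "IAA",
                          delivery = "instant", ...) {
  auxin_schedule(data.frame(start = t_on, end = horizon, conc = conc,
                            compound = compound),
                 delivery = delivery, horizon = horizon, ...)
}

#' @rdname auxin_schedule
#' @param duration pulse length (min).
#' @export
schedule_pulse <- function(conc, t_on = 240, duration = 120, horizon = 1100,
                           compound = "IAA", delivery = "fast", ...) {
  auxin_schedule(data.frame(start = t_on, end = t_on + duration, conc = conc,
                            compound = compound),
                 delivery = delivery, horizon = horizon, ...)
}

#' @rdname auxin_schedule
#' @export
schedule_none <- function(horizon = 300, ...) {
  auxin_schedule(segments = NULL, delivery = "instant", horizon = horizon, ...)
}

ramp_width <- function(schedule) {
  switch(schedule$delivery, instant = 0, fast = 3.5, pump = 10)
}

delivery_lag <- function(schedule) {
  if (schedule$delivery == "pump") schedule$pump_lag %||% 50 else 0
}

# unchecked, vectorized concentration profile (used internally with shifted t)
profile_eval <- function(schedule, t) {
  conc <- numeric(length(t))
  segs <- schedule$segments
  if (nrow(segs) == 0) return(conc)
  w <- ramp_width(schedule)
  lag <- delivery_lag(schedule)
  edge <- function(x) {  # 0 -> 1 over the ramp width
    if (w == 0) as.numeric(x >= 0) else pmin(pmax(x / w, 0), 1)
  }
  for (i in seq_len(nrow(segs))) {
    conc <- conc + segs$conc[i] *
      (edge(t - (segs$start[i] + lag)) - edge(t - (segs$end[i] + lag)))
  }
  conc
}

# times at which the profile's slope can change
profile_knots <- function(schedule) {
  segs <- schedule$segments
  if (nrow(segs) == 0) return(numeric(0))
  w <- ramp_width(schedule)
  lag <- delivery_lag(schedule)
  sort(unique(c(segs$start + lag, segs$start + lag + w,
                segs$end + lag, segs$end + lag + w)))
}

# first time auxin appears in the chamber (Inf if never)
first_arrival <- function(schedule) {
  segs <- schedule$segments
  if (nrow(segs) == 0 || all(segs$conc == 0)) return(Inf)
  min(segs$start[segs$conc > 0]) + delivery_lag(schedule)
}

#' Auxin concentration at the cells
#'
#' Evaluates the piecewise-linear delivery profile of a schedule: a step for
#' `instant` delivery, a 3.5-min linear ramp for the `fast` perfusion switch,
#' and a per-experiment lag (default 50 min) followed by a 10-min ramp for
#' `pump` delivery.
#'
#' @param schedule an [auxin_schedule()].
#' @param t_min time(s) in minutes, within `[0, horizon]`.
#' @return concentration(s) in mM.
#' @export
auxin_profile <- function(schedule, t_min) {
  stopifnot(inherits(schedule, "aid_schedule"))
  if (any(t_min < 0 | t_min > schedule$horizon))
    stop("auxin_profile: t outside the experiment horizon", call. = FALSE)
  profile_eval(schedule, t_min)
}

#' @export
print.aid_schedule <- function(x, ...) {
  cat(sprintf("AID auxin schedule '%s': %s delivery, pH %.2g, light %s, horizon %g min\n",
              x$schedule_id, x$delivery, x$ph,
              if (x$light_on) "on" else "off", x$horizon))
  if (nrow(x$segments) == 0) {
    cat("  no auxin exposure\n")
  } else {
    for (i in seq_len(nrow(x$segments)))
      cat(sprintf("  %g-%g min: %g mM %s\n", x$segments$start[i],
                  x$segments$end[i], x$segments$conc[i],
                  x$segments$compound[i]))
  }
  invisible(x)
}
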
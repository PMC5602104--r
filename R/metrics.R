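#' Clock helpers
#'
#' Timestamps throughout the package are seconds since experiment start;
#' `start_hour` in the configuration anchors time zero to the wall clock.
#' `hour_of_day()` maps timestamps to the 24-h clock; `day_index()` assigns
#' each timestamp to a day, with day boundaries at the lights-on instant so
#' that "per day" quantities (the entry-reward cap, daily trial counts) are
#' aligned with the photoperiod.
#'
#' @param t_s Timestamps, seconds since experiment start.
#' @param config A [task_config()].
#' @return `hour_of_day()`: fractional hours in `[0, 24)`. `day_index()`:
#'   integer day numbers (day 0 contains the first lights-on at or before
#'   time zero).
#' @export
hour_of_day <- function(t_s, config) {
  (config$start_hour + t_s / 3600) %% 24
}

#' @rdname hour_of_day
#' @export
day_index <- function(t_s, config) {
  offset <- (config$lights_on_hour - config$start_hour) * 3600
  floor((t_s - offset) / 86400)
}

# hours of the 24-h clock belonging to the dark phase
dark_hours <- function(config) {
  lights_off <- (config$lights_on_hour + 24 - config$dark_phase_hours) %% 24
  (lights_off + seq_len(config$dark_phase_hours) - 1) %% 24
}

#' Phase-1 acquisition criterion
#'
#' An animal acquires the task only if it performs strictly more than
#' `criterion` trials (200 by default) during the acquisition phase;
#' animals at or below the criterion are excluded from further testing.
#'
#' @param n_phase1_trials Number of phase-1 trials performed.
#' @param criterion Acquisition cutoff (strict).
#' @return `"acquired"` or `"not_acquired"`.
#' @examples
#' acquisition_flag(200)  # exactly 200 does not acquire
#' acquisition_flag(201)
#' @export
acquisition_flag <- function(n_phase1_trials, criterion = 200) {
  stopifnot(n_phase1_trials >= 0)
  if (n_phase1_trials > criterion) "acquired" else "not_acquired"
}

#' Circadian distribution of trials
#'
#' Bins trial times into the 24 wall-clock hours (half-open intervals
#' `[h, h+1)`) and reports the percentage of trials per bin together with
#' the percentage falling in the dark phase (the 12 h starting at
#' lights-off).
#'
#' @param t_s Trial initiation times, seconds since experiment start.
#' @param config A [task_config()].
#' @return An object of class `"circadian_histogram"`: list with
#'   `bin_percentages` (named, hours 0-23), `dark_phase_percentage` and
#'   `n_trials`. With no trials the percentages are `NA` (empty sentinel).
#' @examples
#' cfg <- task_config()
#' h <- circadian_histogram(c(13.2, 13.5, 13.9) * 3600, cfg)
#' h$bin_percentages[["13"]]
#' @export
circadian_histogram <- function(t_s, config) {
  n <- length(t_s)
  hrs <- 0:23
  if (n == 0) {
    pct <- stats::setNames(rep(NA_real_, 24), hrs)
    out <- list(bin_percentages = pct, dark_phase_percentage = NA_real_,
                n_trials = 0L)
  } else {
    bin <- floor(hour_of_day(t_s, config))
    counts <- vapply(hrs, function(h) sum(bin == h), numeric(1))
    pct <- stats::setNames(100 * counts / n, hrs)
    out <- list(bin_percentages = pct,
                dark_phase_percentage = sum(pct[as.character(dark_hours(config))]),
                n_trials = n)
  }
  structure(out, class = "circadian_histogram")
}

#' @export
print.circadian_histogram <- function(x, ...) {
  cat(sprintf("<circadian_histogram> %d trials, %.1f%% in dark phase\n",
              x$n_trials, x$dark_phase_percentage))
  invisible(x)
}

#' Staircase progression curve
#'
#' Replays the block evaluation rule over an ordered sequence of phase-2
#' outcomes for one animal and reports, for each consecutive block of
#' `block_size` trials, the required hold duration in effect at the end of
#' the block (after evaluation), the block success rate, and the cumulative
#' success rate. This is an independent reconstruction of the staircase the
#' controller runs live; the two must agree on the same outcome sequence.
#'
#' @param outcomes Logical (or 0/1) vector of trial outcomes in order, from
#'   the start of phase 2. A trailing incomplete block is ignored.
#' @param config A [task_config()].
#' @param t_s Optional trial initiation times (seconds), same length as
#'   `outcomes`; if given, each bin carries the time its last trial ran.
#' @param max_trials Horizon: only the first `max_trials` outcomes are used
#'   (`Inf` for all).
#' @return A data frame of class `"progression_curve"` with one row per
#'   complete block: `bin`, `trial_end`, `required_hold`, `block_success_pct`,
#'   `cum_success_pct` and (if times were supplied) `t_end`.
#' @examples
#' cfg <- task_config()
#' pc <- progression_curve(rep(TRUE, 500), cfg)
#' pc$required_hold[7]  # ceiling reached at block 7
#' @export
progression_curve <- function(outcomes, config, t_s = NULL, max_trials = Inf) {
  outcomes <- as.logical(outcomes)
  if (!is.null(t_s)) stopifnot(length(t_s) == length(outcomes))
  if (is.finite(max_trials) && length(outcomes) > max_trials) {
    outcomes <- outcomes[seq_len(max_trials)]
    if (!is.null(t_s)) t_s <- t_s[seq_len(max_trials)]
  }
  n_bins <- length(outcomes) %/% config$block_size
  hold <- config$hold_init
  rows <- vector("list", n_bins)
  cum_succ <- 0L
  for (b in seq_len(n_bins)) {
    idx <- ((b - 1L) * config$block_size + 1L):(b * config$block_size)
    s <- sum(outcomes[idx])
    cum_succ <- cum_succ + s
    hold <- evaluate_block(s, config$block_size, hold, config)
    rows[[b]] <- data.frame(
      bin = b,
      trial_end = b * config$block_size,
      required_hold = hold,
      block_success_pct = 100 * s / config$block_size,
      cum_success_pct = 100 * cum_succ / (b * config$block_size))
    if (!is.null(t_s)) rows[[b]]$t_end <- t_s[idx[config$block_size]]
  }
  out <- if (n_bins > 0) do.call(rbind, rows) else
    data.frame(bin = integer(0), trial_end = integer(0),
               required_hold = numeric(0), block_success_pct = numeric(0),
               cum_success_pct = numeric(0))
  class(out) <- c("progression_curve", "data.frame")
  out
}

#' Did the animal reach the maximum hold duration in time?
#'
#' @param progression A [progression_curve()] with a `t_end` column (or an
#'   empty curve).
#' @param config A [task_config()].
#' @param horizon_days Days allowed from the first block's end to reach the
#'   ceiling (default 7, the length of the hold phase).
#' @return `"reached"` or `"not_reached"`.
#' @export
reach_max_flag <- function(progression, config, horizon_days = 7) {
  if (nrow(progression) == 0) return("not_reached")
  at_max <- progression$required_hold >= config$hold_max
  if (!any(at_max)) return("not_reached")
  if (!"t_end" %in% names(progression)) return("reached")
  t0 <- progression$t_end[1] - 1  # start of phase 2, approximated by bin 1
  if (min(progression$t_end[at_max]) - t0 <= horizon_days * 86400)
    "reached" else "not_reached"
}

#' Daily activity table
#'
#' Per animal and per day (lights-on boundaries): number of trials
#' initiated, total time spent in the chamber (visits clipped at day
#' edges), and the natural log of the trial count (the transform used to
#' normalise right-skewed daily counts; undefined and set to `NA` for zero
#' counts).
#'
#' @param events Session events (columns `t_s`, `animal_id`, `kind`) with
#'   alternating entry/exit per animal; an unmatched final entry is closed
#'   at the stream end with a warning.
#' @param trials Trial data frame with columns `animal_id`, `t_init`.
#' @param config A [task_config()].
#' @return Data frame with one row per animal-day spanned by the data:
#'   `animal_id`, `day`, `n_trials`, `time_in_chamber_s`, `log_n_trials`.
#' @export
daily_activity <- function(events, trials, config) {
  check_entry_exit_alternation(events)
  visits <- visits_from_events(events)
  ids <- sort(unique(c(visits$animal_id, trials$animal_id)))
  t_all <- c(visits$t_entry, visits$t_exit, trials$t_init)
  if (length(t_all) == 0)
    return(data.frame(animal_id = character(0), day = integer(0),
                      n_trials = integer(0), time_in_chamber_s = numeric(0),
                      log_n_trials = numeric(0)))
  days <- seq(min(day_index(t_all, config)), max(day_index(t_all, config)))
  offset <- (config$lights_on_hour - config$start_hour) * 3600
  rows <- list()
  for (id in ids) {
    v <- visits[visits$animal_id == id, , drop = FALSE]
    tt <- trials$t_init[trials$animal_id == id]
    for (d in days) {
      d0 <- offset + d * 86400
      d1 <- d0 + 86400
      tic <- sum(pmax(0, pmin(v$t_exit, d1) - pmax(v$t_entry, d0)))
      n <- sum(tt >= d0 & tt < d1)
      rows[[length(rows) + 1L]] <- data.frame(
        animal_id = id, day = d, n_trials = n, time_in_chamber_s = tic,
        log_n_trials = if (n > 0) log(n) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
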
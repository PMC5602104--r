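#' Per-trial kinematic features
#'
#' Three features summarise each lever-pull trial: the maximum displacement
#' (largest sampled angle over the trial segment), the hold slope (ordinary
#' least-squares slope of angle against time over a window 200--800 ms
#' after initiation; negative values indicate a progressive release of the
#' lever), and the mean speed (mean absolute instantaneous velocity over
#' consecutive samples).
#'
#' @param trace A [lever_trace()] trial segment whose first sample is the
#'   initiation sample.
#' @return `max_displacement()` and `mean_speed()` return a scalar;
#'   `hold_slope()` the OLS slope in degrees per second.
#' @examples
#' tr <- lever_trace(rep(12, 101))
#' max_displacement(tr); hold_slope(tr); mean_speed(tr)
#' @export
max_displacement <- function(trace) {
  stopifnot(inherits(trace, "lever_trace"))
  max(trace$samples)
}

#' @rdname max_displacement
#' @param window_start,window_end Analysis window for the slope, ms after
#'   trial initiation (endpoints inclusive on the sample lattice).
#' @export
hold_slope <- function(trace, window_start = 200, window_end = 800) {
  stopifnot(inherits(trace, "lever_trace"))
  t_ms <- trace_times_ms(trace)
  if (t_ms[length(t_ms)] < window_end)
    stop(sprintf("insufficient trace: %g ms recorded, slope window ends at %g ms",
                 t_ms[length(t_ms)], window_end))
  keep <- t_ms >= window_start & t_ms <= window_end
  tt <- t_ms[keep] / 1000  # seconds
  yy <- trace$samples[keep]
  tc <- tt - mean(tt)
  sum(tc * yy) / sum(tc * tc)
}

#' @rdname max_displacement
#' @export
mean_speed <- function(trace) {
  stopifnot(inherits(trace, "lever_trace"))
  dt <- trace$sample_period / 1000
  mean(abs(diff(trace$samples))) / dt
}

#' @rdname max_displacement
#' @export
trial_features <- function(trace, window_start = 200, window_end = 800) {
  data.frame(max_displacement = max_displacement(trace),
             hold_slope = hold_slope(trace, window_start, window_end),
             mean_speed = mean_speed(trace))
}

#' Per-animal kinematic summary
#'
#' Aggregates trial features under the eligibility rules used for the
#' kinematic analysis: only successful trials at the maximum required hold
#' duration count, and an animal contributes a summary only if it has at
#' least `min_eligible` such trials (200 by default) -- otherwise it is
#' flagged excluded, to keep averages representative in the face of
#' inter-trial variability.
#'
#' @param trials Trial data frame (as from [run_session()]) with columns
#'   `animal_id`, `outcome`, `required_hold`, `trace_id`.
#' @param traces Named list of [lever_trace()] trial segments, indexed by
#'   `trace_id`.
#' @param config A [task_config()].
#' @param min_eligible Minimum eligible trials for inclusion.
#' @param window_start,window_end Hold-slope analysis window, ms.
#' @return Data frame with one row per animal: `animal_id`, `n_eligible`,
#'   `excluded`, and mean and SD of each feature (`NA` when excluded).
#' @export
aggregate_kinematics <- function(trials, traces, config, min_eligible = 200,
                                 window_start = 200, window_end = 800) {
  elig <- trials[trials$outcome == "success" &
                 !is.na(trials$required_hold) &
                 trials$required_hold == config$hold_max, , drop = FALSE]
  ids <- sort(unique(trials$animal_id))
  rows <- lapply(ids, function(id) {
    tr_ids <- elig$trace_id[elig$animal_id == id]
    n <- length(tr_ids)
    if (n < min_eligible) {
      return(data.frame(animal_id = id, n_eligible = n, excluded = TRUE,
                        mean_max_displacement = NA_real_, sd_max_displacement = NA_real_,
                        mean_hold_slope = NA_real_, sd_hold_slope = NA_real_,
                        mean_speed = NA_real_, sd_speed = NA_real_,
                        stringsAsFactors = FALSE))
    }
    feats <- do.call(rbind, lapply(traces[tr_ids], trial_features,
                                   window_start = window_start,
                                   window_end = window_end))
    data.frame(animal_id = id, n_eligible = n, excluded = FALSE,
               mean_max_displacement = mean(feats$max_displacement),
               sd_max_displacement = stats::sd(feats$max_displacement),
               mean_hold_slope = mean(feats$hold_slope),
               sd_hold_slope = stats::sd(feats$hold_slope),
               mean_speed = mean(feats$mean_speed),
               sd_speed = stats::sd(feats$mean_speed),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
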
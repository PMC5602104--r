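#' Detect pull trials in a lever trace
#'
#' The controller is armed at the start of the stream. A trial initiates at
#' the first sample whose angle reaches `pull_threshold` (12 degrees by
#' default) while armed; the controller then disarms until the lever has
#' returned below `rearm_threshold` (1 degree), so one pull produces exactly
#' one trial however much the angle oscillates around the initiation
#' threshold. Each returned segment runs from the initiation sample to the
#' re-arm sample (or the end of the stream if the lever never returns).
#'
#' @param trace A [lever_trace()] covering one recording stretch.
#' @param config A [task_config()].
#' @return A list of trial segments; each element is a list with `t_init`
#'   (absolute seconds) and `trace` (the segment as a `lever_trace`).
#' @examples
#' cfg <- task_config()
#' tr <- lever_trace(c(0, 5, 14, 14, 6, 0.5, 0, 7, 13, 3, 0.2), t0 = 0)
#' length(detect_trials(tr, cfg))  # 2 pulls, 2 trials
#' @export
detect_trials <- function(trace, config) {
  stopifnot(inherits(trace, "lever_trace"))
  check_trace_range(trace, config)
  x <- trace$samples
  n <- length(x)
  sp <- trace$sample_period
  segments <- list()
  i <- 1L
  while (i <= n) {
    # armed: scan for initiation
    hits <- which(x[i:n] >= config$pull_threshold)
    if (length(hits) == 0) break
    start <- i + hits[1] - 1L
    if (start == n) break  # initiation on the final sample: truncated pull
    # disarmed: scan for return below the re-arm threshold
    rearms <- which(x[(start + 1L):n] < config$rearm_threshold)
    end <- if (length(rearms) == 0) n else start + rearms[1]
    seg <- lever_trace(x[start:end],
                       t0 = trace$t0 + (start - 1L) * sp / 1000,
                       sample_period = sp)
    segments[[length(segments) + 1L]] <-
      list(t_init = seg$t0, trace = seg,
           complete = !(end == n && x[n] >= config$rearm_threshold))
    i <- end + 1L
  }
  segments
}

trial_record <- function(animal_id, phase, t_init, required_hold, outcome,
                         reward_volume, t_reward, trace_id = NA_character_) {
  data.frame(animal_id = animal_id, phase = phase, t_init = t_init,
             required_hold = required_hold, outcome = outcome,
             reward_volume = reward_volume, t_reward = t_reward,
             trace_id = trace_id, stringsAsFactors = FALSE)
}

#' Classify a detected trial under phase-1 (acquisition) rules
#'
#' In phase 1 every lever pull past the initiation threshold is rewarded on
#' a continuous reinforcement schedule: the trial is a success and a 10
#' microlitre drop is dispensed at initiation.
#'
#' @param segment One element of the list returned by [detect_trials()].
#' @param config A [task_config()].
#' @param animal_id Animal identifier to stamp on the record.
#' @return A one-row data frame (animal, phase, initiation time, outcome,
#'   reward volume, reward time).
#' @export
classify_trial_phase1 <- function(segment, config, animal_id = NA_character_) {
  trial_record(animal_id, phase = 1L, t_init = segment$t_init,
               required_hold = NA_real_, outcome = "success",
               reward_volume = config$trial_reward_volume,
               t_reward = segment$t_init)
}

#' Classify a detected trial under phase-2 (hold) rules
#'
#' A phase-2 trial succeeds if every sample from initiation through
#' `required_hold` ms after initiation (endpoints inclusive) lies inside the
#' goal range `[goal_low, goal_high]`; the reward is dispensed when the hold
#' elapses. The trial fails at the first sample outside the range before the
#' hold has elapsed, and no water is dispensed. A segment that is cut off by
#' the end of the stream while still inside the range is indeterminate and
#' is discarded (`outcome = "discard"`), not scored.
#'
#' @inheritParams classify_trial_phase1
#' @param required_hold Required hold duration, ms; must be representable on
#'   the trace's sample lattice.
#' @return A one-row data frame as for [classify_trial_phase1()], with
#'   outcome `"success"`, `"failure"` or `"discard"`.
#' @examples
#' cfg <- task_config()
#' seg <- detect_trials(lever_trace(c(0, rep(12, 95), 0.5)), cfg)[[1]]
#' classify_trial_phase2(seg, 800, cfg)$outcome  # held 940 ms: success
#' @export
classify_trial_phase2 <- function(segment, required_hold, config,
                                  animal_id = NA_character_) {
  sp <- segment$trace$sample_period
  if (required_hold %% sp != 0)
    stop(sprintf("required_hold (%g ms) not representable at sample period %g ms",
                 required_hold, sp))
  x <- segment$trace$samples
  n_hold <- as.integer(required_hold / sp) + 1L  # samples 0 .. required_hold
  out_of_range <- x < config$goal_low | x > config$goal_high
  first_out <- which(out_of_range)[1]

  if (!is.na(first_out) && first_out <= n_hold) {
    rec <- trial_record(animal_id, 2L, segment$t_init, required_hold,
                        "failure", 0,
                        t_reward = NA_real_)
  } else if (length(x) >= n_hold) {
    rec <- trial_record(animal_id, 2L, segment$t_init, required_hold,
                        "success", config$trial_reward_volume,
                        t_reward = segment$t_init + required_hold / 1000)
  } else {
    # stream ended inside the goal range before the hold elapsed
    rec <- trial_record(animal_id, 2L, segment$t_init, required_hold,
                        "discard", 0, t_reward = NA_real_)
  }
  rec
}

#' Advance the staircase after a completed block
#'
#' Every `block_size` trials the controller compares the block success
#' fraction with the up and down thresholds: strictly above `up_threshold`
#' (75%) the required hold duration increases by one step, strictly below
#' `down_threshold` (10%) it decreases by one step, and otherwise it is
#' unchanged. The result is clamped to `[hold_init, hold_max]`.
#'
#' @param block_successes Number of successes in the completed block.
#' @param block_size Number of trials in the block.
#' @param required_hold Current required hold duration, ms.
#' @param config A [task_config()].
#' @return The new required hold duration, ms.
#' @examples
#' cfg <- task_config()
#' evaluate_block(19, 25, 300, cfg)  # 76% success: step up to 400
#' evaluate_block(2, 25, 300, cfg)   # 8%: step down to 200
#' evaluate_block(3, 25, 300, cfg)   # 12%: dead zone, unchanged
#' @export
evaluate_block <- function(block_successes, block_size, required_hold, config) {
  if (block_successes < 0 || block_successes > block_size)
    stop("block_successes must lie in [0, block_size]")
  if (!required_hold %in% hold_levels(config))
    stop("required_hold is not on the staircase lattice")
  rate <- block_successes / block_size
  if (rate > config$up_threshold) {
    min(required_hold + config$hold_step, config$hold_max)
  } else if (rate < config$down_threshold) {
    max(required_hold - config$hold_step, config$hold_init)
  } else {
    required_hold
  }
}

#' Per-animal staircase state
#'
#' Tracks one animal's required hold duration and within-block counters.
#' [staircase_record_trial()] folds in one scored trial outcome, evaluating
#' the block (via [evaluate_block()]) whenever `block_size` trials have
#' accumulated, and appends any duration change to the state's history.
#'
#' @param animal_id Animal identifier.
#' @param config A [task_config()].
#' @return `staircase_state()` returns an object of class
#'   `"staircase_state"`; `staircase_record_trial()` the updated state.
#' @export
staircase_state <- function(animal_id, config) {
  structure(list(animal_id = animal_id,
                 required_hold = config$hold_init,
                 block_successes = 0L,
                 block_trials = 0L,
                 n_trials = 0L,
                 history = data.frame(trial = 0L,
                                      required_hold = config$hold_init)),
            class = "staircase_state")
}

#' @rdname staircase_state
#' @param state A `staircase_state`.
#' @param success Logical: was the trial a success?
#' @export
staircase_record_trial <- function(state, success, config) {
  stopifnot(inherits(state, "staircase_state"))
  state$n_trials <- state$n_trials + 1L
  state$block_trials <- state$block_trials + 1L
  state$block_successes <- state$block_successes + as.integer(success)
  if (state$block_trials == config$block_size) {
    new_hold <- evaluate_block(state$block_successes, config$block_size,
                               state$required_hold, config)
    if (new_hold != state$required_hold) {
      state$history <- rbind(state$history,
                             data.frame(trial = state$n_trials,
                                        required_hold = new_hold))
      state$required_hold <- new_hold
    }
    state$block_successes <- 0L
    state$block_trials <- 0L
  }
  state
}

#' @export
print.staircase_state <- function(x, ...) {
  cat(sprintf("<staircase_state> animal %s: %d trials, hold %g ms (block %d/%d successes)\n",
              x$animal_id, x$n_trials, x$required_hold,
              x$block_successes, x$block_trials))
  invisible(x)
}

#' Entry-reward accounting
#'
#' `process_entry()` applies the per-entry reward rule: a chamber entry
#' dispenses `entry_reward_volume` (5 microlitres) if the animal has had
#' fewer than `entry_reward_daily_cap` (200) rewarded entries since the last
#' day boundary, else nothing. `entry_rewards()` vectorises this over a
#' sequence of entry times for one animal, resetting the counter at each
#' lights-on day boundary.
#'
#' @param daily_entry_reward_count Rewarded entries so far today.
#' @param config A [task_config()].
#' @return `process_entry()`: the dispensed volume in microlitres.
#'   `entry_rewards()`: a numeric vector of volumes, one per entry.
#' @examples
#' cfg <- task_config()
#' sum(entry_rewards(seq_len(300) * 60, cfg) > 0)  # capped at 200
#' @export
process_entry <- function(daily_entry_reward_count, config) {
  if (daily_entry_reward_count < config$entry_reward_daily_cap)
    config$entry_reward_volume
  else 0
}

#' @rdname process_entry
#' @param t_s Entry timestamps for one animal, seconds since experiment
#'   start, non-decreasing.
#' @export
entry_rewards <- function(t_s, config) {
  if (length(t_s) == 0) return(numeric(0))
  if (is.unsorted(t_s)) stop("entry times must be non-decreasing")
  day <- day_index(t_s, config)
  vol <- numeric(length(t_s))
  count <- 0L
  cur_day <- day[1]
  for (i in seq_along(t_s)) {
    if (day[i] != cur_day) {
      cur_day <- day[i]
      count <- 0L
    }
    vol[i] <- process_entry(count, config)
    if (vol[i] > 0) count <- count + 1L
  }
  vol
}

#' Run the closed-loop controller over a cage's streams
#'
#' Orchestrates trial detection, classification, reward accounting and the
#' per-animal staircase over time-ordered entry/exit events and lever
#' traces. Each trace is attributed to the animal inside the chamber at its
#' start time; trial numbering, block accounting and staircase history are
#' kept separate per animal, so interleaved animals behave exactly as if
#' each were run alone.
#'
#' @param events Data frame of session events with columns `t_s` (seconds),
#'   `animal_id`, `kind` (`"entry"` or `"exit"`), time-ordered, with entries
#'   and exits alternating per animal.
#' @param traces List of [lever_trace()] objects (absolute `t0`), each
#'   recorded while some animal was in the chamber.
#' @param phase Task phase, 1 or 2.
#' @param config A [task_config()].
#' @param states Optional named list of [staircase_state()] objects to
#'   resume from; missing animals are initialised at `hold_init`.
#' @return A list with `trials` (data frame of scored trials; discarded
#'   indeterminate segments are dropped), `events` (the input events plus
#'   `entry_reward`, `trial` and `staircase_change` events, time-ordered)
#'   and `states` (updated staircase states).
#' @export
run_session <- function(events, traces, phase, config, states = list()) {
  stopifnot(all(c("t_s", "animal_id", "kind") %in% names(events)))
  if (is.unsorted(events$t_s)) stop("events must be time-ordered")
  check_entry_exit_alternation(events)
  phase <- as.integer(phase)
  stopifnot(phase %in% c(1L, 2L))

  visits <- visits_from_events(events, end_time = Inf)
  occupant <- function(t) {
    hit <- visits$animal_id[visits$t_entry <= t & t < visits$t_exit]
    if (length(hit) == 0)
      stop(sprintf("attribution error: no animal in chamber at t = %.3f s", t))
    hit[1]
  }

  extra <- list()
  add_event <- function(t, id, kind, payload) {
    extra[[length(extra) + 1L]] <<- data.frame(
      t_s = t, animal_id = id, kind = kind, payload = payload,
      stringsAsFactors = FALSE)
  }

  # entry rewards, per animal, day-capped
  for (id in unique(events$animal_id)) {
    ent <- events$t_s[events$animal_id == id & events$kind == "entry"]
    vols <- entry_rewards(ent, config)
    for (i in seq_along(ent)) if (vols[i] > 0)
      add_event(ent[i], id, "entry_reward", sprintf("volume_ul=%g", vols[i]))
  }

  trials <- list()
  if (length(traces) > 0) {
    ord <- order(vapply(traces, function(tr) tr$t0, numeric(1)))
    traces <- traces[ord]
  }
  for (tr in traces) {
    id <- occupant(tr$t0)
    if (is.null(states[[id]])) states[[id]] <- staircase_state(id, config)
    for (seg in detect_trials(tr, config)) {
      if (phase == 1L) {
        rec <- classify_trial_phase1(seg, config, animal_id = id)
      } else {
        rec <- classify_trial_phase2(seg, states[[id]]$required_hold, config,
                                     animal_id = id)
        if (rec$outcome == "discard") next
        old_hold <- states[[id]]$required_hold
        states[[id]] <- staircase_record_trial(states[[id]],
                                               rec$outcome == "success",
                                               config)
        if (states[[id]]$required_hold != old_hold)
          add_event(seg$t_init, id, "staircase_change",
                    sprintf("required_hold_ms=%g", states[[id]]$required_hold))
      }
      add_event(rec$t_init, id, "trial",
                sprintf("outcome=%s;reward_ul=%g", rec$outcome,
                        rec$reward_volume))
      trials[[length(trials) + 1L]] <- rec
    }
  }

  trials <- if (length(trials) > 0) do.call(rbind, trials) else
    trial_record(character(0), integer(0), numeric(0), numeric(0),
                 character(0), numeric(0), numeric(0), character(0))
  ev <- events
  ev$payload <- if ("payload" %in% names(events)) events$payload else ""
  all_events <- rbind(ev[, c("t_s", "animal_id", "kind", "payload")],
                      if (length(extra) > 0) do.call(rbind, extra))
  all_events <- all_events[order(all_events$t_s), , drop = FALSE]
  rownames(all_events) <- NULL
  list(trials = trials, events = all_events, states = states)
}

check_entry_exit_alternation <- function(events) {
  ee <- events[events$kind %in% c("entry", "exit"), , drop = FALSE]
  for (id in unique(ee$animal_id)) {
    k <- ee$kind[ee$animal_id == id]
    expected <- rep(c("entry", "exit"), length.out = length(k))
    if (!all(k == expected))
      stop("entry/exit events must alternate (starting with entry) for animal ", id)
  }
  invisible(events)
}

# entry/exit event pairs -> one row per visit; an unmatched trailing entry
# is closed at end_time with a warning
visits_from_events <- function(events, end_time = max(events$t_s)) {
  ee <- events[events$kind %in% c("entry", "exit"), , drop = FALSE]
  out <- list()
  for (id in unique(ee$animal_id)) {
    k <- ee[ee$animal_id == id, , drop = FALSE]
    ent <- k$t_s[k$kind == "entry"]
    ext <- k$t_s[k$kind == "exit"]
    if (length(ent) > length(ext)) {
      warning("unmatched entry for animal ", id, "; closing at stream end")
      ext <- c(ext, end_time)
    }
    if (length(ent) > 0)
      out[[length(out) + 1L]] <- data.frame(animal_id = id, t_entry = ent,
                                            t_exit = ext,
                                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(animal_id = character(0), t_entry = numeric(0),
                      t_exit = numeric(0)))
  do.call(rbind, out)
}
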
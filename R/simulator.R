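#' Virtual-mouse agent profile
#'
#' Parameter set for one simulated animal: how often it visits the chamber
#' and when (a 24-value circadian intensity profile), how its hold skill
#' evolves (a logistic success model with linear learning), and the shape
#' of the lever traces it produces (rise to a Gaussian peak, Gaussian hold
#' level with sample noise and linear drift, release to rest). Presets
#' encode the phenotypes the task is designed to separate: a steady-holding
#' `"wt"` animal, an overshoot-and-release `"hd"` animal, an always-correct
#' `"perfect"` agent, a `"deadzone"` agent whose success rate never leaves
#' the staircase's no-change band, and a `"nonacquirer"` that stops
#' performing after the first day.
#'
#' @param animal_id Animal identifier.
#' @param preset One of `"wt"`, `"hd"`, `"perfect"`, `"deadzone"`,
#'   `"nonacquirer"`, or `"custom"` (use the defaults below as given).
#' @param circadian_weights 24 non-negative relative entry intensities, one
#'   per hour of day. Default: dark phase emphasised, strongest over the
#'   first 6 h after lights-off.
#' @param visits_per_day Mean chamber visits per day (Poisson).
#' @param trials_per_visit Mean trials per visit (Poisson).
#' @param visit_duration_s Mean visit duration, seconds (exponential,
#'   floored at 60 s); visits are stretched if needed to fit their trials.
#' @param skill_ms Hold duration the agent can sustain with probability
#'   one-half, ms.
#' @param learning_rate Skill gain per phase-2 trial, ms/trial.
#' @param skill_max Skill ceiling, ms.
#' @param tau_ms Logistic slope of the success model, ms: the probability
#'   of sustaining a required hold `d` is `1 / (1 + exp((d - skill)/tau))`.
#' @param pull_peak_mean,pull_peak_sd Peak displacement of the initial
#'   pull, degrees.
#' @param hold_level_mean,hold_level_sd Hold-segment level, degrees.
#' @param hold_noise_sd Per-sample Gaussian noise on the hold segment,
#'   degrees.
#' @param release_slope_mean,release_slope_sd Linear drift of the hold
#'   segment, degrees/s (negative = progressive release).
#' @param rise_speed Lever speed during rise and release, degrees/s.
#' @param quit_after_days Day index after which the agent stops performing
#'   trials (visits continue); `Inf` to never quit.
#' @return An object of class `"agent_profile"`.
#' @examples
#' agent_profile("m1", preset = "hd")
#' @export
agent_profile <- function(animal_id,
                          preset = "custom",
                          circadian_weights = default_circadian_weights(),
                          visits_per_day = 20,
                          trials_per_visit = 20,
                          visit_duration_s = 300,
                          skill_ms = 250,
                          learning_rate = 4,
                          skill_max = 1500,
                          tau_ms = 50,
                          pull_peak_mean = 14,
                          pull_peak_sd = 1,
                          hold_level_mean = 12,
                          hold_level_sd = 0.8,
                          hold_noise_sd = 0.3,
                          release_slope_mean = -0.5,
                          release_slope_sd = 0.4,
                          rise_speed = 150,
                          quit_after_days = Inf) {
  p <- list(animal_id = animal_id, preset = preset,
            circadian_weights = circadian_weights,
            visits_per_day = visits_per_day,
            trials_per_visit = trials_per_visit,
            visit_duration_s = visit_duration_s,
            skill_ms = skill_ms, learning_rate = learning_rate,
            skill_max = skill_max, tau_ms = tau_ms,
            pull_peak_mean = pull_peak_mean, pull_peak_sd = pull_peak_sd,
            hold_level_mean = hold_level_mean, hold_level_sd = hold_level_sd,
            hold_noise_sd = hold_noise_sd,
            release_slope_mean = release_slope_mean,
            release_slope_sd = release_slope_sd,
            rise_speed = rise_speed, quit_after_days = quit_after_days)
  overrides <- switch(preset,
    custom = list(),
    wt = list(),
    hd = list(pull_peak_mean = 18.5, pull_peak_sd = 1.0,
              hold_level_mean = 16, hold_level_sd = 1.0,
              hold_noise_sd = 0.5,
              release_slope_mean = -5, release_slope_sd = 1.5,
              learning_rate = 3),
    perfect = list(pull_peak_sd = 0, hold_level_sd = 0, hold_noise_sd = 0,
                   release_slope_mean = 0, release_slope_sd = 0,
                   skill_ms = 1e6, learning_rate = 0),
    deadzone = list(skill_ms = 80, learning_rate = 0),
    nonacquirer = list(visits_per_day = 10, trials_per_visit = 8,
                       quit_after_days = 1),
    stop("unknown preset: ", preset)
  )
  p[names(overrides)] <- overrides
  if (length(p$circadian_weights) != 24 || any(p$circadian_weights < 0) ||
      sum(p$circadian_weights) == 0)
    stop("circadian_weights must be 24 non-negative values, not all zero")
  stopifnot(p$skill_ms >= 0, p$tau_ms > 0, p$rise_speed > 0,
            p$pull_peak_sd >= 0, p$hold_level_sd >= 0, p$hold_noise_sd >= 0,
            p$release_slope_sd >= 0, p$visit_duration_s > 0)
  class(p) <- "agent_profile"
  p
}

#' @rdname agent_profile
#' @param lights_on_hour,dark_phase_hours Photoperiod used to place the
#'   default activity emphasis.
#' @export
default_circadian_weights <- function(lights_on_hour = 7,
                                      dark_phase_hours = 12) {
  w <- rep(1, 24)
  lights_off <- (lights_on_hour + 24 - dark_phase_hours) %% 24
  early <- (lights_off + 0:5) %% 24
  late <- (lights_off + 6:(dark_phase_hours - 1)) %% 24
  w[early + 1] <- 6
  w[late + 1] <- 3
  w
}

#' @export
print.agent_profile <- function(x, ...) {
  cat(sprintf("<agent_profile> %s (preset %s): peak %g+-%g deg, hold %g+-%g deg, drift %g deg/s, skill %g ms\n",
              x$animal_id, x$preset, x$pull_peak_mean, x$pull_peak_sd,
              x$hold_level_mean, x$hold_level_sd, x$release_slope_mean,
              x$skill_ms))
  invisible(x)
}

#' Hold-success model
#'
#' The probability that an agent with skill `skill_ms` sustains a required
#' hold of `required_hold` ms is logistic:
#' `1 / (1 + exp((required_hold - skill_ms) / tau_ms))`. After each phase-2
#' trial the skill increases by `learning_rate` up to `skill_max`.
#'
#' @param required_hold Required hold duration, ms.
#' @param skill_ms Current skill, ms.
#' @param tau_ms Logistic slope, ms.
#' @return `success_probability()`: a probability. `step_skill()`: the
#'   profile with updated `skill_ms`.
#' @export
success_probability <- function(required_hold, skill_ms, tau_ms = 50) {
  1 / (1 + exp((required_hold - skill_ms) / tau_ms))
}

#' @rdname success_probability
#' @param profile An [agent_profile()].
#' @param outcome Trial outcome (unused: practice drives learning
#'   regardless of success).
#' @export
step_skill <- function(profile, outcome = NULL) {
  profile$skill_ms <- min(profile$skill_max,
                          profile$skill_ms + profile$learning_rate)
  profile
}

#' Sample a chamber-visit schedule
#'
#' Draws entry/exit events for one agent over `n_days` days: visit counts
#' are Poisson per day, start hours follow the agent's circadian weights,
#' and durations are exponential. Visits are made non-overlapping within
#' the animal by pushing each visit after the previous one ends.
#'
#' @param profile An [agent_profile()].
#' @param n_days Number of days to simulate.
#' @param config A [task_config()].
#' @return Data frame of visits: `animal_id`, `day`, `t_entry`, `t_exit`
#'   (seconds since experiment start), time-ordered. Draws come from R's
#'   current RNG stream; seed it for reproducibility.
#' @export
sample_visit_schedule <- function(profile, n_days, config) {
  rows <- list()
  for (d in seq_len(n_days) - 1L) {
    nv <- stats::rpois(1, profile$visits_per_day)
    if (nv == 0) next
    hour <- sample(0:23, nv, replace = TRUE,
                   prob = profile$circadian_weights) + stats::runif(nv)
    dur <- pmax(60, stats::rexp(nv, 1 / profile$visit_duration_s))
    start <- d * 86400 + (hour - config$start_hour) %% 24 * 3600
    rows[[length(rows) + 1L]] <- data.frame(
      animal_id = profile$animal_id, day = d, t_entry = start,
      t_exit = start + dur, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(animal_id = character(0), day = integer(0),
                      t_entry = numeric(0), t_exit = numeric(0)))
  v <- do.call(rbind, rows)
  v <- v[order(v$t_entry), , drop = FALSE]
  # enforce non-overlap within the animal
  for (i in seq_len(nrow(v))[-1]) {
    if (v$t_entry[i] <= v$t_exit[i - 1]) {
      shift <- v$t_exit[i - 1] + 1 - v$t_entry[i]
      v$t_entry[i] <- v$t_entry[i] + shift
      v$t_exit[i] <- v$t_exit[i] + shift
    }
  }
  rownames(v) <- NULL
  v
}

#' Generate one synthetic lever trace
#'
#' Builds a trial trace from the agent's kinematic parameters: a linear
#' rise at `rise_speed` to a Gaussian peak, a hold segment at a Gaussian
#' level with linear drift and per-sample Gaussian noise, then a linear
#' release back to rest. If `intend_success` the hold segment outlasts the
#' required hold duration; otherwise the agent lets go after a uniform
#' fraction (10--80%) of it. The trace is what the agent *attempts*; the
#' recorded outcome is always whatever [classify_trial_phase2()] says about
#' the trace.
#'
#' @param profile An [agent_profile()].
#' @param required_hold Required hold duration, ms.
#' @param intend_success Logical: does the agent attempt a full hold?
#' @param config A [task_config()].
#' @param t0 Absolute start time of the trace, seconds.
#' @return A [lever_trace()], samples clipped to the lever's mechanical
#'   range.
#' @export
generate_trace <- function(profile, required_hold, intend_success, config,
                           t0 = 0) {
  sp <- config$sample_period
  peak <- stats::rnorm(1, profile$pull_peak_mean, profile$pull_peak_sd)
  peak <- min(max(peak, config$pull_threshold), config$lever_range_max)
  level <- stats::rnorm(1, profile$hold_level_mean, profile$hold_level_sd)
  slope <- stats::rnorm(1, profile$release_slope_mean,
                        profile$release_slope_sd)

  step_deg <- profile$rise_speed * sp / 1000
  rise <- seq(0, peak, by = step_deg)
  if (rise[length(rise)] < peak) rise <- c(rise, peak)

  hold_ms <- if (intend_success) required_hold + 200 else
    stats::runif(1, 0.05, 0.6) * required_hold
  n_hold <- max(1L, as.integer(round(hold_ms / sp)))
  t_hold <- seq_len(n_hold) * sp / 1000
  hold <- level + slope * t_hold +
    stats::rnorm(n_hold, 0, profile$hold_noise_sd)

  # a failed hold ends in a quick let-go; a completed one is released at
  # the ordinary movement speed
  rel_step <- if (intend_success) step_deg else 3 * step_deg
  last <- hold[n_hold]
  release <- if (last > 0) seq(last, 0, by = -rel_step)[-1] else numeric(0)
  samples <- c(rise, hold, release, 0)
  samples <- pmin(pmax(samples, 0), config$lever_range_max)
  lever_trace(samples, t0 = t0, sample_period = sp)
}

#' Simulate a full cage run
#'
#' End-to-end virtual experiment: each agent visits the chamber on its own
#' circadian schedule (one animal in the chamber at a time; concurrent
#' visits are queued), performs pull-and-hold trials whose traces come from
#' [generate_trace()], and every trace is scored by the real controller
#' ([detect_trials()] + phase classifiers), which also drives the per-animal
#' staircase. Each animal draws from its own seeded substream, so adding an
#' animal does not perturb the others.
#'
#' @param profiles List of [agent_profile()] objects.
#' @param n_days Total days to simulate.
#' @param phase1_days Days of acquisition phase before the hold phase
#'   starts (trials on day `>= phase1_days` run under phase-2 rules).
#' @param config A [task_config()].
#' @param seed Master seed (integer).
#' @return An object of class `"sim_output"`: list with `events` (session
#'   events including rewards and staircase changes), `trials`, `traces`
#'   (named list of [lever_trace()] keyed by `trace_id`), `states`
#'   (staircase states), `profiles` (ground truth, with final skill),
#'   `config`, `seed`.
#' @examples
#' sim <- simulate_cage(list(agent_profile("m1", preset = "perfect")),
#'                      n_days = 2, phase1_days = 0,
#'                      config = task_config(), seed = 1)
#' nrow(sim$trials)
#' @export
simulate_cage <- function(profiles, n_days, phase1_days, config, seed) {
  stopifnot(length(profiles) >= 1, n_days >= 1, phase1_days >= 0)
  ids <- vapply(profiles, function(p) p$animal_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate animal_id in profiles")

  # per-animal visit schedules from independent substreams
  visits <- list()
  for (i in seq_along(profiles)) {
    set.seed(substream_seed(seed, i, 1L))
    visits[[i]] <- sample_visit_schedule(profiles[[i]], n_days, config)
  }
  visits <- do.call(rbind, visits)
  visits <- visits[order(visits$t_entry), , drop = FALSE]

  states <- stats::setNames(
    lapply(ids, staircase_state, config = config), ids)
  skills <- stats::setNames(profiles, ids)
  trial_counter <- stats::setNames(rep(0L, length(ids)), ids)
  trials <- list()
  traces <- list()
  extra_events <- list()

  # trial generation draws: one substream per animal, consumed in that
  # animal's visit order
  rng_state <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_along(profiles)) {
    set.seed(substream_seed(seed, i, 2L))
    rng_state[[ids[i]]] <- get(".Random.seed", envir = .GlobalEnv)
  }

  prev_exit <- -Inf
  for (vi in seq_len(nrow(visits))) {
    id <- visits$animal_id[vi]
    prof <- skills[[id]]
    # one animal in the chamber at a time: queue concurrent visits
    if (visits$t_entry[vi] <= prev_exit) {
      shift <- prev_exit + 1 - visits$t_entry[vi]
      visits$t_entry[vi] <- visits$t_entry[vi] + shift
      visits$t_exit[vi] <- visits$t_exit[vi] + shift
    }
    day <- max(visits$day[vi], floor(visits$t_entry[vi] / 86400))
    phase <- if (day < phase1_days) 1L else 2L
    lambda <- if (day >= prof$quit_after_days) 0 else prof$trials_per_visit

    assign(".Random.seed", rng_state[[id]], envir = .GlobalEnv)
    n_tr <- if (lambda > 0) stats::rpois(1, lambda) else 0L
    t_cursor <- visits$t_entry[vi] + 2
    for (k in seq_len(n_tr)) {
      gap <- stats::rexp(1, 1 / 3)
      if (phase == 1L) {
        tr <- generate_trace(prof, required_hold = 100,
                             intend_success = TRUE, config,
                             t0 = t_cursor + gap)
      } else {
        req <- states[[id]]$required_hold
        p <- success_probability(req, prof$skill_ms, prof$tau_ms)
        intend <- stats::runif(1) < p
        tr <- generate_trace(prof, required_hold = req,
                             intend_success = intend, config,
                             t0 = t_cursor + gap)
      }
      t_cursor <- tr$t0 + (length(tr$samples) - 1) * tr$sample_period / 1000

      segs <- detect_trials(tr, config)
      if (length(segs) == 0) next
      seg <- segs[[1]]
      trial_counter[[id]] <- trial_counter[[id]] + 1L
      trace_id <- sprintf("%s_t%05d", id, trial_counter[[id]])
      if (phase == 1L) {
        rec <- classify_trial_phase1(seg, config, animal_id = id)
      } else {
        rec <- classify_trial_phase2(seg, states[[id]]$required_hold, config,
                                     animal_id = id)
        prof <- step_skill(prof)
        if (rec$outcome != "discard") {
          old_hold <- states[[id]]$required_hold
          states[[id]] <- staircase_record_trial(
            states[[id]], rec$outcome == "success", config)
          if (states[[id]]$required_hold != old_hold)
            extra_events[[length(extra_events) + 1L]] <- data.frame(
              t_s = rec$t_init, animal_id = id, kind = "staircase_change",
              payload = sprintf("required_hold_ms=%g",
                                states[[id]]$required_hold),
              stringsAsFactors = FALSE)
        }
      }
      rec$trace_id <- trace_id
      traces[[trace_id]] <- tr
      trials[[length(trials) + 1L]] <- rec
      extra_events[[length(extra_events) + 1L]] <- data.frame(
        t_s = rec$t_init, animal_id = id, kind = "trial",
        payload = sprintf("outcome=%s;reward_ul=%g", rec$outcome,
                          rec$reward_volume),
        stringsAsFactors = FALSE)
    }
    # visit must contain its trials
    visits$t_exit[vi] <- max(visits$t_exit[vi], t_cursor + 1)
    prev_exit <- visits$t_exit[vi]
    rng_state[[id]] <- get(".Random.seed", envir = .GlobalEnv)
    skills[[id]] <- prof
  }

  ev_entry <- data.frame(t_s = visits$t_entry, animal_id = visits$animal_id,
                         kind = "entry", payload = "",
                         stringsAsFactors = FALSE)
  ev_exit <- data.frame(t_s = visits$t_exit, animal_id = visits$animal_id,
                        kind = "exit", payload = "", stringsAsFactors = FALSE)
  reward_rows <- list()
  for (id in ids) {
    ent <- sort(visits$t_entry[visits$animal_id == id])
    vols <- entry_rewards(ent, config)
    keep <- vols > 0
    if (any(keep))
      reward_rows[[length(reward_rows) + 1L]] <- data.frame(
        t_s = ent[keep], animal_id = id, kind = "entry_reward",
        payload = sprintf("volume_ul=%g", vols[keep]),
        stringsAsFactors = FALSE)
  }
  events <- rbind(ev_entry, ev_exit,
                  if (length(reward_rows)) do.call(rbind, reward_rows),
                  if (length(extra_events)) do.call(rbind, extra_events))
  events <- events[order(events$t_s, events$animal_id, events$kind), ,
                   drop = FALSE]
  rownames(events) <- NULL

  trials <- if (length(trials) > 0) do.call(rbind, trials) else
    trial_record(character(0), integer(0), numeric(0), numeric(0),
                 character(0), numeric(0), numeric(0), character(0))
  rownames(trials) <- NULL

  structure(list(events = events, trials = trials, traces = traces,
                 states = states, profiles = skills, config = config,
                 seed = seed),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("<sim_output> seed %d: %d animals, %d trials, %d traces, %d events\n",
              x$seed, length(x$profiles), nrow(x$trials), length(x$traces),
              nrow(x$events)))
  invisible(x)
}

# deterministic 32-bit substream seed per (master seed, animal, purpose)
substream_seed <- function(seed, i, purpose) {
  as.integer((as.numeric(seed) * 1000003 + i * 7919 + purpose * 104729) %%
               2147483647)
}
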
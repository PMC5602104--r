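#' Task configuration
#'
#' Build the full parameter set of the lever-positioning task. Defaults are
#' the task constants of the published apparatus: the lever moves over a 24
#' degree range, a trial initiates when it is pulled 12 degrees back from
#' rest, and in the hold phase it must stay inside the 4.5--19.5 degree goal
#' range for the required hold duration. The required duration starts at
#' 100 ms and is re-evaluated every 25 trials: above a 75% block success
#' rate it steps up 100 ms (to an 800 ms ceiling), below 10% it steps down
#' 100 ms (to the 100 ms floor). Chamber entries dispense a 5 microlitre
#' drop up to 200 per day; successful trials dispense 10 microlitres.
#'
#' @param lever_range_max Mechanical range of the lever, degrees.
#' @param pull_threshold Angle at which a trial initiates, degrees from rest.
#' @param goal_low,goal_high Goal range the lever must be held within
#'   during phase 2, degrees from rest (inclusive bounds).
#' @param hold_init,hold_max,hold_step Initial, maximum and increment of the
#'   required hold duration, ms. `hold_step` must divide
#'   `hold_max - hold_init`.
#' @param block_size Number of trials per staircase evaluation block.
#' @param up_threshold,down_threshold Block success fractions governing the
#'   staircase: strictly above `up_threshold` steps the duration up, strictly
#'   below `down_threshold` steps it down, otherwise it is unchanged.
#' @param entry_reward_volume Volume dispensed on chamber entry, microlitres.
#' @param entry_reward_daily_cap Maximum rewarded entries per animal per day.
#' @param trial_reward_volume Volume dispensed for a rewarded trial,
#'   microlitres.
#' @param rearm_threshold Angle below which the lever must return before the
#'   next trial can initiate, degrees.
#' @param sample_period Lever trace sampling period, ms. Must divide
#'   `hold_init` and `hold_step`.
#' @param lights_on_hour Hour of day (0-23) at which lights turn on. Day
#'   boundaries for the entry-reward cap and per-day metrics are anchored
#'   here.
#' @param dark_phase_hours Length of the dark phase, hours.
#' @param start_hour Hour of day at experiment time zero; timestamps are
#'   seconds since experiment start.
#'
#' @return An object of class `"task_config"`: a validated named list.
#' @examples
#' cfg <- task_config()
#' cfg$goal_high
#' @export
task_config <- function(lever_range_max = 24,
                        pull_threshold = 12,
                        goal_low = 4.5,
                        goal_high = 19.5,
                        hold_init = 100,
                        hold_max = 800,
                        hold_step = 100,
                        block_size = 25,
                        up_threshold = 0.75,
                        down_threshold = 0.10,
                        entry_reward_volume = 5,
                        entry_reward_daily_cap = 200,
                        trial_reward_volume = 10,
                        rearm_threshold = 1.0,
                        sample_period = 10,
                        lights_on_hour = 7,
                        dark_phase_hours = 12,
                        start_hour = 0) {
  cfg <- list(
    lever_range_max = lever_range_max,
    pull_threshold = pull_threshold,
    goal_low = goal_low,
    goal_high = goal_high,
    hold_init = hold_init,
    hold_max = hold_max,
    hold_step = hold_step,
    block_size = block_size,
    up_threshold = up_threshold,
    down_threshold = down_threshold,
    entry_reward_volume = entry_reward_volume,
    entry_reward_daily_cap = entry_reward_daily_cap,
    trial_reward_volume = trial_reward_volume,
    rearm_threshold = rearm_threshold,
    sample_period = sample_period,
    lights_on_hour = lights_on_hour,
    dark_phase_hours = dark_phase_hours,
    start_hour = start_hour
  )
  class(cfg) <- "task_config"
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "task_config"))
  with(cfg, {
    if (!(pull_threshold > 0 && pull_threshold < lever_range_max))
      stop("pull_threshold must lie strictly inside (0, lever_range_max)")
    if (!(goal_low < pull_threshold && pull_threshold < goal_high &&
          goal_high <= lever_range_max))
      stop("goal range must satisfy goal_low < pull_threshold < goal_high <= lever_range_max")
    if (!(hold_init <= hold_max))
      stop("hold_init must not exceed hold_max")
    if (!(hold_step > 0))
      stop("hold_step must be positive")
    if ((hold_max - hold_init) %% hold_step != 0)
      stop("hold_step must divide hold_max - hold_init")
    if (!(down_threshold >= 0 && down_threshold < up_threshold && up_threshold <= 1))
      stop("need 0 <= down_threshold < up_threshold <= 1")
    if (block_size < 1) stop("block_size must be >= 1")
    if (sample_period <= 0) stop("sample_period must be positive")
    if (hold_init %% sample_period != 0 || hold_step %% sample_period != 0)
      stop("sample_period must divide hold_init and hold_step")
    if (!(lights_on_hour >= 0 && lights_on_hour < 24))
      stop("lights_on_hour must be in [0, 24)")
    if (entry_reward_daily_cap < 0 || entry_reward_volume < 0 ||
        trial_reward_volume < 0)
      stop("reward volumes and cap must be non-negative")
  })
  invisible(cfg)
}

#' @export
print.task_config <- function(x, ...) {
  cat("Lever task configuration\n")
  cat(sprintf("  lever range 0-%g deg; initiation at %g deg; goal [%g, %g] deg\n",
              x$lever_range_max, x$pull_threshold, x$goal_low, x$goal_high))
  cat(sprintf("  hold: %g -> %g ms in %g ms steps, %d-trial blocks (>%.0f%% up, <%.0f%% down)\n",
              x$hold_init, x$hold_max, x$hold_step, x$block_size,
              100 * x$up_threshold, 100 * x$down_threshold))
  cat(sprintf("  rewards: %g ul entry (cap %d/day), %g ul trial; lights on at %02d:00\n",
              x$entry_reward_volume, x$entry_reward_daily_cap,
              x$trial_reward_volume, x$lights_on_hour))
  invisible(x)
}

#' Read or write a task configuration file
#'
#' Configurations are stored as a flat YAML mapping mirroring the
#' [task_config()] fields; missing keys take their defaults.
#'
#' @param path File path.
#' @param cfg A `task_config` object.
#' @return `read_task_config()` returns a `task_config`;
#'   `write_task_config()` returns `path` invisibly.
#' @export
read_task_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(task_config))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0)
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  do.call(task_config, vals)
}

#' @rdname read_task_config
#' @export
write_task_config <- function(cfg, path) {
  validate_task_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# staircase lattice of admissible hold durations
hold_levels <- function(cfg) seq(cfg$hold_init, cfg$hold_max, by = cfg$hold_step)
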
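# Independent reference implementations and fixture builders used across
# the suite. The oracles deliberately use a different computational route
# from the package code they check.

# Brute-force phase-2 checker: walk the hold window sample by sample, in
# simulated time, and stop at the first violation.
oracle_phase2 <- function(samples, required_hold, cfg, sp = cfg$sample_period) {
  n_need <- required_hold / sp + 1  # samples at 0, sp, ..., required_hold
  for (i in seq_along(samples)) {
    a <- samples[i]
    if (a < cfg$goal_low || a > cfg$goal_high)
      return(if (i <= n_need) "failure" else "success")
  }
  if (length(samples) >= n_need) "success" else "discard"
}

# OLS slope by explicit normal equations (matrix solve), angle vs seconds.
oracle_slope <- function(t_ms, y, window = c(200, 800)) {
  keep <- t_ms >= window[1] & t_ms <= window[2]
  X <- cbind(1, t_ms[keep] / 1000)
  beta <- solve(t(X) %*% X, t(X) %*% y[keep])
  beta[2]
}

# A plausible random trial segment: starts at/above the initiation
# threshold, wanders, may or may not leave the goal range.
random_segment <- function(cfg, n = 120) {
  start <- runif(1, cfg$pull_threshold, cfg$goal_high + 1)
  steps <- rnorm(n - 1, mean = runif(1, -0.15, 0.1), sd = runif(1, 0.05, 0.6))
  x <- pmin(pmax(cumsum(c(start, steps)), 0), cfg$lever_range_max)
  lever_trace(x, sample_period = cfg$sample_period)
}

# Wrap a bare sample vector as a detected segment (first sample is the
# initiation sample), bypassing detection.
as_segment <- function(samples, cfg, t0 = 0) {
  list(t_init = t0, trace = lever_trace(samples, t0 = t0,
                                        sample_period = cfg$sample_period),
       complete = TRUE)
}

# Constant-hold trace used for boundary recovery: rise in 2-degree steps
# to theta, then hold theta for hold_ms.
constant_hold_trace <- function(theta, hold_ms, cfg) {
  rise <- seq(0, theta, by = 2)
  if (rise[length(rise)] < theta) rise <- c(rise, theta)
  lever_trace(c(rise, rep(theta, hold_ms / cfg$sample_period)),
              sample_period = cfg$sample_period)
}

# Rise to 13 degrees, settle instantly to theta, hold.
settle_trace <- function(theta, hold_ms, cfg) {
  rise <- c(seq(0, 12, by = 6), 13)
  lever_trace(c(rise, rep(theta, hold_ms / cfg$sample_period)),
              sample_period = cfg$sample_period)
}

# Pull to peak theta and return to rest (phase-1 probe).
pull_release_trace <- function(theta, cfg) {
  up <- seq(0, theta, length.out = 25)
  lever_trace(c(up, rev(up)[-1], 0), sample_period = cfg$sample_period)
}

# Simple alternating entry/exit event frame for one or more animals.
make_visit_events <- function(visits) {
  ev <- rbind(
    data.frame(t_s = visits$t_entry, animal_id = visits$animal_id,
               kind = "entry", stringsAsFactors = FALSE),
    data.frame(t_s = visits$t_exit, animal_id = visits$animal_id,
               kind = "exit", stringsAsFactors = FALSE))
  ev <- ev[order(ev$t_s), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}
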
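---
title: "The levercage task model: controller, kinematics and virtual mice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The levercage task model: controller, kinematics and virtual mice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(levercage)
```

## The task

`levercage` implements the decision logic of an automated home-cage
lever-positioning task for group-housed, RFID-identified mice. A lever is
restricted to a 24° horizontal range and recorded by a rotary encoder;
mice enter a small chamber (identified by their RFID chip, which earns a
5 µl water drop up to 200 times per animal per day) and pull the lever.

Testing has two phases:

* **Phase 1 (acquisition).** Pulling the lever back past the centre of
  its range — 12° from rest — is rewarded with a 10 µl drop on a
  continuous reinforcement schedule. Animals that fail to perform
  strictly more than 200 trials in this phase are flagged
  `not_acquired` and excluded.
* **Phase 2 (hold).** After the 12° crossing the lever must stay within
  a goal range of 4.5°–19.5° for a required hold duration before the
  drop is dispensed; leaving the range earlier records a failure and no
  water. The required duration starts at 100 ms and adapts per animal:
  every 25 trials, a block success rate strictly above 75% raises it by
  100 ms (to an 800 ms ceiling) and a rate strictly below 10% lowers it
  by 100 ms (to the 100 ms floor); anything in between leaves it
  unchanged.

All of these constants live in `task_config()` and every rule above is an
operational outcome of the code, recovered by the acceptance checks
(e.g., the goal bounds by bisection on synthetic traces).

## Controller contracts and edge policies

Several details are deliberate policies where the task description admits
more than one reading; they are fixed here as the package's contract:

* **Inclusive thresholds.** Initiation fires at angle ≥ 12°, and the
  goal range is the closed interval [4.5°, 19.5°]. Encoder quantisation
  makes open and closed bounds indistinguishable in practice; the
  inclusive form is the simplest testable contract.
* **Hold timing.** The hold clock starts at the initiation sample (the
  12° crossing), which necessarily lies inside the goal range, and the
  window includes both endpoints on the sample lattice: a hold of
  *d* ms at a 10 ms period checks samples 0 through *d*/10.
* **One trial per pull.** After initiation the detector disarms until
  the lever returns below a 1° re-arm threshold, so oscillation around
  12° cannot double-count trials. The re-arm angle is configurable.
* **Strict block thresholds.** With 25-trial blocks the staircase steps
  up only at ≥ 19/25 and down only at ≤ 2/25; exactly 75% or 10% leaves
  the duration unchanged.
* **Truncated trials.** A phase-2 trial cut off by the end of a
  recording while still inside the goal range is discarded, not scored,
  avoiding truncation bias; a pull initiating on a stream's final
  sample is likewise dropped.
* **Day boundaries.** "Per day" quantities — the 200-drop entry-reward
  cap, daily trial counts, chamber time — reset at the lights-on
  instant (07:00 by default), keeping them aligned with the photoperiod
  used by the circadian analyses. The entry cap is per animal.
* **Sampling.** Traces are uniform at 100 Hz by default; the
  configuration requires the sample period to divide the hold-duration
  lattice, so every staircase level is exactly representable.

## Kinematic features

For each trial segment (initiation to re-arm) three features are
computed:

* `max_displacement` — the largest sampled angle (degrees);
* `hold_slope` — the ordinary least-squares slope of angle against time
  over samples 200–800 ms after initiation (degrees/s), computed on raw
  samples with no smoothing; strongly negative values indicate a
  progressive release of the lever during the hold, the signature of
  motor impersistence;
* `mean_speed` — the mean absolute sample-to-sample velocity
  (degrees/s) over the full segment. "Speed" admits several readings;
  mean absolute instantaneous velocity over the whole trial is used
  because it is the most literal one, and the analysis window is a
  parameter if the hold-only variant is wanted.

`aggregate_kinematics()` averages features per animal over successful
trials at the ceiling duration only, and reports an animal only when it
has at least 200 such trials (configurable); per-trial slopes are
averaged rather than fitting one slope to an averaged trace, so the
summary is an unweighted mean of independent trials with an SD attached.

## The virtual cage

The simulator exists so the whole pipeline can be exercised end-to-end
at desk scale; it is a generative invention, not a fit to any animal
data. Its parts are the simplest forms that can express the phenotypes
the task is meant to detect:

* **Visits** are Poisson per day (default 20/day), with start hours
  drawn from a 24-value circadian weight vector (default: weight 6 for
  the first six dark hours, 3 for the rest of the dark phase, 1 in the
  light — the usual nocturnal activity profile) and exponential
  durations (default mean 300 s). One animal occupies the chamber at a
  time; concurrent visits queue.
* **Trials** are Poisson per visit (default 20). Whether the agent
  *attempts* a full hold is Bernoulli with logistic probability
  `1/(1 + exp((d - skill)/tau))` at required duration `d`; skill grows
  linearly per phase-2 trial up to a ceiling. An attempted hold outlasts
  the requirement by 200 ms; an abandoned one releases after 5–60% of it
  with a fast let-go.
* **Traces** rise linearly (150°/s) to a Gaussian peak, hold at a
  Gaussian level with linear drift and Gaussian sample noise, then
  release to rest, clipped to the lever's range. Crucially, the recorded
  outcome is never set by fiat: every generated trace is scored by the
  same `detect_trials()`/`classify_trial_phase2()` code that scores real
  recordings, and the staircase advances from those outcomes.
* **Presets.** `wt` (peak 14 ± 1°, hold 12 ± 0.8°, drift −0.5 °/s)
  holds steadily just past centre; `hd` (peak 18.5 ± 1°, hold 16 ± 1°,
  drift −5 °/s) pulls deep into the goal range and progressively
  releases — the overshoot-and-release morphology; `perfect` is
  noiseless and always correct; `deadzone` (skill 80 ms, no learning)
  has a ~40–50% success rate at the floor, inside the staircase's
  no-change band; `nonacquirer` stops performing after day 1 and fails
  the acquisition criterion.

Reproducibility is part of the contract: each animal draws from its own
substream derived from the master seed, so identical inputs give
byte-identical outputs and adding an animal does not perturb the others.

What the simulator does *not* emulate: real lever biomechanics,
within-trial corrective movements, satiety or weight dynamics, and any
coupling between circadian state and kinematics. Passing tests therefore
show that the controller, staircase and feature definitions behave as
specified on traces of realistic shape — not that biological effect
sizes would be recovered from real animals.

## Numerical choices and problem sizes

Bisections for the boundary-recovery checks run to 0.01° on noiseless
constructed traces, where success is exactly monotone in the bisected
angle. The OLS slope uses the centred closed form, checked against an
explicit normal-equations solve to 1e-9. The staircase monotonicity
property (more block successes never yield a lower duration) is checked
by randomised search over short success-count sequences; classifier
correctness by 1000 randomised traces against a sample-by-sample oracle.
Simulated experiments in the test-suite use 1–3 day runs with the
default visit and trial rates (roughly 300–500 trials per animal-day,
the realistic operating range for this apparatus), and the phenotype
sign-recovery study uses 100 replicates of 20 agents per group with 250
trials each — large enough that the group contrast is essentially
deterministic in sign.

## Known limitations

* The staircase replay (`progression_curve()`) and the live controller
  are two code paths with one contract; they are tested for agreement
  but the replay ignores discarded trials by construction, so feeding
  it raw outcome vectors that include discards would diverge.
* `reach_max_flag()` approximates the phase-2 start by the first block's
  end time; with very sparse trials this biases the horizon slightly
  late.
* Timestamps are plain seconds since experiment start with a clock
  anchor (`start_hour`); daylight-saving and calendar effects are out of
  scope.
* The event-log reader validates per-animal monotonicity and
  entry/exit alternation but does not attempt repair; malformed logs are
  errors, not warnings.
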
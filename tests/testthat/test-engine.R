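cfg <- task_config()

test_that("trial detection follows the arm/disarm cycle", {
  # lever never leaves rest: no trials
  expect_length(detect_trials(lever_trace(rep(0, 1000)), cfg), 0)

  # two clean pulls -> two trials
  tr <- lever_trace(c(0, 5, 14, 14, 6, 0.5, 0, 7, 13, 3, 0.2))
  segs <- detect_trials(tr, cfg)
  expect_length(segs, 2)
  # segments start at the initiation sample, end at the re-arm sample
  expect_equal(segs[[1]]$trace$samples, c(14, 14, 6, 0.5))
  expect_equal(segs[[2]]$trace$samples, c(13, 3, 0.2))
  expect_equal(segs[[1]]$t_init, 2 * cfg$sample_period / 1000)

  # oscillation around the initiation threshold without re-arming: 1 trial
  osc <- lever_trace(c(0, rep(c(11.9, 12.1), 100), 0.5))
  expect_length(detect_trials(osc, cfg), 1)

  # initiation is inclusive at exactly the threshold
  expect_length(detect_trials(lever_trace(c(0, 12, 0.5)), cfg), 1)
  expect_length(detect_trials(lever_trace(c(0, 11.99, 0.5)), cfg), 0)

  # out-of-range angles are rejected
  expect_error(detect_trials(lever_trace(c(0, 25, 0)), cfg), "range")
  expect_error(detect_trials(lever_trace(c(0, -2, 0)), cfg), "range")
})

test_that("phase-1 classification rewards every detected pull", {
  segs <- detect_trials(lever_trace(c(0, 5, 14, 3, 0.5)), cfg)
  rec <- classify_trial_phase1(segs[[1]], cfg, animal_id = "m1")
  expect_equal(rec$outcome, "success")
  expect_equal(rec$reward_volume, 10)
  expect_equal(rec$t_reward, rec$t_init)

  # peak exactly at threshold still counts
  segs2 <- detect_trials(lever_trace(c(0, 12, 0.5)), cfg)
  expect_equal(classify_trial_phase1(segs2[[1]], cfg)$outcome, "success")
})

test_that("phase-2 classification enforces the goal range over the hold window", {
  # constant at 12 degrees for 900 ms: success at 800 ms hold
  seg <- as_segment(rep(12, 91), cfg)
  rec <- classify_trial_phase2(seg, 800, cfg)
  expect_equal(rec$outcome, "success")
  expect_equal(rec$reward_volume, 10)
  expect_equal(rec$t_reward, rec$t_init + 0.8)

  # exits above goal_high at 400 ms: failure, no water
  samples <- c(rep(12, 40), 20.1, rep(12, 60))
  rec2 <- classify_trial_phase2(as_segment(samples, cfg), 800, cfg)
  expect_equal(rec2$outcome, "failure")
  expect_equal(rec2$reward_volume, 0)

  # goal-range bounds are inclusive
  expect_equal(classify_trial_phase2(as_segment(rep(19.5, 91), cfg),
                                     800, cfg)$outcome, "success")
  expect_equal(classify_trial_phase2(as_segment(c(rep(12, 50), rep(4.5, 41)),
                                                cfg), 800, cfg)$outcome,
               "success")
  expect_equal(classify_trial_phase2(as_segment(rep(19.51, 91), cfg),
                                     800, cfg)$outcome, "failure")

  # stream truncation inside the range: discarded, not scored
  expect_equal(classify_trial_phase2(as_segment(rep(12, 30), cfg),
                                     800, cfg)$outcome, "discard")

  # hold not representable on the sample lattice
  expect_error(classify_trial_phase2(seg, 805, cfg), "not representable")
})

test_that("phase-2 classifier agrees with the brute-force oracle", {
  set.seed(42)
  holds <- hold_levels(cfg)
  for (i in 1:1000) {
    tr <- random_segment(cfg, n = sample(30:140, 1))
    d <- sample(holds, 1)
    got <- classify_trial_phase2(list(t_init = 0, trace = tr), d, cfg)$outcome
    expect_identical(got, oracle_phase2(tr$samples, d, cfg))
  }
})

test_that("block evaluation applies the printed up/down rule with clamping", {
  expect_equal(evaluate_block(19, 25, 300, cfg), 400)  # 76% > 75%
  expect_equal(evaluate_block(2, 25, 300, cfg), 200)   # 8% < 10%
  expect_equal(evaluate_block(3, 25, 300, cfg), 300)   # 12%: dead zone
  # ties at the thresholds leave the duration unchanged
  expect_equal(evaluate_block(18, 25, 300, cfg), 300)  # 72% (<=75%)
  # exact 75% with a divisible block size
  cfg4 <- task_config(block_size = 4)
  expect_equal(evaluate_block(3, 4, 300, cfg4), 300)
  # ceiling and floor clamps
  expect_equal(evaluate_block(25, 25, 800, cfg), 800)
  expect_equal(evaluate_block(0, 25, 100, cfg), 100)
  # counts out of range
  expect_error(evaluate_block(26, 25, 300, cfg), "block")
})

test_that("staircase stays on the lattice and is monotone in block successes", {
  holds <- hold_levels(cfg)
  run_chain <- function(success_counts) {
    h <- cfg$hold_init
    sapply(success_counts, function(s) h <<- evaluate_block(s, 25, h, cfg))
  }
  set.seed(7)
  for (rep in 1:200) {
    a <- sample(0:25, 8, replace = TRUE)
    b <- pmax(0, a - sample(0:5, 8, replace = TRUE))  # b <= a elementwise
    ha <- run_chain(a)
    hb <- run_chain(b)
    expect_true(all(ha %in% holds) && all(hb %in% holds))
    expect_true(all(ha >= hb))
    expect_true(all(abs(diff(c(cfg$hold_init, ha))) %in% c(0, cfg$hold_step)))
  }
})

test_that("a perfect agent reaches the ceiling after exactly 175 trials", {
  st <- staircase_state("m1", cfg)
  first_max <- NA
  for (i in 1:500) {
    st <- staircase_record_trial(st, TRUE, cfg)
    if (is.na(first_max) && st$required_hold == cfg$hold_max) first_max <- i
  }
  expect_equal(first_max, 175)
  expect_equal(st$required_hold, 800)
  # duration just before trial 175 was below the ceiling
  expect_true(all(st$history$required_hold ==
                    seq(100, 800, by = 100)))
  expect_equal(st$history$trial, seq(0, 175, by = 25))
})

test_that("entry rewards are capped per animal per day and reset at lights-on", {
  # 300 entries in one day: only the first 200 are rewarded
  t_entries <- cfg$lights_on_hour * 3600 + seq_len(300) * 60
  vols <- entry_rewards(t_entries, cfg)
  expect_equal(vols[1], 5)
  expect_equal(sum(vols > 0), 200)
  expect_equal(vols[201:300], rep(0, 100))
  expect_equal(sum(vols), 1000)

  # first entry after the day boundary is rewarded again
  t2 <- c(t_entries, cfg$lights_on_hour * 3600 + 86400 + 10)
  v2 <- entry_rewards(t2, cfg)
  expect_equal(v2[301], 5)

  expect_equal(process_entry(0, cfg), 5)
  expect_equal(process_entry(200, cfg), 0)
})

test_that("run_session isolates animals and conserves dispensed volume", {
  sp <- cfg$sample_period
  pull <- function(ok) if (ok) c(12, rep(12, 90), 0.5) else c(12, 20, 0.5)
  # build interleaved traces for two animals with disjoint outcome patterns
  mk_traces <- function(outcomes, t_start) {
    lapply(seq_along(outcomes), function(i)
      lever_trace(c(0, pull(outcomes[i])),
                  t0 = t_start + (i - 1) * 2, sample_period = sp))
  }
  out_a <- rep(c(TRUE, FALSE), length.out = 30)
  out_b <- rep(TRUE, 30)
  tr_a <- mk_traces(out_a, 100)
  tr_b <- mk_traces(out_b, 300)
  ev <- make_visit_events(data.frame(
    animal_id = c("a", "b"), t_entry = c(95, 295), t_exit = c(250, 450),
    stringsAsFactors = FALSE))

  res <- run_session(ev, c(tr_a, tr_b), phase = 2, config = cfg)
  expect_equal(nrow(res$trials), 60)
  # staircase history per animal identical to running each alone
  res_a <- run_session(ev[ev$animal_id == "a", ], tr_a, 2, cfg)
  res_b <- run_session(ev[ev$animal_id == "b", ], tr_b, 2, cfg)
  expect_equal(res$states[["a"]]$history, res_a$states[["a"]]$history)
  expect_equal(res$states[["b"]]$history, res_b$states[["b"]]$history)
  expect_equal(res$states[["b"]]$required_hold, 200)  # 25 successes -> 1 step

  # conservation: total volume = 5 * rewarded entries + 10 * rewarded trials
  rewarded_entries <- sum(res$events$kind == "entry_reward")
  rewarded_trials <- sum(res$trials$reward_volume > 0)
  expect_equal(rewarded_entries, 2)
  total <- 5 * rewarded_entries + 10 * rewarded_trials
  ev_vol <- sum(as.numeric(sub("volume_ul=", "",
                 res$events$payload[res$events$kind == "entry_reward"]))) +
    sum(res$trials$reward_volume)
  expect_equal(ev_vol, total)

  # determinism
  res2 <- run_session(ev, c(tr_a, tr_b), phase = 2, config = cfg)
  expect_identical(res$trials, res2$trials)
  expect_identical(res$events, res2$events)

  # phase-1: every pull rewarded at 10 ul
  res1 <- run_session(ev[ev$animal_id == "a", ], tr_a, 1, cfg)
  expect_equal(nrow(res1$trials), 30)
  expect_equal(sum(res1$trials$reward_volume), 300)

  # a trace with no animal present is an attribution error
  expect_error(run_session(ev, list(lever_trace(c(0, 14, 0.2), t0 = 10)),
                           2, cfg), "attribution")
})
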
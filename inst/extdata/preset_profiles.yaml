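- animal_id: wt01
  preset: wt
  circadian_weights:
  - 6.0
  - 3.0
  - 3.0
  - 3.0
  - 3.0
  - 3.0
  - 3.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 6.0
  - 6.0
  - 6.0
  - 6.0
  - 6.0
  visits_per_day: 20.0
  trials_per_visit: 20.0
  visit_duration_s: 300.0
  skill_ms: 250.0
  learning_rate: 4.0
  skill_max: 1500.0
  tau_ms: 50.0
  pull_peak_mean: 14.0
  pull_peak_sd: 1.0
  hold_level_mean: 12.0
  hold_level_sd: 0.8
  hold_noise_sd: 0.3
  release_slope_mean: -0.5
  release_slope_sd: 0.4
  rise_speed: 150.0
  quit_after_days: .inf
- animal_id: hd01
  preset: hd
  circadian_weights:
  - 6.0
  - 3.0
  - 3.0
  - 3.0
  - 3.0
  - 3.0
  - 3.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 6.0
  - 6.0
  - 6.0
  - 6.0
  - 6.0
  visits_per_day: 20.0
  trials_per_visit: 20.0
  visit_duration_s: 300.0
  skill_ms: 250.0
  learning_rate: 3.0
  skill_max: 1500.0
  tau_ms: 50.0
  pull_peak_mean: 18.5
  pull_peak_sd: 1.0
  hold_level_mean: 16.0
  hold_level_sd: 1.0
  hold_noise_sd: 0.5
  release_slope_mean: -5.0
  release_slope_sd: 1.5
  rise_speed: 150.0
  quit_after_days: .inf
- animal_id: perfect01
  preset: perfect
  circadian_weights:
  - 6.0
  - 3.0
  - 3.0
  - 3.0
  - 3.0
  - 3.0
  - 3.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 6.0
  - 6.0
  - 6.0
  - 6.0
  - 6.0
  visits_per_day: 20.0
  trials_per_visit: 20.0
  visit_duration_s: 300.0
  skill_ms: 1000000.0
  learning_rate: 0.0
  skill_max: 1500.0
  tau_ms: 50.0
  pull_peak_mean: 14.0
  pull_peak_sd: 0.0
  hold_level_mean: 12.0
  hold_level_sd: 0.0
  hold_noise_sd: 0.0
  release_slope_mean: 0.0
  release_slope_sd: 0.0
  rise_speed: 150.0
  quit_after_days: .inf
- animal_id: deadzone01
  preset: deadzone
  circadian_weights:
  - 6.0
  - 3.0
  - 3.0
  - 3.0
  - 3.0
  - 3.0
  - 3.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 6.0
  - 6.0
  - 6.0
  - 6.0
  - 6.0
  visits_per_day: 20.0
  trials_per_visit: 20.0
  visit_duration_s: 300.0
  skill_ms: 80.0
  learning_rate: 0.0
  skill_max: 1500.0
  tau_ms: 50.0
  pull_peak_mean: 14.0
  pull_peak_sd: 1.0
  hold_level_mean: 12.0
  hold_level_sd: 0.8
  hold_noise_sd: 0.3
  release_slope_mean: -0.5
  release_slope_sd: 0.4
  rise_speed: 150.0
  quit_after_days: .inf
- animal_id: nonacq01
  preset: nonacquirer
  circadian_weights:
  - 6.0
  - 3.0
  - 3.0
  - 3.0
  - 3.0
  - 3.0
  - 3.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 1.0
  - 6.0
  - 6.0
  - 6.0
  - 6.0
  - 6.0
  visits_per_day: 10.0
  trials_per_visit: 8.0
  visit_duration_s: 300.0
  skill_ms: 250.0
  learning_rate: 4.0
  skill_max: 1500.0
  tau_ms: 50.0
  pull_peak_mean: 14.0
  pull_peak_sd: 1.0
  hold_level_mean: 12.0
  hold_level_sd: 0.8
  hold_noise_sd: 0.3
  release_slope_mean: -0.5
  release_slope_sd: 0.4
  rise_speed: 150.0
  quit_after_days: 1.0
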
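# Generator contracts: forced noiseless forms, seed determinism, Poisson
# statistics, parameter recovery on noiseless data.

test_that("noiseless imaging trace is exactly linear during the stimulus", {
  plan <- trial_table(onset = 10, duration = 10, direction = 0,
                      condition = "a")
  cfg <- simulation_config(n_cells = 1, frame_rate = 10, trial_plan = plan,
                           noise_sd = 0, calcium_tau = 0,
                           drift_amplitude = 0, amplitude_sd = 0,
                           slope_by_condition = c(a = -0.05), seed = 3)
  ds <- simulate_imaging_dataset(cfg)
  tr <- ds$truth[1, ]
  g <- tuning_gain(0, tr$pref_direction, tr$tuning_width, tr$null_ratio)
  tm <- frame_times(ds$recording)
  stim <- which(tm >= 10 & tm < 20)
  y <- ds$recording$values[1, stim]
  # exact line: baseline + A*g*(1 - 0.05 * t)
  t_rel <- tm[stim] - 10
  expect_equal(y, tr$baseline + tr$amplitude * g * (1 - 0.05 * t_rel),
               tolerance = 1e-12)
  # and the fitted OLS slope is exactly A*g*(-0.05)
  expect_equal(ols <- adaptation_slope(y, 10, c(0, 10 - 1e-6)),
               -0.05 * tr$amplitude * g, tolerance = 1e-9)
})

test_that("identical configs and seeds give bit-identical datasets", {
  cfg <- quick_state_config(seed = 21, n_cells = 4, n_adapt = 3)
  d1 <- simulate_imaging_dataset(cfg)
  d2 <- simulate_imaging_dataset(cfg)
  expect_identical(d1$recording$values, d2$recording$values)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$behavior$speed, d2$behavior$speed)
  expect_identical(d1$behavior$lick_times, d2$behavior$lick_times)
  s1 <- simulate_spike_dataset(simulation_config(
    n_cells = 3, trial_plan = spike_trial_plan(2),
    slope_by_condition = c(adapted = 0, control = 0, led_adapted = 0),
    seed = 5))
  s2 <- simulate_spike_dataset(simulation_config(
    n_cells = 3, trial_plan = spike_trial_plan(2),
    slope_by_condition = c(adapted = 0, control = 0, led_adapted = 0),
    seed = 5))
  expect_identical(s1$spikes, s2$spikes)
})

test_that("generator validates its configuration", {
  plan <- trial_table(onset = 10, duration = 2)
  expect_error(simulation_config(n_cells = 2, trial_plan = plan,
                                 noise_sd = -0.1,
                                 slope_by_condition = c(default = 0)),
               "noise_sd")
  expect_error(simulation_config(n_cells = 2, trial_plan = plan[0, ],
                                 slope_by_condition = c(default = 0)),
               "non-empty")
  expect_error(simulation_config(n_cells = 2, trial_plan = plan,
                                 slope_by_condition = c(other = 0)),
               "lacks conditions")
})

test_that("trial count and trial times are conserved", {
  cfg <- quick_state_config(seed = 2, n_cells = 3, n_adapt = 5)
  ds <- simulate_imaging_dataset(cfg)
  expect_equal(nrow(ds$trials), nrow(cfg$trial_plan))
  t_max <- ncol(ds$recording$values) / ds$recording$frame_rate
  expect_true(all(ds$trials$onset + ds$trials$duration <= t_max))
})

test_that("downstream slope estimator recovers generative slopes on noiseless data", {
  cfg <- clean_config(seed = 8, n_cells = 6, n_adapt = 4)
  ds <- simulate_imaging_dataset(cfg)
  plan <- ds$trials
  adapt <- plan[plan$type == "adaptation" & plan$condition == "anesthetized", ]
  tens <- dff_prestim(ds$recording, adapt, baseline_s = 2)
  av <- average_trace(tens)
  for (i in seq_len(6)) {
    tr <- ds$truth[i, ]
    g <- tuning_gain(0, tr$pref_direction, tr$tuning_width, tr$null_ratio)
    est <- adaptation_slope(av$mean[i, ], av$time, c(1, 9.75))
    contrast_gain <- adapt$contrast[1] / 100
    expected <- tr$slope_anesthetized * tr$amplitude * g * contrast_gain /
      tr$baseline
    expect_equal(est, expected, tolerance = 1e-6)
  }
})

test_that("slope estimate converges to the generative value across replicates", {
  # Monte-Carlo: noisy replicate datasets; mean estimated slope within
  # 3 SEM of the noiseless expectation
  est <- expected <- numeric(30)
  for (r in 1:30) {
    plan <- trial_table(onset = seq(5, 5 + 19 * 14, by = 14), duration = 10,
                        direction = 0, condition = "a")
    cfg <- simulation_config(n_cells = 1, frame_rate = 10, trial_plan = plan,
                             noise_sd = 0.1, calcium_tau = 0,
                             drift_amplitude = 0, amplitude_sd = 0,
                             slope_by_condition = c(a = -0.05),
                             seed = 1000 + r)
    ds <- simulate_imaging_dataset(cfg)
    tens <- dff_prestim(ds$recording, ds$trials, baseline_s = 2)
    av <- average_trace(tens)
    est[r] <- adaptation_slope(av$mean[1, ], av$time, c(1, 9.75))
    tr <- ds$truth[1, ]
    g <- tuning_gain(0, tr$pref_direction, tr$tuning_width, tr$null_ratio)
    expected[r] <- -0.05 * tr$amplitude * g
  }
  err <- est - expected
  expect_lt(abs(mean(err)), 3 * sd(err) / sqrt(length(err)))
})

test_that("behavior generator honors saccade and anticipation switches", {
  plan <- relevance_trial_plan(n_sessions = 2, trials_per_session = 6,
                               rewarded = TRUE, seed = 12)
  cfg <- simulation_config(
    n_cells = 1, trial_plan = plan,
    slope_by_condition = c(s1 = 0, s2 = 0), seed = 4,
    behavior = behavior_config(saccade_rate_per_min = 0,
                               anticipation_gain = 0))
  beh <- simulate_behavior(cfg)
  expect_length(beh$truth$saccade_times, 0)
  # homogeneous Poisson licking: pre-reward rate matches baseline within
  # Poisson error (pooled over rewards)
  la <- lick_analysis(beh$lick_times, beh$reward_times,
                      sessions = plan$session[!is.na(plan$reward_time)])
  n <- nrow(la$per_reward)
  rate0 <- cfg$behavior$lick_rate_hz
  # corrected frequency: difference of two Poisson rate estimates, mean 0
  se <- sqrt(rate0 / 0.5 + rate0 / 2) / sqrt(n)
  expect_lt(abs(mean(la$per_reward$corrected)), 4 * se)
})

test_that("run bouts exceed the running threshold and rest does not", {
  cfg <- quick_state_config(seed = 31, n_cells = 1, n_adapt = 4)
  beh <- simulate_behavior(cfg)
  rb <- beh$truth$run_bouts
  expect_gt(nrow(rb), 0)
  in_run <- rep(FALSE, length(beh$time))
  for (k in seq_len(nrow(rb)))
    in_run[beh$time >= rb$start[k] & beh$time < rb$end[k]] <- TRUE
  expect_true(all(beh$speed[in_run] > 1))
  expect_true(mean(beh$speed[!in_run] > 1) < 0.05)
})

test_that("spike generator: silencing, PV drive, adaptation ratio, Poisson counts", {
  plan <- spike_trial_plan(reps_per_condition = 50, directions = c(0, 90))
  cfg <- simulation_config(
    n_cells = 2, trial_plan = plan, pv_frac = 0, tuning_width_range = c(30, 30),
    slope_by_condition = c(adapted = 0, control = 0, led_adapted = 0),
    seed = 17,
    spikes = spike_params(base_rate = 0, stim_drive = 30, adapt_floor = 0.4))
  ds <- simulate_spike_dataset(cfg)
  led_trials <- plan$trial[plan$condition == "led_adapted"]
  # complete silencing (silencing_factor 0, base rate 0): no spikes while the
  # LED is at full intensity
  led_spikes <- ds$spikes[ds$spikes$trial %in% led_trials &
                            ds$spikes$spike_time < 3.5, ]
  expect_equal(nrow(led_spikes), 0L)
  # adapted / control rate ratio at the probe matches the closed-form rates
  # within Poisson error, pooled over >= 200 trials
  probe <- post_led_probe(ds, preferred_only = TRUE)
  for (i in 1:2) {
    tr <- ds$truth[i, ]
    pref <- preferred_cardinal_and_exclusion(ds, tr$cell_id)$preferred_orientation
    j <- which(plan$condition == "adapted" & plan$direction %% 180 == pref)[1]
    t_grid <- seq(0, 7, by = 0.002); t_grid <- t_grid[-length(t_grid)]
    prof_a <- spike_rate_profile(tr, plan[j, ], cfg, t_grid)
    jc <- which(plan$condition == "control" & plan$direction %% 180 == pref)[1]
    prof_c <- spike_rate_profile(tr, plan[jc, ], cfg, t_grid)
    pw <- t_grid >= 4 & t_grid < 4 + 1 / 3
    exp_a <- mean(prof_a[pw]); exp_c <- mean(prof_c[pw])
    n_tr <- 50
    se_a <- sqrt(exp_a / (1 / 3) / n_tr); se_c <- sqrt(exp_c / (1 / 3) / n_tr)
    row <- probe[probe$cell_id == tr$cell_id, ]
    expect_lt(abs(row$adapted - exp_a), 4 * se_a)
    expect_lt(abs(row$control - exp_c), 4 * se_c)
  }
  # PV cells: higher rate with LED than without
  cfg_pv <- simulation_config(
    n_cells = 3, trial_plan = spike_trial_plan(10, directions = c(0, 90)),
    pv_frac = 1,
    slope_by_condition = c(adapted = 0, control = 0, led_adapted = 0),
    seed = 23)
  ds_pv <- simulate_spike_dataset(cfg_pv)
  for (cl in ds_pv$truth$cell_id) {
    led <- mean_rate(ds_pv, cl,
                     ds_pv$trials$trial[ds_pv$trials$condition == "led_adapted"],
                     c(0, 3.5))
    off <- mean_rate(ds_pv, cl,
                     ds_pv$trials$trial[ds_pv$trials$condition == "adapted"],
                     c(0, 3.5))
    expect_gt(led, off)
  }
})

test_that("spike counts follow the configured rate within 4-sigma Poisson bounds", {
  plan <- spike_trial_plan(reps_per_condition = 70, directions = c(0, 90))
  cfg <- simulation_config(
    n_cells = 1, trial_plan = plan,
    slope_by_condition = c(adapted = 0, control = 0, led_adapted = 0),
    seed = 29)
  ds <- simulate_spike_dataset(cfg)
  tr <- ds$truth[1, ]
  for (cond in c("adapted", "control")) {
    j_all <- which(plan$condition == cond & plan$direction == 0)
    t_grid <- seq(0, 7, by = 0.002); t_grid <- t_grid[-length(t_grid)]
    prof <- spike_rate_profile(tr, plan[j_all[1], ], cfg, t_grid)
    for (win in list(c(0, 3.5), c(3.5, 7))) {
      lambda <- sum(prof[t_grid >= win[1] & t_grid < win[2]]) * 0.002
      counts <- vapply(j_all, function(j) {
        st <- ds$spikes$spike_time[ds$spikes$trial == plan$trial[j]]
        sum(st >= win[1] & st < win[2])
      }, numeric(1))
      se <- sqrt(lambda / length(j_all))
      expect_lt(abs(mean(counts) - lambda), 4 * se)
    }
  }
})

test_that("spike generator rejects plans without the required conditions", {
  plan <- spike_trial_plan(2)
  plan2 <- plan[plan$condition != "led_adapted", ]
  cfg <- simulation_config(n_cells = 1, trial_plan = plan,
                           slope_by_condition = c(adapted = 0, control = 0,
                                                  led_adapted = 0),
                           seed = 1)
  cfg$trial_plan <- plan2
  expect_error(simulate_spike_dataset(cfg), "conditions")
  plan3 <- plan; plan3$led <- FALSE
  cfg$trial_plan <- plan3
  expect_error(simulate_spike_dataset(cfg), "LED metadata")
})
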
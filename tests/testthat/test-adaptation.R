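# Adaptation metrics: averaging, normalization, slopes, iso/cross,
# suppression, matched exclusion, session trajectories.

mk_tensor <- function(arr, fr = 10, t0_frames = 0, trials = NULL) {
  structure(arr, time = (seq_len(dim(arr)[3]) - 1 - t0_frames) / fr,
            frame_rate = fr, trials = trials, class = "trial_tensor")
}

test_that("average_trace: single trial, constants, loop oracle", {
  arr <- array(0, dim = c(1, 1, 10)); arr[1, 1, ] <- sin(1:10)
  av <- average_trace(mk_tensor(arr))
  expect_equal(av$mean[1, ], sin(1:10))
  expect_true(all(is.na(av$sem)))
  arr2 <- array(0, dim = c(1, 2, 5))
  arr2[1, 1, ] <- 1; arr2[1, 2, ] <- 3
  av2 <- average_trace(mk_tensor(arr2))
  expect_equal(unique(av2$mean[1, ]), 2)
  set.seed(8)
  arr3 <- array(rnorm(3 * 7 * 12), dim = c(3, 7, 12))
  av3 <- average_trace(mk_tensor(arr3), trials = c(2, 4, 6))
  for (i in 1:3) for (k in 1:12) {
    vals <- sapply(c(2, 4, 6), function(j) arr3[i, j, k])
    expect_equal(av3$mean[i, k], mean(vals))
    expect_equal(av3$sem[i, k], sd(vals) / sqrt(3))
  }
  # population mode: trials within cell first, then across cells
  avp <- average_trace(mk_tensor(arr3), population = TRUE)
  cell_means <- apply(arr3, c(1, 3), mean)
  expect_equal(avp$mean, colMeans(cell_means))
  expect_equal(avp$sem, apply(cell_means, 2, sd) / sqrt(3))
  expect_error(average_trace(mk_tensor(arr3), trials = integer()), "empty")
})

test_that("normalize_trace: peak scaling and the slope identity", {
  tm <- seq(0, 10, by = 0.1)
  tr <- 0.8 * exp(-((tm - 2)^2))
  out <- normalize_trace(tr, tm, c(0, 10))
  expect_equal(max(out$trace), 1)
  expect_equal(out$peak, max(tr))
  expect_equal(normalize_trace(out$trace, tm, c(0, 10))$trace, out$trace)
  # slope of a normalized trace equals raw slope / peak (exact identity)
  lin <- 0.9 - 0.05 * tm
  nl <- normalize_trace(lin, tm, c(0, 10))
  expect_equal(adaptation_slope(nl$trace, tm, c(1, 9)),
               adaptation_slope(lin, tm, c(1, 9)) / nl$peak)
  expect_error(normalize_trace(-lin, tm, c(0, 10)), "peak")
})

test_that("adaptation_slope: exact lines and the OLS oracle", {
  tm <- seq(0, 10, by = 0.05)
  expect_equal(adaptation_slope(rep(2, length(tm)), tm, c(1, 9.75)), 0)
  y <- 0.9 - 0.1 * tm
  expect_equal(adaptation_slope(y, tm, c(1, 9.75)), -0.1, tolerance = 1e-12)
  # frame-rate form: scalar time argument
  expect_equal(adaptation_slope(y, 20, c(1, 9.75)), -0.1, tolerance = 1e-12)
  set.seed(12)
  for (k in 1:50) {
    yy <- rnorm(length(tm))
    win <- sort(runif(2, 0, 10)); if (diff(win) < 1) win <- c(0, 10)
    idx <- which(tm >= win[1] & tm < win[2])
    expect_equal(adaptation_slope(yy, tm, win),
                 unname(coef(lm(yy[idx] ~ tm[idx]))[2]))
  }
  expect_error(adaptation_slope(y, tm, c(1, 1.05)), "3 samples")
})

test_that("slopes are invariant to the sampling rate of the same signal", {
  shape <- function(t) 0.5 - 0.04 * t + 0.02 * sin(2 * pi * t / 7)
  for (fr in c(5, 10, 40)) {
    tm <- seq(0, 12, by = 1 / fr)
    s <- adaptation_slope(shape(tm), tm, c(1, 9.75))
    expect_equal(s, adaptation_slope(shape(seq(0, 12, by = 0.1)),
                                     seq(0, 12, by = 0.1), c(1, 9.75)),
                 tolerance = 5e-3)
  }
})

test_that("mean_response: constants, line midpoint, loop oracle", {
  tm <- seq(0, 10, by = 0.1)
  expect_equal(mean_response(rep(0.2, length(tm)), tm, c(1, 10)), 0.2)
  # line from 0.3 to 0.1 over the window averages to 0.2
  win <- c(2, 8)
  y <- 0.3 - (0.3 - 0.1) * (tm - 2) / 6
  idx <- which(tm >= 2 & tm < 8)
  expect_equal(mean_response(y, tm, win), mean(y[idx]))
  expect_equal(mean_response(y, tm, win), 0.2, tolerance = 0.01)
  set.seed(4)
  yy <- rnorm(length(tm))
  expect_equal(mean_response(yy, tm, c(1.5, 7.5)),
               mean(yy[tm >= 1.5 & tm < 7.5]))
})

test_that("iso/cross adaptation: window arithmetic and generative contracts", {
  fr <- 10
  plan <- iso_cross_trial_plan(reps = 8)
  # frame indices for 11-12 s are exactly [11, 12) at the frame rate
  cfg0 <- simulation_config(n_cells = 30, frame_rate = fr, trial_plan = plan,
                            noise_sd = 0.05, calcium_tau = 0,
                            drift_amplitude = 0,
                            slope_by_condition = c(adapt_test = -0.03),
                            iso_adapt_factor = 1, seed = 61)
  ds0 <- simulate_imaging_dataset(cfg0)
  tens <- dff_prestim(ds0$recording, ds0$trials, baseline_s = 2)
  tm <- tensor_time(tens)
  idx <- which(tm >= 11 & tm < 12)
  expect_equal(length(idx), fr)
  expect_equal(min(tm[idx]), 11)
  expect_lt(max(tm[idx]), 12)
  # no orientation-specific adaptation -> paired difference centered on zero
  ic0 <- iso_cross_adaptation(tens)
  expect_lt(abs(mean(ic0$difference)), 3 * sd(ic0$difference) /
              sqrt(nrow(ic0)))
  # extra iso-specific adaptation factor 0.8 -> iso < cross for most cells
  cfg1 <- cfg0; cfg1$iso_adapt_factor <- 0.8
  ds1 <- simulate_imaging_dataset(cfg1)
  tens1 <- dff_prestim(ds1$recording, ds1$trials, baseline_s = 2)
  ic1 <- iso_cross_adaptation(tens1)
  # restrict to cells actually driven at the iso orientation
  driven <- ic1$cell %in% which(
    tuning_gain(0, ds1$truth$pref_direction, ds1$truth$tuning_width,
                ds1$truth$null_ratio) > 0.3)
  expect_gt(mean(ic1$difference[driven] < 0), 0.8)
})

test_that("suppressed-cell statistics match sign counting", {
  set.seed(19)
  resp <- matrix(abs(rnorm(20 * 6)), 20, 6)
  arr <- array(rnorm(20 * 6 * 30), dim = c(20, 6, 30))
  tens <- mk_tensor(arr)
  s <- suppressed_cell_stats(resp, tens, late_window = c(1, 2))
  expect_equal(s$fraction_suppressed, 0)
  resp2 <- resp; resp2[1:10, ] <- -resp2[1:10, ]
  s2 <- suppressed_cell_stats(resp2, tens, late_window = c(1, 2))
  expect_equal(s2$fraction_suppressed, 0.5)
  expect_equal(which(s2$suppressed), 1:10)
  # counting oracle on random signs
  resp3 <- matrix(rnorm(20 * 6), 20, 6)
  s3 <- suppressed_cell_stats(resp3, tens, late_window = c(1, 2))
  expect_equal(s3$fraction_suppressed, mean(rowMeans(resp3) < 0))
  late_idx <- which(attr(tens, "time") >= 1 & attr(tens, "time") < 2)
  expect_equal(s3$late_decrease,
               mean(apply(arr[s3$suppressed, , late_idx], 1, mean)))
})

test_that("matched exclusion removes exactly the largest deviations", {
  set.seed(23)
  v <- rnorm(100)
  me <- matched_exclusion(v, 0, frac = 0.10)
  expect_length(me$retained, 90)
  expect_length(me$excluded, 10)
  expect_equal(matched_exclusion(v, 0, frac = 0)$retained, seq_along(v))
  # hand-built 10-cell set: exactly the largest-deviation cell removed
  resp <- c(0.1, 0.2, 0.15, 0.9, 0.22, 0.18, 0.25, 0.12, 0.3, 0.21)
  me2 <- matched_exclusion(resp, 0.2, frac = 0.10,
                           ids = paste0("c", 1:10))
  expect_equal(me2$excluded, "c4")
  expect_setequal(me2$retained, paste0("c", c(1:3, 5:10)))
  # ceiling rule and retention property on random sizes
  for (n in c(7, 10, 33, 101)) {
    x <- rnorm(n)
    m <- matched_exclusion(x, mean(x), frac = 0.1)
    expect_length(m$excluded, ceiling(0.1 * n))
    expect_length(m$retained, n - ceiling(0.1 * n))
  }
  expect_error(matched_exclusion(v, 0, frac = 1), "frac")
})

test_that("session quarters partition trials with remainders to the front", {
  expect_equal(quarter_labels(120), rep(1:4, each = 30))
  q <- quarter_labels(10)
  expect_equal(as.vector(table(q)), c(3, 3, 2, 2))
  expect_equal(q, sort(q))  # contiguous
  for (n in c(4, 5, 121, 163))
    expect_equal(sum(table(quarter_labels(n))), n)
})

test_that("exponential fit: noiseless recovery and unidentifiable constants", {
  t <- 1:20
  y <- 0.3 + 0.5 * exp(-t / 4)
  f <- fit_exponential(y, t)
  expect_lt(abs(f$a - 0.3) / 0.3, 1e-4)
  expect_lt(abs(f$b - 0.5) / 0.5, 1e-4)
  expect_lt(abs(f$tau - 4) / 4, 1e-4)
  fc <- fit_exponential(rep(0.7, 12))
  expect_lt(abs(fc$b), 1e-6)
  expect_equal(fc$a + fc$b * mean(exp(-(1:12) / fc$tau)), 0.7,
               tolerance = 1e-6)
  expect_false(fc$identifiable)
})

test_that("session trajectory bins and refits the generative decay", {
  set.seed(31)
  sessions <- rep(paste0("s", 1:5), each = 24)
  bin_truth <- 0.1 + 0.4 * exp(-(1:20) / 3)
  values <- rep(bin_truth, each = 6) + rnorm(120, sd = 0.005)
  st <- session_trajectory(values, sessions)
  expect_equal(nrow(st$bins), 20)
  expect_equal(unique(st$bins$n_trials), 6)
  expect_lt(abs(st$fit$tau - 3), 0.5)
  expect_lt(abs(st$fit$a - 0.1), 0.02)
  # quarter means match a direct computation
  v1 <- values[sessions == "s1"]
  expect_equal(st$bins$value[1], mean(v1[1:6]))
  expect_equal(st$bins$value[4], mean(v1[19:24]))
})
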
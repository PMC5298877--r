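# Tuning fits, orientation classes, responsiveness rules.

dirs8 <- seq(0, 315, by = 45)

test_that("trial responses match explicit index arithmetic", {
  set.seed(5)
  fr <- 10
  vals <- matrix(runif(2 * 300, 1, 2), 2, 300)
  rec <- toy_recording(vals, fr)
  tt <- trial_table(onset = c(5, 15), duration = 4)
  tens <- cut_trials(rec, tt, pre_s = 2)
  resp <- trial_responses(tens, c(0, 4), baseline_window = c(-2, 0))
  for (cell in 1:2) for (tr in 1:2) {
    onset_frame <- tt$onset[tr] * fr + 1
    r <- mean(vals[cell, onset_frame:(onset_frame + 4 * fr - 1)])
    b <- mean(vals[cell, (onset_frame - 2 * fr):(onset_frame - 1)])
    expect_equal(resp[cell, tr], r - b)
  }
  # constant-zero tensor -> all responses zero
  z <- cut_trials(toy_recording(matrix(0, 1, 300), fr), tt, pre_s = 2)
  expect_equal(unique(as.vector(trial_responses(z, c(0, 4)))), 0)
})

test_that("double-Gaussian fit recovers noiseless parameters and is equivariant", {
  y <- 0.1 + 0.5 * tuning_gain(dirs8, 90, 30, 0.4)
  f <- fit_direction_tuning(y, dirs8)
  expect_lt(abs(f$pref_direction - 90), 0.5)
  expect_lt(abs(f$width_sigma - 30), 0.5)
  expect_equal(f$amp_pref, 0.5, tolerance = 1e-3)
  expect_equal(f$amp_null, 0.2, tolerance = 1e-3)
  # rotating the stimulus labels by +45 shifts the peak by +45 (mod 360)
  f45 <- fit_direction_tuning(y, dirs8 + 45)
  expect_lt(abs(((f45$pref_direction - f$pref_direction - 45 + 180) %% 360) - 180),
            0.5)
  # degenerate flat curve
  ff <- fit_direction_tuning(rep(0.3, 8), dirs8)
  expect_true(ff$flat)
  expect_identical(ff$amp_pref, 0)
  expect_true(is.na(ff$pref_direction))
})

test_that("fit RSS never exceeds the flat-model RSS", {
  set.seed(9)
  for (k in 1:40) {
    y <- rnorm(8, sd = runif(1, 0.01, 1))
    f <- fit_direction_tuning(y, dirs8)
    expect_lte(f$rss, sum((y - mean(y))^2) + 1e-10)
  }
})

test_that("noisy fits match the 1-degree grid-search oracle's accuracy", {
  # 10% amplitude noise; median |pref error| compared against an exhaustive
  # grid-search oracle on the same curves
  set.seed(14)
  n_rep <- 40
  err_fit <- err_oracle <- numeric(n_rep)
  sig_grid <- seq(15, 60, by = 5)
  for (r in 1:n_rep) {
    truth_pref <- runif(1, 0, 360)
    y0 <- 0.05 + 0.5 * tuning_gain(dirs8, truth_pref, 30, 0.3)
    y <- y0 + rnorm(8, sd = 0.05)
    f <- fit_direction_tuning(y, dirs8)
    err_fit[r] <- min(abs(f$pref_direction - truth_pref) %% 360,
                      360 - abs(f$pref_direction - truth_pref) %% 360)
    best <- Inf; best_th <- NA
    for (th in 0:359) for (sg in sig_grid) {
      b1 <- tuning_gain(dirs8, th, sg, 0)
      b2 <- tuning_gain(dirs8, th + 180, sg, 0)
      rss <- sum(lm.fit(cbind(1, b1, b2), y)$residuals^2)
      if (rss < best) { best <- rss; best_th <- th }
    }
    e <- abs(best_th - truth_pref) %% 360
    err_oracle[r] <- min(e, 360 - e)
    # allow for the pref/null ambiguity when the noisy null lobe dominates
    err_oracle[r] <- min(err_oracle[r], abs(180 - err_oracle[r]))
    err_fit[r] <- min(err_fit[r], abs(180 - err_fit[r]))
  }
  expect_lte(median(err_fit), median(err_oracle) + 1)
  expect_lt(median(err_fit), 5)
})

test_that("iso/cross assignment and the 45-degree tie rule", {
  mk_fit <- function(pref) structure(list(pref_direction = pref, flat = FALSE),
                                     class = "tuning_fit")
  expect_equal(assign_adaptation_class(mk_fit(10), 0), "iso")
  expect_equal(assign_adaptation_class(mk_fit(80), 0), "cross")
  expect_equal(assign_adaptation_class(mk_fit(44), 0), "iso")
  expect_equal(assign_adaptation_class(mk_fit(45), 0), "iso")  # tie -> iso
  expect_equal(assign_adaptation_class(mk_fit(46), 0), "cross")
  expect_true(is.na(assign_adaptation_class(
    structure(list(pref_direction = NA_real_, flat = TRUE),
              class = "tuning_fit"), 0)))
})

test_that("horizontal classification is inclusive at 45 degrees", {
  mk_fit <- function(pref) structure(list(pref_direction = pref, flat = FALSE),
                                     class = "tuning_fit")
  expect_true(classify_horizontal_tuned(mk_fit(30)))
  expect_false(classify_horizontal_tuned(mk_fit(60)))
  expect_true(classify_horizontal_tuned(mk_fit(45)))
  expect_true(classify_horizontal_tuned(mk_fit(180 + 30)))
  expect_false(classify_horizontal_tuned(
    structure(list(pref_direction = NA_real_, flat = TRUE),
              class = "tuning_fit")))
})

# small helper: tensor with given per-trial response/baseline structure
noise_tensor <- function(n_cells, n_trials, n_pre, n_post, sd = 1,
                         stim_add = 0) {
  arr <- array(rnorm(n_cells * n_trials * (n_pre + n_post), sd = sd),
               dim = c(n_cells, n_trials, n_pre + n_post))
  arr[, , (n_pre + 1):(n_pre + n_post)] <-
    arr[, , (n_pre + 1):(n_pre + n_post)] + stim_add
  structure(arr, time = (seq_len(n_pre + n_post) - 1 - n_pre) / 10,
            frame_rate = 10, class = "trial_tensor")
}

test_that("trial-wise responsiveness: trivial, boundary, null calibration", {
  set.seed(2)
  z0 <- noise_tensor(5, 10, 20, 20, sd = 1e-6)
  expect_false(any(classify_responsive_trialwise(z0, c(-2, 0), c(0, 2))$responsive))
  # strong responders are responsive
  zr <- noise_tensor(5, 10, 20, 20, sd = 0.1, stim_add = 2)
  expect_true(all(classify_responsive_trialwise(zr, c(-2, 0), c(0, 2))$responsive))
  # responsiveness is invariant to multiplicative rescaling
  zr2 <- zr * 17
  attributes(zr2) <- attributes(zr)
  expect_equal(classify_responsive_trialwise(zr2, c(-2, 0), c(0, 2))$z,
               classify_responsive_trialwise(zr, c(-2, 0), c(0, 2))$z)
  # exactly half the trials above threshold -> responsive (inclusive)
  half <- noise_tensor(1, 10, 20, 20, sd = 0.05)
  half[1, 1:5, 21:40] <- half[1, 1:5, 21:40] + 5
  res <- classify_responsive_trialwise(half, c(-2, 0), c(0, 2))
  expect_equal(res$frac, 0.5)
  expect_true(res$responsive)
  # null calibration: single-frame response window, i.i.d. noise; the
  # per-trial exceedance probability approximates the nominal 1% level
  set.seed(33)
  big <- noise_tensor(150, 30, 40, 1, sd = 1)
  resn <- classify_responsive_trialwise(big, c(-4, 0), c(0, 0.1))
  p_hat <- mean(resn$z > 2.58)
  expect_false(any(resn$responsive))
  expect_lt(abs(p_hat - 0.01), 0.006)
})

test_that("session-wise responsiveness: suppression, null, boundary", {
  set.seed(6)
  n_trials <- 40
  sessions <- rep(c("s1", "s2", "s3", "s4"), each = 10)
  base <- matrix(rnorm(3 * n_trials, sd = 0.1), 3, n_trials)
  resp <- base + matrix(rnorm(3 * n_trials, sd = 0.1), 3, n_trials)
  resp[1, ] <- resp[1, ] - 1    # strongly suppressed cell
  resp[2, ] <- resp[2, ] + 1    # strongly driven cell
  res <- classify_responsive_sessionwise(resp, base, sessions)
  expect_true(res$responsive[1])  # suppressed cells count (two-sided)
  expect_true(res$responsive[2])
  expect_false(res$responsive[3]) # zero-effect cell
  # effect in exactly half the sessions -> responsive (inclusive)
  resp2 <- base
  resp2[3, sessions %in% c("s1", "s2")] <-
    resp2[3, sessions %in% c("s1", "s2")] + 1
  res2 <- classify_responsive_sessionwise(resp2, base, sessions)
  expect_equal(unname(res2$frac[3]), 0.5)
  expect_true(res2$responsive[3])
  # sessions with too few trials are dropped
  sess3 <- c(rep("tiny", 2), rep("s1", 19), rep("s2", 19))
  res3 <- classify_responsive_sessionwise(resp, base, sess3)
  expect_equal(colnames(res3$z), c("s1", "s2"))
})

test_that("responsiveness sensitivity is monotone in generative amplitude", {
  set.seed(44)
  amps <- c(0.05, 0.2, 0.8)
  frac <- vapply(amps, function(a) {
    tens <- noise_tensor(60, 12, 20, 20, sd = 0.3, stim_add = a)
    mean(classify_responsive_trialwise(tens, c(-2, 0), c(0, 2))$responsive)
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
  expect_gt(frac[3], frac[1])
})
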
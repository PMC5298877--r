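# Monte-Carlo validation studies: slope-recovery bias, tuning-fit accuracy,
# and the power / false-positive rate of the state experiment.

#' Slope-recovery study
#'
#' Generates a synthetic population (sustained gratings at one direction),
#' estimates every cell's adaptation slope through the full preprocessing
#' chain, and compares against the same estimator run on the noise-free twin
#' of the dataset (same seed, so identical cells and drift phases): by
#' linearity of the pipeline the noise-free estimate is the expectation of
#' the noisy one, so `bias = mean(estimate - expectation)` measures estimator
#' bias directly.
#'
#' @param n_cells population size.
#' @param n_trials sustained-grating trials.
#' @param slope generative adaptation slope, (fraction of response)/s.
#' @param noise_sd frame-wise noise SD.
#' @param seed seed.
#' @param slope_window slope-fit window, s.
#' @return list: `estimate` and `expectation` (per cell), `bias`, `mc_sem`
#'   (SD of the per-cell error / sqrt(n)), `recovered_slope` (mean estimated
#'   slope rescaled to the generative fraction-per-second scale),
#'   `generative_slope`.
#' @export
slope_recovery_study <- function(n_cells = 200, n_trials = 40,
                                 slope = -0.05, noise_sd = 0.1, seed = 1,
                                 slope_window = c(1, 9.75)) {
  plan <- trial_table(onset = 5 + (seq_len(n_trials) - 1) * 14,
                      duration = 10, direction = 0, condition = "a")
  mk <- function(nsd) simulation_config(
    n_cells = n_cells, frame_rate = 10, trial_plan = plan, noise_sd = nsd,
    slope_by_condition = c(a = slope), seed = seed)
  est_of <- function(ds) {
    tens <- dff_prestim(ds$recording, ds$trials, baseline_s = 2)
    av <- average_trace(tens)
    apply(av$mean, 1L, adaptation_slope, time = av$time,
          window = slope_window)
  }
  ds <- simulate_imaging_dataset(mk(noise_sd))
  ds0 <- simulate_imaging_dataset(mk(0))
  est <- est_of(ds)
  expectation <- est_of(ds0)
  err <- est - expectation
  tr <- ds$truth
  scale <- tr$amplitude *
    tuning_gain(0, tr$pref_direction, tr$tuning_width, tr$null_ratio) /
    tr$baseline
  list(estimate = est, expectation = expectation,
       bias = mean(err), mc_sem = stats::sd(err) / sqrt(length(err)),
       recovered_slope = mean(est / scale),
       generative_slope = slope)
}

#' Tuning-fit accuracy study
#'
#' Fits the constrained double-Gaussian to noisy tuning curves (noise SD a
#' fraction of the response amplitude) and reports the median absolute
#' preferred-direction error, folding the 180-degree pref/null ambiguity.
#'
#' @param n_cells number of simulated curves.
#' @param noise_frac noise SD as a fraction of the peak amplitude.
#' @param directions measured directions, degrees.
#' @param sigma generative tuning width, degrees.
#' @param seed seed.
#' @return list: `errors` (degrees, per curve), `median_error`.
#' @export
tuning_error_study <- function(n_cells = 200, noise_frac = 0.10,
                               directions = seq(0, 315, by = 45),
                               sigma = 30, seed = 1) {
  with_seed(seed, {
    errors <- vapply(seq_len(n_cells), function(i) {
      pref <- stats::runif(1, 0, 360)
      amp <- 0.5
      y <- 0.05 + amp * tuning_gain(directions, pref, sigma, 0.3) +
        stats::rnorm(length(directions), sd = noise_frac * amp)
      f <- fit_direction_tuning(y, directions)
      if (f$flat) return(90)
      e <- abs(f$pref_direction - pref) %% 360
      e <- min(e, 360 - e)
      min(e, abs(180 - e))
    }, numeric(1))
    list(errors = errors, median_error = stats::median(errors))
  })
}

#' Power / false-positive study of the state experiment
#'
#' Repeatedly generates state-experiment datasets and runs
#' [run_state_experiment()], recording whether the paired anesthetized-vs-
#' awake signed-rank test rejects at `alpha`. With distinct generative
#' slopes this estimates power; with equal slopes it estimates the
#' false-positive rate.
#'
#' @param n_replicates Monte-Carlo replicates.
#' @param n_cells cells per replicate dataset.
#' @param slopes named generative slopes, `c(awake = ..., anesthetized =
#'   ...)`.
#' @param n_adapt sustained-grating trials per state.
#' @param alpha rejection level.
#' @param seed base seed (replicate r uses `seed + r`).
#' @return list: `p_values`, `rejection_rate`, `n_tuned` (per replicate).
#' @export
state_power_study <- function(n_replicates = 40, n_cells = 150,
                              slopes = c(awake = 0.01, anesthetized = -0.05),
                              n_adapt = 10, alpha = 0.05, seed = 1) {
  p <- n_tuned <- numeric(n_replicates)
  plan <- state_trial_plan(n_adapt_per_state = n_adapt)
  for (r in seq_len(n_replicates)) {
    cfg <- simulation_config(n_cells = n_cells, trial_plan = plan,
                             slope_by_condition = slopes,
                             seed = seed + r)
    rep <- run_state_experiment(simulate_imaging_dataset(cfg))
    paired <- rep$comparisons[rep$comparisons$test == "signed_rank", ]
    p[r] <- paired$p_value[1]
    n_tuned[r] <- nrow(rep$cells)
  }
  list(p_values = p, rejection_rate = mean(!is.na(p) & p < alpha),
       n_tuned = n_tuned)
}
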
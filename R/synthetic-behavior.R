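# Synthetic behavioral time series: locomotion bouts, pupil traces with
# saccadic steps, heading, and (optionally anticipatory) licking.

#' Behavior-generator parameters
#'
#' Defaults emulate head-fixed mouse behavior on a spherical treadmill:
#' alternating rest/run bouts with run speeds well above the 1 cm/s
#' classification threshold, pupil position as slow drift plus discrete
#' saccadic steps, licks as an inhomogeneous Poisson process with an optional
#' linear rate ramp before reward.
#'
#' @param sample_rate behavior sampling rate, Hz; `NULL` uses the recording
#'   frame rate.
#' @param rest_bout_mean_s,run_bout_mean_s mean bout durations (exponential).
#' @param run_speed_mean,run_speed_sd running speed distribution, cm/s.
#' @param rest_speed_sd residual speed jitter at rest, cm/s.
#' @param heading_sd baseline SD of heading around the goal direction,
#'   degrees.
#' @param heading_learn_tau learning time constant (sessions) by which the
#'   heading SD shrinks; `Inf` disables learning.
#' @param saccade_rate_per_min mean saccade rate; 0 disables saccades.
#' @param saccade_amp saccadic step amplitude (pupil position units).
#' @param pupil_noise_sd frame-wise pupil position noise.
#' @param pupil_drift_amp,pupil_drift_period_s slow sinusoidal pupil drift.
#' @param lick_rate_hz baseline lick rate.
#' @param anticipation_gain added lick rate (Hz) reached at reward time when
#'   the animal anticipates; 0 disables anticipation.
#' @param anticipation_window_s length of the linear pre-reward ramp, s.
#' @param anticipation_from_session first session (1-based) in which the
#'   anticipatory ramp is present.
#' @return list of class `"behavior_config"`.
#' @export
behavior_config <- function(sample_rate = NULL,
                            rest_bout_mean_s = 20, run_bout_mean_s = 10,
                            run_speed_mean = 6, run_speed_sd = 2,
                            rest_speed_sd = 0.1,
                            heading_sd = 60, heading_learn_tau = 1.5,
                            saccade_rate_per_min = 3, saccade_amp = 5,
                            pupil_noise_sd = 0.2,
                            pupil_drift_amp = 1, pupil_drift_period_s = 60,
                            lick_rate_hz = 0.5,
                            anticipation_gain = 0,
                            anticipation_window_s = 2,
                            anticipation_from_session = 3) {
  structure(as.list(environment()), class = "behavior_config")
}

#' Session index of each time point, from the trial plan
#' @noRd
session_of_time <- function(time, plan) {
  sess <- unique(plan$session)
  starts <- vapply(sess, function(s) min(plan$onset[plan$session == s]),
                   numeric(1))
  o <- order(starts)
  sess <- sess[o]; starts <- starts[o]
  idx <- findInterval(time, starts)
  idx[idx < 1L] <- 1L
  list(index = idx, levels = sess)
}

#' Simulate a behavioral trace
#'
#' Generates running speed as alternating rest/run bouts, heading as a
#' mean-reverting random walk around the goal direction (with SD shrinking
#' over sessions to emulate learning), pupil position as slow drift plus
#' discrete saccadic steps at Poisson times, and licks as an inhomogeneous
#' Poisson process with an optional linear pre-reward ramp from
#' `anticipation_from_session` onward. Ground-truth saccade times and run
#' bouts are returned for recovery tests.
#'
#' @param config a [simulation_config()]; behavioral parameters are taken
#'   from `config$behavior` and reward times from the trial plan.
#' @return list of class `"behavior_trace"` with elements `time`, `speed`,
#'   `heading`, `pupil_x`, `pupil_y`, `lick_times`, `reward_times`,
#'   `sample_rate`, `session` (per-sample session label), and `truth`
#'   (list with `saccade_times`, `run_bouts`).
#' @export
simulate_behavior <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  bc <- config$behavior
  plan <- config$trial_plan
  rate <- if (is.null(bc$sample_rate)) config$frame_rate else bc$sample_rate
  t_end <- max(plan$onset + plan$duration) + 10
  time <- seq(0, t_end, by = 1 / rate)
  nt <- length(time)
  with_seed(config$seed + 1L, {
    ## --- running: alternating rest/run bouts -----------------------------
    bouts <- list(); t_cur <- 0; running <- FALSE
    while (t_cur < t_end) {
      dur <- stats::rexp(1, 1 / (if (running) bc$run_bout_mean_s
                                 else bc$rest_bout_mean_s))
      bouts[[length(bouts) + 1L]] <-
        data.frame(start = t_cur, end = min(t_cur + dur, t_end),
                   running = running)
      t_cur <- t_cur + dur
      running <- !running
    }
    bouts <- do.call(rbind, bouts)
    speed <- abs(stats::rnorm(nt, 0, bc$rest_speed_sd))
    run_bouts <- bouts[bouts$running, , drop = FALSE]
    for (k in seq_len(nrow(run_bouts))) {
      idx <- which(time >= run_bouts$start[k] & time < run_bouts$end[k])
      if (length(idx))
        speed[idx] <- pmax(stats::rnorm(length(idx), bc$run_speed_mean,
                                        bc$run_speed_sd), 1.5)
    }

    ## --- heading: mean-reverting walk, SD shrinking over sessions --------
    sess <- session_of_time(time, plan)
    sess_num <- sess$index
    sd_per_session <- bc$heading_sd *
      exp(-(seq_along(sess$levels) - 1) / bc$heading_learn_tau)
    target_sd <- sd_per_session[sess_num]
    phi <- 0.98
    h <- numeric(nt)
    innov <- stats::rnorm(nt)
    for (i in 2:nt)
      h[i] <- phi * h[i - 1] +
        innov[i] * target_sd[i] * sqrt(1 - phi^2)
    heading <- ((h + 180) %% 360) - 180

    ## --- pupil: drift + noise + saccadic steps ---------------------------
    drift_x <- bc$pupil_drift_amp * sin(2 * pi * time / bc$pupil_drift_period_s)
    drift_y <- bc$pupil_drift_amp * cos(2 * pi * time / bc$pupil_drift_period_s)
    n_sacc <- stats::rpois(1, bc$saccade_rate_per_min / 60 * t_end)
    saccade_times <- sort(stats::runif(n_sacc, 1, t_end - 1))
    step_x <- numeric(nt); step_y <- numeric(nt)
    if (n_sacc > 0) {
      ang <- stats::runif(n_sacc, 0, 2 * pi)
      for (k in seq_len(n_sacc)) {
        idx <- which(time >= saccade_times[k])
        step_x[idx] <- step_x[idx] + bc$saccade_amp * cos(ang[k])
        step_y[idx] <- step_y[idx] + bc$saccade_amp * sin(ang[k])
      }
    }
    pupil_x <- drift_x + step_x + stats::rnorm(nt, 0, bc$pupil_noise_sd)
    pupil_y <- drift_y + step_y + stats::rnorm(nt, 0, bc$pupil_noise_sd)

    ## --- licking: inhomogeneous Poisson via per-sample thinning ----------
    reward_times <- plan$reward_time[!is.na(plan$reward_time)]
    reward_session <- plan$session[!is.na(plan$reward_time)]
    sess_rank <- match(reward_session, sess$levels)
    lick_rate <- rep(bc$lick_rate_hz, nt)
    if (bc$anticipation_gain > 0 && length(reward_times)) {
      for (k in seq_along(reward_times)) {
        if (sess_rank[k] < bc$anticipation_from_session) next
        r <- reward_times[k]
        idx <- which(time >= r - bc$anticipation_window_s & time < r)
        if (length(idx))
          lick_rate[idx] <- lick_rate[idx] + bc$anticipation_gain *
            (time[idx] - (r - bc$anticipation_window_s)) /
            bc$anticipation_window_s
      }
    }
    lick_draw <- stats::rpois(nt, lick_rate / rate)
    lick_times <- time[lick_draw > 0]

    structure(list(time = time, speed = speed, heading = heading,
                   pupil_x = pupil_x, pupil_y = pupil_y,
                   lick_times = lick_times, reward_times = reward_times,
                   sample_rate = rate,
                   session = sess$levels[sess_num],
                   truth = list(saccade_times = saccade_times,
                                run_bouts = run_bouts)),
              class = "behavior_trace")
  })
}

#' @export
print.behavior_trace <- function(x, ...) {
  cat(sprintf("<behavior_trace> %.0f s @ %g Hz, %d saccades, %d licks, %d rewards\n",
              max(x$time), x$sample_rate, length(x$truth$saccade_times),
              length(x$lick_times), length(x$reward_times)))
  invisible(x)
}
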
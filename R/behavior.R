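# Behavioral classification: locomotion, saccades, navigation performance,
# licking.

#' Classify a trial as running or resting
#'
#' A trial counts as running iff the running speed exceeds `threshold` for at
#' least `min_frac` (inclusive) of the in-window samples.
#'
#' @param behavior a `"behavior_trace"` (or list with `time` and `speed`).
#' @param window trial window `c(start, end)` on the behavior time base, s.
#' @param threshold speed threshold, cm/s.
#' @param min_frac minimum fraction of supra-threshold samples.
#' @return logical flag; errors if the window has no behavior coverage.
#' @export
classify_running <- function(behavior, window, threshold = 1,
                             min_frac = 0.5) {
  idx <- frames_in_window(behavior$time, window)
  if (!length(idx)) stop("behavior trace does not cover the trial window")
  mean(behavior$speed[idx] > threshold) >= min_frac
}

#' Detect saccades from a pupil-position trace
#'
#' Median-filters each pupil coordinate, computes the frame-to-frame
#' displacement magnitude, and marks saccades where the displacement exceeds
#' an adaptive threshold of `k_mad` times the MAD of all displacements.
#' Events closer than `refractory_s` are merged into one (keeping the first
#' sample). A flat trace yields no events.
#'
#' @param pupil_x,pupil_y pupil position coordinates.
#' @param time sample times, s (sampling >= 10 Hz).
#' @param median_filter_width median filter width in samples (odd; even
#'   values are incremented).
#' @param k_mad threshold in MAD units.
#' @param refractory_s merge gap, s.
#' @return numeric vector of saccade times (time of the first post-step
#'   sample).
#' @export
detect_saccades <- function(pupil_x, pupil_y, time,
                            median_filter_width = 5, k_mad = 6,
                            refractory_s = 0.2) {
  stopifnot(length(pupil_x) == length(pupil_y),
            length(pupil_x) == length(time))
  if (length(time) > 1 && 1 / stats::median(diff(time)) < 10 - 1e-6)
    stop("pupil trace must be sampled at >= 10 Hz")
  w <- as.integer(median_filter_width)
  if (w %% 2L == 0L) w <- w + 1L
  fx <- stats::runmed(pupil_x, w)
  fy <- stats::runmed(pupil_y, w)
  disp <- sqrt(diff(fx)^2 + diff(fy)^2)
  # noise scale from the unfiltered displacements: the median filter leaves
  # occasional isolated jumps that make the filtered-displacement MAD an
  # unstable denominator, while true saccadic steps survive filtering intact
  scale <- stats::mad(sqrt(diff(pupil_x)^2 + diff(pupil_y)^2))
  if (scale == 0) return(numeric(0))
  above <- which(disp > k_mad * scale)
  if (!length(above)) return(numeric(0))
  ev_times <- time[above + 1L]
  keep <- c(TRUE, diff(ev_times) > refractory_s)
  ev_times[keep]
}

#' Classify a trial by the presence of eye movements
#'
#' TRUE iff at least one saccade falls inside the stimulus window
#' (inclusive of onset, half-open at offset).
#'
#' @param saccade_times saccade times, s (see [detect_saccades()]).
#' @param window stimulus window `c(onset, offset)`, s.
#' @return list: `eye_movement` (flag), `n_saccades` (count in window).
#' @export
classify_eye_movement_trial <- function(saccade_times, window) {
  n <- sum(saccade_times >= window[1] - .time_eps &
             saccade_times < window[2] - .time_eps)
  list(eye_movement = n > 0L, n_saccades = n)
}

#' Navigation performance
#'
#' Fraction of session samples spent running (speed > `speed_threshold`) in
#' the direction of the goal within `tolerance` degrees (inclusive). The
#' denominator is the total session time.
#'
#' @param heading heading relative to the goal, degrees in `(-180, 180]`.
#' @param speed running speed, cm/s (same time base as `heading`).
#' @param tolerance heading tolerance, degrees.
#' @param speed_threshold speed threshold, cm/s.
#' @return fraction in `[0, 1]`.
#' @export
navigation_performance <- function(heading, speed, tolerance = 25,
                                   speed_threshold = 1) {
  stopifnot(length(heading) == length(speed))
  if (!length(heading)) stop("empty session")
  mean(speed > speed_threshold & abs(heading) <= tolerance)
}

#' Peri-reward lick analysis
#'
#' Per reward, computes the baseline-corrected pre-reward lick frequency:
#' the lick rate in `pre_window` (0.5 s to 0 s before the reward) minus the
#' rate in `baseline_window` (15 s to 13 s before the reward), both as event
#' counts divided by window duration. Rewards with less than 15 s of
#' preceding data are excluded. An animal is flagged as anticipating iff its
#' last-session pre-reward rates significantly exceed the first-session
#' rates (one-sided Wilcoxon rank-sum, alpha = 0.05).
#'
#' @param lick_times lick event times, s.
#' @param reward_times reward delivery times, s.
#' @param sessions optional session label per reward (required for the
#'   anticipation flag).
#' @param baseline_window,pre_window windows relative to reward, s.
#' @param alpha significance level of the anticipation test.
#' @return list of class `"lick_analysis"`: `per_reward` (data.frame
#'   `reward_time`, `session`, `pre_rate`, `baseline_rate`, `corrected`),
#'   `anticipating` (flag, `NA` without session labels), `p_value`.
#' @export
lick_analysis <- function(lick_times, reward_times, sessions = NULL,
                          baseline_window = c(-15, -13),
                          pre_window = c(-0.5, 0), alpha = 0.05) {
  if (is.null(sessions)) sessions <- rep(NA_character_, length(reward_times))
  stopifnot(length(sessions) == length(reward_times))
  min_history <- -min(baseline_window[1], pre_window[1])
  ok <- reward_times >= min_history
  rate_in <- function(r, win) {
    sum(lick_times >= r + win[1] - .time_eps &
          lick_times < r + win[2] - .time_eps) / diff(win)
  }
  pre <- vapply(reward_times[ok], rate_in, numeric(1), win = pre_window)
  base <- vapply(reward_times[ok], rate_in, numeric(1), win = baseline_window)
  per_reward <- data.frame(reward_time = reward_times[ok],
                           session = sessions[ok],
                           pre_rate = pre, baseline_rate = base,
                           corrected = pre - base)
  anticipating <- NA
  p_value <- NA_real_
  sess <- unique(per_reward$session)
  sess <- sess[!is.na(sess)]
  if (length(sess) >= 2L) {
    first <- per_reward$corrected[per_reward$session == sess[1]]
    last <- per_reward$corrected[per_reward$session == sess[length(sess)]]
    if (length(first) >= 2L && length(last) >= 2L) {
      wt <- suppressWarnings(
        stats::wilcox.test(last, first, alternative = "greater"))
      p_value <- wt$p.value
      anticipating <- is.finite(p_value) && p_value < alpha
    }
  }
  structure(list(per_reward = per_reward, anticipating = anticipating,
                 p_value = p_value),
            class = "lick_analysis")
}

#' Per-session behavioral summary
#'
#' @param behavior a `"behavior_trace"` with a per-sample `session` label
#'   (or pass `sessions` explicitly).
#' @param saccade_times saccade times, s; defaults to running
#'   [detect_saccades()] on the pupil trace.
#' @param sessions optional per-sample session label.
#' @param speed_threshold running threshold, cm/s.
#' @return data.frame: `session`, `running_fraction`, `mean_speed` (cm/s),
#'   `saccade_rate` (saccades/min), `duration_s`.
#' @export
session_behavior_summary <- function(behavior, saccade_times = NULL,
                                     sessions = NULL, speed_threshold = 1) {
  if (is.null(sessions)) sessions <- behavior$session
  stopifnot(length(sessions) == length(behavior$time))
  if (is.null(saccade_times))
    saccade_times <- detect_saccades(behavior$pupil_x, behavior$pupil_y,
                                     behavior$time)
  out <- lapply(unique(sessions), function(s) {
    idx <- which(sessions == s)
    dur <- length(idx) / behavior$sample_rate
    t_lo <- min(behavior$time[idx]); t_hi <- max(behavior$time[idx])
    n_sacc <- sum(saccade_times >= t_lo & saccade_times <= t_hi)
    data.frame(session = s,
               running_fraction = mean(behavior$speed[idx] > speed_threshold),
               mean_speed = mean(behavior$speed[idx]),
               saccade_rate = n_sacc / dur * 60,
               duration_s = dur)
  })
  do.call(rbind, out)
}
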
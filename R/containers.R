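#' Recording of per-cell activity traces
#'
#' Container for a cells x frames matrix of fluorescence (arbitrary units) or
#' binned spike rate (spikes/s) on a uniform time base. Frame `f` covers the
#' half-open interval `[(f-1)/frame_rate, f/frame_rate)` seconds, so frame 1
#' starts at time 0.
#'
#' @param values numeric matrix, cells x frames.
#' @param frame_rate sampling rate in Hz (> 0).
#' @param cell_class character vector, one of `"putative_excitatory"` or
#'   `"PV"` per cell. Recycled if length 1.
#' @param state behavioral state of the recording, `"awake"` or
#'   `"anesthetized"` (free-form values are allowed for synthetic conditions).
#' @param session session identifier.
#' @param cell_ids optional cell identifiers; defaults to `cell_1 ...`.
#'
#' @return An object of class `"recording"`: a list with elements `values`,
#'   `frame_rate`, `cell_class`, `state`, `session`, `cell_ids`.
#' @export
recording <- function(values, frame_rate,
                      cell_class = "putative_excitatory",
                      state = "awake", session = "session_1",
                      cell_ids = NULL) {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), is.numeric(frame_rate),
            length(frame_rate) == 1L, frame_rate > 0)
  n <- nrow(values)
  if (length(cell_class) == 1L) cell_class <- rep(cell_class, n)
  stopifnot(length(cell_class) == n)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  structure(list(values = values, frame_rate = frame_rate,
                 cell_class = cell_class, state = state,
                 session = session, cell_ids = cell_ids),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d cells x %d frames @ %.4g Hz (%.1f s), state=%s\n",
              nrow(x$values), ncol(x$values), x$frame_rate,
              ncol(x$values) / x$frame_rate, x$state))
  invisible(x)
}

#' Frame times of a recording
#'
#' @param rec a [recording()].
#' @return numeric vector of frame start times in seconds (frame 1 at 0).
#' @export
frame_times <- function(rec) {
  (seq_len(ncol(rec$values)) - 1L) / rec$frame_rate
}

#' Stimulus trial table
#'
#' One row per stimulus presentation. Times are in seconds on the recording
#' time base; trial time is 0 at stimulus onset and windows follow the
#' half-open convention `[left, right)`.
#'
#' @param onset stimulus onset times (s).
#' @param duration stimulus durations (s).
#' @param direction drifting direction in degrees, `[0, 360)`.
#' @param contrast stimulus contrast in percent.
#' @param condition condition tag (e.g. `"awake"`, `"anesthetized"`, `"s1"`,
#'   `"adapted"`, `"control"`, `"led_adapted"`).
#' @param session session identifier.
#' @param led logical, optogenetic LED on during this trial.
#' @param reward_time reward delivery time (s), `NA` if unrewarded.
#' @param type trial type tag, e.g. `"tuning"` or `"adaptation"`.
#' @param adapter adapter orientation tag for two-epoch trials
#'   (`"iso"`/`"cross"`), `NA` otherwise.
#'
#' @return A `data.frame` of class `"trial_table"` with a `trial` id column.
#' @export
trial_table <- function(onset, duration, direction = 0, contrast = 100,
                        condition = "default", session = "session_1",
                        led = FALSE, reward_time = NA_real_,
                        type = "adaptation", adapter = NA_character_) {
  stopifnot(is.numeric(onset), is.numeric(duration), all(duration > 0))
  n <- length(onset)
  tt <- data.frame(trial = seq_len(n), onset = onset, duration = duration,
                   direction = wrap_deg(rep_len(direction, n)),
                   contrast = rep_len(contrast, n),
                   condition = rep_len(condition, n),
                   session = rep_len(session, n),
                   led = rep_len(led, n),
                   reward_time = rep_len(reward_time, n),
                   type = rep_len(type, n),
                   adapter = rep_len(adapter, n),
                   stringsAsFactors = FALSE)
  class(tt) <- c("trial_table", "data.frame")
  tt
}

#' Cut a recording into a trial-aligned tensor
#'
#' Extracts, for every trial, the frames whose start times fall in
#' `[onset - pre_s, onset + post_s)` and stacks them into a cells x trials x
#' time array. All trials must fit inside the recording.
#'
#' @param rec a [recording()].
#' @param trials a [trial_table()].
#' @param pre_s seconds of pre-onset data to include (>= 0).
#' @param post_s seconds of post-onset data to include (> 0).
#'
#' @return A 3-d array of class `"trial_tensor"` (cells x trials x time) with
#'   attributes `time` (frame times relative to onset), `frame_rate`,
#'   `trials` (the trial table), `cell_ids`, `cell_class`.
#' @export
cut_trials <- function(rec, trials, pre_s = 2, post_s = NULL) {
  stopifnot(inherits(rec, "recording"), pre_s >= 0)
  if (is.null(post_s)) post_s <- max(trials$duration)
  fr <- rec$frame_rate
  n_pre <- round(pre_s * fr)
  n_post <- round(post_s * fr)
  rel_idx <- seq.int(-n_pre, n_post - 1L)
  n_frames <- ncol(rec$values)
  # first frame whose start time >= onset
  onset_idx <- floor(trials$onset * fr + .time_eps) + 1L
  lo <- onset_idx - n_pre
  hi <- onset_idx + n_post - 1L
  if (any(lo < 1L) || any(hi > n_frames))
    stop("trial windows fall outside the recording")
  n_cells <- nrow(rec$values)
  out <- array(NA_real_, dim = c(n_cells, nrow(trials), length(rel_idx)))
  for (j in seq_len(nrow(trials)))
    out[, j, ] <- rec$values[, onset_idx[j] + rel_idx, drop = FALSE]
  structure(out,
            time = rel_idx / fr,
            frame_rate = fr,
            trials = trials,
            cell_ids = rec$cell_ids,
            cell_class = rec$cell_class,
            class = "trial_tensor")
}

#' @export
print.trial_tensor <- function(x, ...) {
  d <- dim(x)
  tm <- attr(x, "time")
  cat(sprintf("<trial_tensor> %d cells x %d trials x %d frames, t in [%.2f, %.2f] s\n",
              d[1], d[2], d[3], tm[1], tm[length(tm)]))
  invisible(x)
}

#' Time axis of a trial tensor
#' @param tensor a `"trial_tensor"`.
#' @return numeric vector of frame times relative to stimulus onset (s).
#' @export
tensor_time <- function(tensor) attr(tensor, "time")
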
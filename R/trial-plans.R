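# Trial-plan builders for the three experimental protocols.

#' Trial plan for the awake/anesthetized state experiment
#'
#' Per state: a direction-tuning block (short gratings in 8 directions) and an
#' adaptation block (sustained gratings at the iso orientation). The awake
#' block precedes the anesthetized block, mirroring an awake-then-anesthesia
#' recording.
#'
#' @param n_adapt_per_state sustained-grating trials per state.
#' @param stim_s sustained-grating duration, s (10 s in the state protocol).
#' @param gap_s grey-screen gap between sustained gratings, s.
#' @param tuning_reps repetitions of each direction in the tuning block.
#' @param tuning_stim_s,tuning_gap_s tuning-grating duration and gap, s.
#' @param directions tuning directions, degrees.
#' @param iso_direction direction of the sustained grating, degrees.
#' @param contrast sustained-grating contrast, percent.
#' @return a [trial_table()] with conditions `"awake"`/`"anesthetized"` and
#'   types `"tuning"`/`"adaptation"`.
#' @export
state_trial_plan <- function(n_adapt_per_state = 15, stim_s = 10, gap_s = 10,
                             tuning_reps = 4, tuning_stim_s = 2,
                             tuning_gap_s = 4,
                             directions = seq(0, 315, by = 45),
                             iso_direction = 0, contrast = 50) {
  onset <- 5
  rows <- list()
  for (state in c("awake", "anesthetized")) {
    dirs <- rep(directions, tuning_reps)
    for (d in dirs) {
      rows[[length(rows) + 1L]] <- list(onset = onset, duration = tuning_stim_s,
                                        direction = d, condition = state,
                                        type = "tuning")
      onset <- onset + tuning_stim_s + tuning_gap_s
    }
    for (k in seq_len(n_adapt_per_state)) {
      rows[[length(rows) + 1L]] <- list(onset = onset, duration = stim_s,
                                        direction = iso_direction,
                                        condition = state,
                                        type = "adaptation")
      onset <- onset + stim_s + gap_s
    }
  }
  df <- do.call(rbind, lapply(rows, as.data.frame))
  trial_table(onset = df$onset, duration = df$duration,
              direction = df$direction, contrast = contrast,
              condition = df$condition, session = "session_1",
              type = df$type)
}

#' Trial plan for the five-session stimulus-relevance experiment
#'
#' Per session: a direction-tuning block followed by sustained horizontal
#' probe-patch gratings (both drift directions) interspersed with random grey
#' intervals. In the grating-relevant variant a water reward is delivered
#' `reward_delay_s` after each probe offset.
#'
#' @param n_sessions number of training sessions.
#' @param trials_per_session probe gratings per session.
#' @param stim_s probe duration, s.
#' @param gap_range range of the random grey interval between probes, s.
#' @param tuning_reps repetitions of each direction in the tuning block.
#' @param tuning_stim_s,tuning_gap_s tuning-grating duration and gap, s.
#' @param directions tuning directions, degrees.
#' @param rewarded logical: deliver a reward after each probe
#'   (grating-relevant condition).
#' @param reward_delay_s delay of the reward after probe offset, s.
#' @param seed seed for the random grey intervals.
#' @return a [trial_table()]; probe trials carry condition and session
#'   `"s1" ... "s5"`, tuning trials type `"tuning"`.
#' @export
relevance_trial_plan <- function(n_sessions = 5, trials_per_session = 16,
                                 stim_s = 10, gap_range = c(10, 20),
                                 tuning_reps = 2, tuning_stim_s = 4,
                                 tuning_gap_s = 4,
                                 directions = seq(0, 315, by = 45),
                                 rewarded = FALSE, reward_delay_s = 1,
                                 seed = 99) {
  with_seed(seed, {
    onset <- 5
    rows <- list()
    for (s in seq_len(n_sessions)) {
      sess <- paste0("s", s)
      for (d in rep(directions, tuning_reps)) {
        rows[[length(rows) + 1L]] <-
          list(onset = onset, duration = tuning_stim_s, direction = d,
               condition = sess, type = "tuning", reward_time = NA_real_)
        onset <- onset + tuning_stim_s + tuning_gap_s
      }
      for (k in seq_len(trials_per_session)) {
        dir <- if (k %% 2 == 0) 180 else 0  # horizontal grating, both drifts
        reward <- if (rewarded) onset + stim_s + reward_delay_s else NA_real_
        rows[[length(rows) + 1L]] <-
          list(onset = onset, duration = stim_s, direction = dir,
               condition = sess, type = "probe", reward_time = reward)
        onset <- onset + stim_s + stats::runif(1, gap_range[1], gap_range[2])
      }
    }
    df <- do.call(rbind, lapply(rows, as.data.frame))
    trial_table(onset = df$onset, duration = df$duration,
                direction = df$direction, contrast = 100,
                condition = df$condition, session = df$condition,
                reward_time = df$reward_time, type = df$type)
  })
}

#' Trial plan for the optogenetic silencing experiment
#'
#' Interleaves the three stimulus conditions: `adapted` (grating for
#' `stim_s`), `control` (grey for the first half, grating for the second) and
#' `led_adapted` (grating for `stim_s` with LED during the first half).
#'
#' @param reps_per_condition trials per condition and direction.
#' @param stim_s stimulus-block duration, s (7 s in the silencing protocol).
#' @param directions grating directions (cardinal by default), degrees.
#' @return a [trial_table()] with `led = TRUE` on `led_adapted` trials.
#'   Onsets are nominal (spike times are trial-relative).
#' @export
spike_trial_plan <- function(reps_per_condition = 10, stim_s = 7,
                             directions = c(0, 90, 180, 270)) {
  grid <- expand.grid(rep = seq_len(reps_per_condition),
                      direction = directions,
                      condition = c("adapted", "control", "led_adapted"),
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  onset <- (seq_len(n) - 1) * (stim_s + 3)
  trial_table(onset = onset, duration = stim_s, direction = grid$direction,
              contrast = 100, condition = grid$condition,
              led = grid$condition == "led_adapted", type = "adaptation")
}

#' Trial plan for the iso/cross-orientation adaptation paradigm
#'
#' Two-epoch trials: a 10 s adapter at the iso or cross orientation (50%
#' contrast) followed by a 10 s test grating at the iso orientation at 25% or
#' 100% contrast. The `contrast` column holds the test contrast; the adapter
#' contrast is fixed at 50%.
#'
#' @param reps trials per adapter x contrast combination.
#' @param epoch_s duration of each epoch, s.
#' @param gap_s grey interval between trials, s.
#' @param test_contrasts test-epoch contrasts, percent.
#' @param iso_direction iso orientation direction, degrees.
#' @return a [trial_table()] with `adapter` in `"iso"`/`"cross"` and
#'   `duration = 2 * epoch_s`.
#' @export
iso_cross_trial_plan <- function(reps = 10, epoch_s = 10, gap_s = 10,
                                 test_contrasts = c(25, 100),
                                 iso_direction = 0) {
  grid <- expand.grid(rep = seq_len(reps),
                      adapter = c("iso", "cross"),
                      contrast = test_contrasts,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  onset <- 5 + (seq_len(n) - 1) * (2 * epoch_s + gap_s)
  trial_table(onset = onset, duration = 2 * epoch_s,
              direction = iso_direction, contrast = grid$contrast,
              condition = "adapt_test", adapter = grid$adapter,
              type = "adaptation")
}
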
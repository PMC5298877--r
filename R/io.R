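# Plain-text dataset container: a directory of CSV files plus a small
# key-value metadata file.

#' Write a generated dataset to a directory of CSV files
#'
#' Layout: `fluorescence.csv` (cells x frames, no header), `cells.csv`
#' (cell_id, cell_class), `meta.csv` (key,value: frame_rate, state),
#' `trials.csv`, `behavior.csv` (time, speed, heading, pupil_x, pupil_y),
#' `events.csv` (event, time: licks, rewards, ground-truth saccades) and
#' `truth.csv`.
#'
#' @param dataset a `"generated_dataset"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- dataset$recording
  utils::write.table(rec$values, file.path(dir, "fluorescence.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.csv(data.frame(cell_id = rec$cell_ids,
                              cell_class = rec$cell_class),
                   file.path(dir, "cells.csv"), row.names = FALSE)
  utils::write.csv(data.frame(key = c("frame_rate", "state"),
                              value = c(rec$frame_rate, rec$state)),
                   file.path(dir, "meta.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(dataset$trials),
                   file.path(dir, "trials.csv"), row.names = FALSE)
  b <- dataset$behavior
  utils::write.csv(data.frame(time = b$time, speed = b$speed,
                              heading = b$heading, pupil_x = b$pupil_x,
                              pupil_y = b$pupil_y, session = b$session),
                   file.path(dir, "behavior.csv"), row.names = FALSE)
  ev <- rbind(
    data.frame(event = rep("lick", length(b$lick_times)),
               time = b$lick_times),
    data.frame(event = rep("reward", length(b$reward_times)),
               time = b$reward_times),
    data.frame(event = rep("saccade", length(b$truth$saccade_times)),
               time = b$truth$saccade_times))
  utils::write.csv(ev, file.path(dir, "events.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(dataset$truth),
                   file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return a list of class `"generated_dataset"` with `recording`, `trials`,
#'   `behavior` (lick/reward/saccade events and the behavioral time series)
#'   and `truth`; the original `config` is not restored.
#' @export
read_dataset <- function(dir) {
  meta <- utils::read.csv(file.path(dir, "meta.csv"),
                          colClasses = "character")
  key <- function(k) meta$value[meta$key == k]
  cells <- utils::read.csv(file.path(dir, "cells.csv"))
  values <- as.matrix(utils::read.table(file.path(dir, "fluorescence.csv"),
                                        sep = ","))
  dimnames(values) <- NULL
  rec <- recording(values, as.numeric(key("frame_rate")),
                   cell_class = cells$cell_class, state = key("state"),
                   cell_ids = cells$cell_id)
  trials <- utils::read.csv(file.path(dir, "trials.csv"))
  class(trials) <- c("trial_table", "data.frame")
  bdf <- utils::read.csv(file.path(dir, "behavior.csv"))
  ev <- utils::read.csv(file.path(dir, "events.csv"))
  dt <- stats::median(diff(bdf$time))
  behavior <- structure(
    list(time = bdf$time, speed = bdf$speed, heading = bdf$heading,
         pupil_x = bdf$pupil_x, pupil_y = bdf$pupil_y,
         lick_times = ev$time[ev$event == "lick"],
         reward_times = ev$time[ev$event == "reward"],
         sample_rate = 1 / dt, session = bdf$session,
         truth = list(saccade_times = ev$time[ev$event == "saccade"])),
    class = "behavior_trace")
  truth <- utils::read.csv(file.path(dir, "truth.csv"))
  class(truth) <- c("ground_truth", "data.frame")
  structure(list(recording = rec, trials = trials, behavior = behavior,
                 truth = truth, config = NULL),
            class = "generated_dataset")
}
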
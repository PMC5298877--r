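# Analysis of the optogenetic silencing experiment: PV classification,
# response-failure exclusion, the post-LED probe bin, spike adaptation rate.

#' @noRd
spike_times_of <- function(dataset, cell, trial) {
  s <- dataset$spikes
  s$spike_time[s$cell_id == cell & s$trial == trial]
}

#' Mean firing rate of a cell over a set of trials
#'
#' @param dataset a `"spike_dataset"`.
#' @param cell cell id.
#' @param trials trial ids.
#' @param window counting window in trial time, s.
#' @return mean rate, spikes/s (count / window length, averaged over trials).
#' @export
mean_rate <- function(dataset, cell, trials, window = c(0, 3.5)) {
  if (!length(trials)) stop("no trials selected")
  counts <- vapply(trials, function(tr) {
    st <- spike_times_of(dataset, cell, tr)
    sum(st >= window[1] - .time_eps & st < window[2] - .time_eps)
  }, numeric(1))
  mean(counts) / diff(window)
}

#' Trial-averaged binned rate trace for one cell
#'
#' @param dataset a `"spike_dataset"`.
#' @param cell cell id.
#' @param trials trial ids to average.
#' @param window binning window, s.
#' @param bin_s bin width, s.
#' @return list: `rate` (mean across trials), `bin_left`, `bin_s`.
#' @export
rate_trace <- function(dataset, cell, trials, window = c(0, 7),
                       bin_s = 1 / 3) {
  mats <- vapply(trials, function(tr)
    bin_spikes(spike_times_of(dataset, cell, tr), window, bin_s)$rate,
    numeric(floor(diff(window) / bin_s + .time_eps)))
  br <- bin_spikes(numeric(0), window, bin_s)
  list(rate = rowMeans(as.matrix(mats)), bin_left = br$bin_left,
       bin_s = bin_s)
}

#' Preferred cardinal orientation and response-failure exclusion
#'
#' The preferred cardinal orientation (0 or 90 degrees) is the one with the
#' higher mean rate over the first 3.5 s of grating-only (`adapted`) trials.
#' A cell is kept iff at least half (inclusive) of its preferred-orientation
#' trials contain at least one spike in the stimulus window.
#'
#' @param dataset a `"spike_dataset"`.
#' @param cell cell id.
#' @param stim_window classification window, s.
#' @return list: `preferred_orientation` (degrees), `keep` (flag),
#'   `respond_frac` (fraction of responding trials).
#' @export
preferred_cardinal_and_exclusion <- function(dataset, cell,
                                             stim_window = c(0, 3.5)) {
  plan <- dataset$trials
  ori <- plan$direction %% 180
  cardinals <- sort(unique(ori[plan$condition == "adapted"]))
  if (length(cardinals) < 2L) stop("need responses to >= 2 cardinal orientations")
  rates <- vapply(cardinals, function(o)
    mean_rate(dataset, cell,
              plan$trial[plan$condition == "adapted" & ori == o],
              stim_window), numeric(1))
  pref <- cardinals[which.max(rates)]
  pref_trials <- plan$trial[plan$condition == "adapted" & ori == pref]
  responded <- vapply(pref_trials, function(tr) {
    st <- spike_times_of(dataset, cell, tr)
    any(st >= stim_window[1] - .time_eps & st < stim_window[2] - .time_eps)
  }, logical(1))
  frac <- mean(responded)
  list(preferred_orientation = pref, keep = frac >= 0.5,
       respond_frac = frac)
}

#' Classify a cell as PV+ or putative excitatory
#'
#' PV+ iff the mean rate over the first 3.5 s of preferred-orientation trials
#' is strictly higher with the LED than without it (ties are putative
#' excitatory). Uses grating trials with LED (`led_adapted`) versus without
#' (`adapted`).
#'
#' @param dataset a `"spike_dataset"`.
#' @param cell cell id.
#' @param stim_window comparison window, s.
#' @param preferred_orientation optional; computed via
#'   [preferred_cardinal_and_exclusion()] when missing.
#' @return `"PV"` or `"putative_excitatory"`.
#' @export
classify_pv <- function(dataset, cell, stim_window = c(0, 3.5),
                        preferred_orientation = NULL) {
  plan <- dataset$trials
  if (is.null(preferred_orientation))
    preferred_orientation <-
      preferred_cardinal_and_exclusion(dataset, cell,
                                       stim_window)$preferred_orientation
  ori <- plan$direction %% 180
  led_trials <- plan$trial[plan$condition == "led_adapted" &
                             ori == preferred_orientation]
  noled_trials <- plan$trial[plan$condition == "adapted" &
                               ori == preferred_orientation]
  if (!length(led_trials) || !length(noled_trials))
    stop("need preferred-orientation trials both with and without LED")
  r_led <- mean_rate(dataset, cell, led_trials, stim_window)
  r_off <- mean_rate(dataset, cell, noled_trials, stim_window)
  if (r_led > r_off) "PV" else "putative_excitatory"
}

#' Probe-bin rates after LED offset
#'
#' For each cell, the mean rate in the first complete bin whose left edge is
#' at or after the LED-off time, computed in the same absolute-time bin for
#' all three conditions (bins of `bin_s` starting at stimulus onset).
#'
#' @param dataset a `"spike_dataset"`.
#' @param cells cell ids (default all).
#' @param led_off LED complete-off time, s; defaults to [led_off_time()] of
#'   the dataset's spike parameters.
#' @param bin_s bin width, s.
#' @param preferred_only restrict to each cell's preferred cardinal
#'   orientation trials.
#' @return data.frame: `cell_id`, `probe_left` (bin left edge), `adapted`,
#'   `control`, `led_adapted` (rates, spikes/s). Cells missing any condition
#'   are dropped.
#' @export
post_led_probe <- function(dataset, cells = NULL, led_off = NULL,
                           bin_s = 1 / 3, preferred_only = TRUE) {
  plan <- dataset$trials
  if (is.null(cells)) cells <- unique(dataset$truth$cell_id)
  if (is.null(led_off)) led_off <- led_off_time(dataset$config$spikes)
  dur <- max(plan$duration)
  left_edges <- seq(0, dur - bin_s + .time_eps, by = bin_s)
  j <- which(left_edges >= led_off - .time_eps)[1]
  if (is.na(j)) stop("no complete bin after LED off within the trial")
  probe <- c(left_edges[j], left_edges[j] + bin_s)
  out <- lapply(cells, function(cl) {
    ori_sel <- if (preferred_only) {
      pref <- preferred_cardinal_and_exclusion(dataset, cl)$preferred_orientation
      plan$direction %% 180 == pref
    } else rep(TRUE, nrow(plan))
    rates <- vapply(c("adapted", "control", "led_adapted"), function(cond) {
      tr <- plan$trial[plan$condition == cond & ori_sel]
      if (!length(tr)) return(NA_real_)
      mean_rate(dataset, cl, tr, probe)
    }, numeric(1))
    data.frame(cell_id = cl, probe_left = probe[1],
               adapted = rates[["adapted"]], control = rates[["control"]],
               led_adapted = rates[["led_adapted"]])
  })
  res <- do.call(rbind, out)
  res[stats::complete.cases(res), , drop = FALSE]
}

#' Spike adaptation rate (decrease per second)
#'
#' The negative of the OLS slope of a normalized (peak = 1) mean rate trace
#' over the analysis window, reported as the mean decrease in normalized
#' rate per second.
#'
#' @param rate normalized mean rate trace (one value per bin).
#' @param time bin times (e.g. bin centers), s.
#' @param window analysis window, s.
#' @return decrease per second (positive = adapting).
#' @export
spike_adaptation_rate <- function(rate, time, window = c(1, 7)) {
  -adaptation_slope(rate, time, window)
}
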
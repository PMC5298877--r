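# End-to-end experiment orchestration: the awake/anesthetized state
# comparison and the five-session stimulus-relevance comparison.

#' Subtract the pre-stimulus baseline from every trial
#'
#' @param tensor a `"trial_tensor"`.
#' @param window baseline window in trial time, s.
#' @return tensor with the per-cell, per-trial mean over `window` subtracted.
#' @export
baseline_subtract <- function(tensor, window = c(-2, 0)) {
  tm <- attr(tensor, "time")
  bidx <- frames_in_window(tm, window)
  if (!length(bidx)) stop("empty baseline window")
  b <- apply(tensor[, , bidx, drop = FALSE], c(1, 2), mean)
  out <- sweep(tensor, c(1, 2), b, "-")
  attributes(out) <- attributes(tensor)
  out
}

# Per-trial OLS slope and window mean for every cell and trial.
#' @noRd
per_trial_metrics <- function(tensor, slope_window, mean_window = slope_window) {
  tm <- attr(tensor, "time")
  sidx <- frames_in_window(tm, slope_window)
  midx <- frames_in_window(tm, mean_window)
  stopifnot(length(sidx) >= 3L, length(midx) >= 1L)
  tc <- tm[sidx] - mean(tm[sidx])
  sxx <- sum(tc^2)
  n_cells <- dim(tensor)[1]; n_trials <- dim(tensor)[2]
  slope <- matrix(NA_real_, n_cells, n_trials)
  for (j in seq_len(n_trials))
    slope[, j] <- (tensor[, j, sidx, drop = TRUE] %*% tc) / sxx
  mean_r <- rowMeans(tensor[, , midx, drop = FALSE], dims = 2L)
  list(slope = slope, mean = mean_r)
}

#' Fit tuning and preferred directions for every cell
#' @noRd
fit_cells <- function(curve_matrix, directions) {
  lapply(seq_len(nrow(curve_matrix)), function(i)
    fit_direction_tuning(curve_matrix[i, ], directions))
}

#' Run the behavioral-state experiment
#'
#' Full pipeline for a dataset holding awake and anesthetized recordings of
#' the same cells: block filtering, pre-stimulus dF/F, per-state tuning fits
#' and trial-wise responsiveness, per-cell adaptation slopes per state and
#' per running/resting and eye-movement/eye-movement-free splits of the awake
#' trials, and the paired/unpaired comparisons between the groups.
#'
#' @param dataset a `"generated_dataset"` whose trial plan has `tuning` and
#'   `adaptation` trial types under conditions `"awake"` and
#'   `"anesthetized"` (see [state_trial_plan()]).
#' @param slope_window slope-fit window, s (1-9.75 s for 10 s stimuli, the
#'   last 0.25 s dropped because of the block filter).
#' @param tuning_response_window response window of the tuning trials, s.
#' @param baseline_s pre-stimulus baseline length, s.
#' @param filter_width block-filter width in frames; default rounds 0.26 s to
#'   frames.
#' @param z_threshold trial-wise responsiveness threshold.
#' @param tuned_rule which cells count as tuned: responsive with a
#'   non-degenerate fit in `"both"` states (default, as for awake-vs-
#'   anesthetized comparisons), in one named state, or in `"either"`.
#' @param min_split_trials minimum trials for a behavioral split slope.
#' @return list of class `"state_report"`: `cells` (one row per tuned cell:
#'   identifiers, class, per-state preferred direction and slope, split
#'   slopes), `comparisons` (see [comparison_table()]), `traces`
#'   (population mean +- SEM per state), `params`.
#' @export
run_state_experiment <- function(dataset,
                                 slope_window = c(1, 9.75),
                                 tuning_response_window = c(0, 2),
                                 baseline_s = 2,
                                 filter_width = NULL,
                                 z_threshold = 2.58,
                                 tuned_rule = c("both", "awake",
                                                "anesthetized", "either"),
                                 min_split_trials = 3L) {
  tuned_rule <- match.arg(tuned_rule)
  rec <- dataset$recording
  plan <- dataset$trials
  beh <- dataset$behavior
  fr <- rec$frame_rate
  if (is.null(filter_width)) filter_width <- max(1L, round(0.26 * fr))
  filt <- block_filter(rec, filter_width)
  states <- c("awake", "anesthetized")
  tune_plan <- plan[plan$type == "tuning", , drop = FALSE]
  adapt_plan <- plan[plan$type == "adaptation", , drop = FALSE]
  stopifnot(nrow(tune_plan) > 0, nrow(adapt_plan) > 0,
            all(states %in% plan$condition))

  ## tuning + responsiveness per state --------------------------------------
  tens_tune <- dff_prestim(filt, tune_plan, baseline_s = baseline_s)
  resp_tune <- trial_responses(tens_tune, tuning_response_window)
  n_cells <- nrow(resp_tune)
  per_state <- list()
  for (st in states) {
    sel <- tune_plan$condition == st
    curve <- tuning_curve(resp_tune[, sel, drop = FALSE],
                          tune_plan$direction[sel])
    dirs <- as.numeric(colnames(curve))
    fits <- fit_cells(curve, dirs)
    pref <- vapply(fits, function(f)
      if (f$flat) NA_real_ else f$pref_direction, numeric(1))
    nearest <- vapply(pref, function(p)
      if (is.na(p)) NA_real_ else dirs[which.min(dir_dist_deg(dirs, p))],
      numeric(1))
    responsive <- rep(FALSE, n_cells)
    for (d in dirs) {
      pick <- which(!is.na(nearest) & nearest == d)
      if (!length(pick)) next
      res_d <- classify_responsive_trialwise(
        tens_tune, c(-baseline_s, 0), tuning_response_window,
        trials = which(sel & tune_plan$direction == d),
        threshold = z_threshold)
      responsive[pick] <- res_d$responsive[pick]
    }
    per_state[[st]] <- list(fits = fits, pref = pref,
                            responsive = responsive,
                            tuned = responsive & !is.na(pref))
  }
  tuned <- switch(tuned_rule,
                  both = per_state$awake$tuned & per_state$anesthetized$tuned,
                  awake = per_state$awake$tuned,
                  anesthetized = per_state$anesthetized$tuned,
                  either = per_state$awake$tuned | per_state$anesthetized$tuned)

  ## adaptation slopes per state and behavioral split -----------------------
  tens_adapt <- dff_prestim(filt, adapt_plan, baseline_s = baseline_s)
  tm <- tensor_time(tens_adapt)
  sacc <- detect_saccades(beh$pupil_x, beh$pupil_y, beh$time)
  is_awake <- adapt_plan$condition == "awake"
  running <- eye <- rep(FALSE, nrow(adapt_plan))
  for (j in which(is_awake)) {
    win <- c(adapt_plan$onset[j], adapt_plan$onset[j] + adapt_plan$duration[j])
    running[j] <- classify_running(beh, win)
    eye[j] <- classify_eye_movement_trial(sacc, win)$eye_movement
  }
  slope_for <- function(trial_idx) {
    if (length(trial_idx) < min_split_trials) return(rep(NA_real_, n_cells))
    av <- average_trace(tens_adapt, trials = trial_idx, compute_sem = FALSE)
    apply(av$mean, 1L, adaptation_slope, time = tm, window = slope_window)
  }
  slopes <- list(
    anesthetized = slope_for(which(!is_awake)),
    awake = slope_for(which(is_awake)),
    running = slope_for(which(is_awake & running)),
    resting = slope_for(which(is_awake & !running)),
    eye_movement = slope_for(which(is_awake & eye)),
    eye_movement_free = slope_for(which(is_awake & !eye)))

  ## comparisons on tuned putative excitatory cells -------------------------
  use <- tuned & rec$cell_class == "putative_excitatory"
  # a behavioral split can be empty (e.g. no running trials); report a
  # degenerate row instead of failing
  safe_unpaired <- function(a, b, groups) {
    if (!any(is.finite(a)) || !any(is.finite(b)))
      return(structure(list(test = "rank_sum",
                            n = c(sum(is.finite(a)), sum(is.finite(b))),
                            statistic = NA_real_, p_value = NA_real_,
                            mean_a = NA_real_, mean_b = NA_real_,
                            sem_a = NA_real_, sem_b = NA_real_,
                            degenerate = TRUE, metric = "slope",
                            groups = groups),
                       class = "comparison_result"))
    unpaired_compare(a, b, metric = "slope", groups = groups)
  }
  cmp <- list(paired_compare(slopes$anesthetized[use], slopes$awake[use],
                             metric = "slope",
                             groups = c("anesthetized", "awake")))
  for (grp in c("running", "resting", "eye_movement", "eye_movement_free"))
    cmp[[length(cmp) + 1L]] <-
      safe_unpaired(slopes$anesthetized[use], slopes[[grp]][use],
                    c("anesthetized", grp))
  cmp[[length(cmp) + 1L]] <-
    safe_unpaired(slopes$running[use], slopes$resting[use],
                  c("running", "resting"))
  cmp[[length(cmp) + 1L]] <-
    safe_unpaired(slopes$eye_movement[use], slopes$eye_movement_free[use],
                  c("eye_movement", "eye_movement_free"))

  traces <- lapply(stats::setNames(states, states), function(st)
    average_trace(tens_adapt,
                  trials = which(adapt_plan$condition == st),
                  cells = which(use), population = TRUE))
  cells <- data.frame(
    cell_id = rec$cell_ids[use],
    cell_class = rec$cell_class[use],
    pref_awake = per_state$awake$pref[use],
    pref_anesthetized = per_state$anesthetized$pref[use],
    slope_anesthetized = slopes$anesthetized[use],
    slope_awake = slopes$awake[use],
    slope_running = slopes$running[use],
    slope_resting = slopes$resting[use],
    slope_eye_movement = slopes$eye_movement[use],
    slope_eye_movement_free = slopes$eye_movement_free[use])
  structure(list(cells = cells, comparisons = comparison_table(cmp),
                 traces = traces, slopes = slopes, tuned = tuned,
                 params = list(slope_window = slope_window,
                               filter_width = filter_width,
                               baseline_s = baseline_s,
                               z_threshold = z_threshold,
                               tuned_rule = tuned_rule,
                               n_total = n_cells,
                               n_running_trials = sum(is_awake & running),
                               n_eye_trials = sum(is_awake & eye))),
            class = "state_report")
}

#' @export
print.state_report <- function(x, ...) {
  cat(sprintf("<state_report> %d/%d tuned cells\n",
              nrow(x$cells), x$params$n_total))
  print(x$comparisons[, c("metric", "test", "group_a", "group_b",
                          "n_a", "n_b", "p_value")])
  invisible(x)
}

# --- relevance experiment ---------------------------------------------------

#' @noRd
as_dataset_list <- function(x) {
  if (inherits(x, "generated_dataset")) list(x) else x
}

# Single-animal analysis for the relevance experiment.
#' @noRd
analyze_relevance_dataset <- function(ds, animal, slope_window,
                                      response_window, baseline_s,
                                      z_threshold) {
  plan <- ds$trials
  dff <- dff_rolling_percentile(ds$recording)
  probes <- plan[plan$type == "probe", , drop = FALSE]
  tune_plan <- plan[plan$type == "tuning", , drop = FALSE]
  sessions <- unique(probes$session)
  tens <- cut_trials(dff, probes, pre_s = baseline_s)
  tens_bs <- baseline_subtract(tens, c(-baseline_s, 0))

  # tuning pooled over all sessions; horizontal +-45 deg rule
  tens_tune <- cut_trials(dff, tune_plan, pre_s = baseline_s)
  resp_tune <- trial_responses(tens_tune, c(0, max(tune_plan$duration)),
                               baseline_window = c(-baseline_s, 0))
  curve <- tuning_curve(resp_tune, tune_plan$direction)
  fits <- fit_cells(curve, as.numeric(colnames(curve)))
  horizontal <- vapply(fits, classify_horizontal_tuned, logical(1))

  # session-wise responsiveness on the probe responses (two-sided)
  resp_raw <- trial_responses(tens, response_window)
  base_raw <- trial_responses(tens, c(-baseline_s, 0))
  responsive <- classify_responsive_sessionwise(
    resp_raw, base_raw, probes$session, threshold = z_threshold)$responsive

  tuned <- horizontal & responsive &
    ds$recording$cell_class == "putative_excitatory"

  pm <- per_trial_metrics(tens_bs, slope_window)
  by_session <- function(m) {
    out <- vapply(sessions, function(s)
      rowMeans(m[, probes$session == s, drop = FALSE], na.rm = TRUE),
      numeric(nrow(m)))
    colnames(out) <- sessions
    out
  }
  licks <- if (length(ds$behavior$reward_times) > 0) {
    rsess <- plan$session[!is.na(plan$reward_time)]
    lick_analysis(ds$behavior$lick_times, ds$behavior$reward_times,
                  sessions = rsess)
  } else NULL
  list(animal = animal, sessions = sessions, tuned = tuned,
       cell_ids = paste0(animal, ":", ds$recording$cell_ids),
       cell_class = ds$recording$cell_class,
       slope_session = by_session(pm$slope),
       mean_session = by_session(pm$mean),
       per_trial = list(slope = pm$slope, mean = pm$mean,
                        session = probes$session),
       licks = licks)
}

#' @noRd
pool_condition <- function(parts, condition) {
  tuned_rows <- lapply(parts, function(p) which(p$tuned))
  data.frame(
    condition = condition,
    animal = unlist(lapply(parts, function(p) rep(p$animal, sum(p$tuned)))),
    cell_id = unlist(lapply(parts, function(p) p$cell_ids[p$tuned])),
    do.call(rbind, lapply(parts, function(p)
      p$slope_session[p$tuned, , drop = FALSE])) |>
      (\(m) stats::setNames(as.data.frame(m),
                            paste0("slope_", colnames(m))))(),
    do.call(rbind, lapply(parts, function(p)
      p$mean_session[p$tuned, , drop = FALSE])) |>
      (\(m) stats::setNames(as.data.frame(m),
                            paste0("mean_", colnames(m))))(),
    row.names = NULL)
}

# Population per-trial metric (mean across a set of cells) concatenated
# across animals, with session labels, for the quarter trajectories.
#' @noRd
population_trials <- function(parts, keep_ids, what = "slope") {
  vals <- list(); sess <- list()
  for (p in parts) {
    keep <- p$tuned & p$cell_ids %in% keep_ids
    if (!any(keep)) next
    vals[[length(vals) + 1L]] <-
      colMeans(p$per_trial[[what]][keep, , drop = FALSE], na.rm = TRUE)
    sess[[length(sess) + 1L]] <- p$per_trial$session
  }
  list(values = unlist(vals), sessions = unlist(sess))
}

#' Run the stimulus-relevance experiment
#'
#' Full pipeline for the five-session grating-irrelevant versus
#' grating-relevant comparison: rolling-percentile dF/F, pooled-session
#' tuning with the horizontal +-45 degree rule, session-wise two-sided
#' responsiveness, per-trial slopes and mean responses over the probe window,
#' matched 10% exclusion of the relevant group against the irrelevant
#' session-1 reference, within-condition (session 1 versus the average of
#' the later sessions, signed-rank) and across-condition (per session,
#' rank-sum) comparisons, four-quarter session trajectories with exponential
#' fits, and anticipatory-licking subgrouping of the relevant animals.
#'
#' @param datasets_irrelevant,datasets_relevant a `"generated_dataset"` or
#'   list of them (one per animal), built on [relevance_trial_plan()]s with
#'   identical session structure.
#' @param slope_window slope/mean window, s (1-10 s of visual stimulation).
#' @param response_window responsiveness window, s (the 4 s used for tuning
#'   in the behavior protocol is applied to the probe via its first seconds).
#' @param baseline_s pre-stimulus baseline, s.
#' @param exclusion_frac matched-exclusion fraction.
#' @param z_threshold session-wise responsiveness threshold.
#' @return list of class `"relevance_report"`: `cells` (per tuned cell:
#'   condition, animal, per-session slopes and mean responses, `excluded`
#'   flag for the relevant group), `exclusion` (the [matched_exclusion()]
#'   ledger), `comparisons`, `trajectories` (per condition and metric,
#'   [session_trajectory()] objects), `licks` (per relevant animal), and
#'   `params`.
#' @export
run_relevance_experiment <- function(datasets_irrelevant, datasets_relevant,
                                     slope_window = c(1, 10),
                                     response_window = c(0, 4),
                                     baseline_s = 2,
                                     exclusion_frac = 0.10,
                                     z_threshold = 3.29) {
  dsi <- as_dataset_list(datasets_irrelevant)
  dsr <- as_dataset_list(datasets_relevant)
  probe_sessions <- function(ds)
    unique(ds$trials$session[ds$trials$type == "probe"])
  sess0 <- probe_sessions(dsi[[1]])
  ok <- vapply(c(dsi, dsr), function(ds)
    identical(probe_sessions(ds), sess0), logical(1))
  if (!all(ok)) stop("datasets have mismatched session structure")
  parts_i <- lapply(seq_along(dsi), function(k)
    analyze_relevance_dataset(dsi[[k]], paste0("irr", k), slope_window,
                              response_window, baseline_s, z_threshold))
  parts_r <- lapply(seq_along(dsr), function(k)
    analyze_relevance_dataset(dsr[[k]], paste0("rel", k), slope_window,
                              response_window, baseline_s, z_threshold))
  sessions <- parts_i[[1]]$sessions
  all_sessions <- lapply(c(parts_i, parts_r), `[[`, "sessions")
  if (!all(vapply(all_sessions, function(s) identical(s, sessions),
                  logical(1))))
    stop("datasets have mismatched session structure")
  n_sess <- length(sessions)
  late <- sessions[-1]

  cells_i <- pool_condition(parts_i, "irrelevant")
  cells_r <- pool_condition(parts_r, "relevant")

  # matched exclusion of the relevant group against the irrelevant
  # session-1 mean response
  ref_mean <- mean(cells_i[[paste0("mean_", sessions[1])]])
  excl <- matched_exclusion(cells_r[[paste0("mean_", sessions[1])]],
                            ref_mean, frac = exclusion_frac,
                            ids = cells_r$cell_id)
  cells_r$excluded <- cells_r$cell_id %in% excl$excluded
  cells_i$excluded <- FALSE
  keep_r <- cells_r[!cells_r$excluded, , drop = FALSE]

  s1_col <- function(df, what) df[[paste0(what, "_", sessions[1])]]
  late_mean <- function(df, what)
    rowMeans(as.matrix(df[paste0(what, "_", late)]))

  cmp <- list()
  for (what in c("slope", "mean")) {
    metric <- if (what == "slope") "adaptation_slope" else "mean_response"
    cmp[[length(cmp) + 1L]] <- paired_compare(
      s1_col(cells_i, what), late_mean(cells_i, what),
      metric = metric,
      groups = c("irrelevant_s1", "irrelevant_late"))
    cmp[[length(cmp) + 1L]] <- paired_compare(
      s1_col(keep_r, what), late_mean(keep_r, what),
      metric = metric,
      groups = c("relevant_s1", "relevant_late"))
    for (s in sessions)
      cmp[[length(cmp) + 1L]] <- unpaired_compare(
        cells_i[[paste0(what, "_", s)]], keep_r[[paste0(what, "_", s)]],
        metric = metric,
        groups = paste(c("irrelevant", "relevant"), s, sep = "_"))
  }

  # anticipatory-licking subgroups of the relevant animals
  licks <- do.call(rbind, lapply(parts_r, function(p)
    data.frame(animal = p$animal,
               anticipating = if (is.null(p$licks)) NA else p$licks$anticipating,
               p_value = if (is.null(p$licks)) NA_real_ else p$licks$p_value)))
  if (!is.null(licks) && any(!is.na(licks$anticipating))) {
    ant_animals <- licks$animal[licks$anticipating %in% TRUE]
    for (grp in c("anticipating", "non_anticipating")) {
      sel <- if (grp == "anticipating")
        keep_r$animal %in% ant_animals else !(keep_r$animal %in% ant_animals)
      if (sum(sel) >= 4L) {
        cmp[[length(cmp) + 1L]] <- paired_compare(
          s1_col(keep_r[sel, ], "slope"), late_mean(keep_r[sel, ], "slope"),
          metric = "adaptation_slope",
          groups = paste0(grp, c("_s1", "_late")))
      }
    }
  }

  trajectories <- list()
  for (cond in c("irrelevant", "relevant")) {
    parts <- if (cond == "irrelevant") parts_i else parts_r
    keep_ids <- if (cond == "irrelevant") cells_i$cell_id else keep_r$cell_id
    for (what in c("slope", "mean")) {
      pt <- population_trials(parts, keep_ids, what)
      trajectories[[paste(cond, what, sep = "_")]] <-
        session_trajectory(pt$values, pt$sessions)
    }
  }

  cells_i$excluded <- FALSE
  cells <- rbind(cells_i, cells_r)
  structure(list(cells = cells, exclusion = excl,
                 comparisons = comparison_table(cmp),
                 trajectories = trajectories, licks = licks,
                 params = list(slope_window = slope_window,
                               response_window = response_window,
                               baseline_s = baseline_s,
                               exclusion_frac = exclusion_frac,
                               z_threshold = z_threshold,
                               sessions = sessions,
                               n_tuned_irrelevant = nrow(cells_i),
                               n_tuned_relevant = nrow(cells_r))),
            class = "relevance_report")
}

#' @export
print.relevance_report <- function(x, ...) {
  cat(sprintf("<relevance_report> %d irrelevant / %d relevant tuned cells (%d excluded)\n",
              x$params$n_tuned_irrelevant, x$params$n_tuned_relevant,
              length(x$exclusion$excluded)))
  print(x$comparisons[, c("metric", "test", "group_a", "group_b",
                          "n_a", "n_b", "p_value")])
  invisible(x)
}
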
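# Adaptation metrics: trial-averaged traces, normalization, slopes, mean
# responses, iso/cross adaptation, suppression statistics, the matched
# 10% exclusion, and session trajectories with exponential fits.

#' Trial-averaged trace with SEM
#'
#' Pointwise mean and SEM across the selected trials for each cell. With
#' `population = TRUE`, trials are first averaged within cells and the mean
#' and SEM are then taken across the per-cell means (the cell is the unit of
#' analysis).
#'
#' @param tensor a `"trial_tensor"`.
#' @param trials optional trial indices/logical mask (default all).
#' @param cells optional cell indices/logical mask (default all).
#' @param population collapse across cells as described above.
#' @param compute_sem set `FALSE` to skip the SEM (faster in inner loops).
#' @return list with `time`, `mean`, `sem`; `mean`/`sem` are cells x time
#'   matrices, or vectors when `population = TRUE`.
#' @export
average_trace <- function(tensor, trials = NULL, cells = NULL,
                          population = FALSE, compute_sem = TRUE) {
  if (is.null(trials)) trials <- seq_len(dim(tensor)[2])
  if (is.null(cells)) cells <- seq_len(dim(tensor)[1])
  sub <- tensor[cells, trials, , drop = FALSE]
  if (dim(sub)[2] < 1L) stop("empty trial selection")
  m <- colMeans(aperm(sub, c(2, 1, 3)), na.rm = TRUE)  # mean over trials
  if (population) {
    pm <- colMeans(m, na.rm = TRUE)
    ps <- if (compute_sem) apply(m, 2L, sem) else NULL
    return(list(time = attr(tensor, "time"), mean = pm, sem = ps))
  }
  s <- if (compute_sem) apply(sub, c(1, 3), function(x) sem(x)) else NULL
  list(time = attr(tensor, "time"), mean = m, sem = s)
}

#' Normalize a trace by its peak within the stimulus window
#'
#' Divides the trace by the maximum of the (trial-averaged) trace within the
#' stimulus window, so the normalized peak is 1. A non-positive peak is an
#' error: such cells are excluded from normalized analyses.
#'
#' @param trace numeric vector (a trial-averaged trace).
#' @param time frame times for `trace`, s.
#' @param stim_window window in which to find the peak, s.
#' @return list: `trace` (normalized), `peak` (the divisor).
#' @export
normalize_trace <- function(trace, time, stim_window) {
  idx <- frames_in_window(time, stim_window)
  if (!length(idx)) stop("empty stimulus window")
  peak <- max(trace[idx], na.rm = TRUE)
  if (!is.finite(peak) || peak <= 0)
    stop("non-positive peak within the stimulus window; cell excluded")
  list(trace = trace / peak, peak = peak)
}

#' Slope of adaptation
#'
#' Ordinary least-squares slope of the trace against time (seconds) within
#' the analysis window. Negative slopes indicate adaptation. Standard
#' windows: 1-9.75 s for 10 s stimuli analyzed with the block filter (the
#' last 0.25 s is trimmed because of the filter), 1-7 s for 7 s stimuli,
#' 1-10 s for the behavior-task probes; the first second is excluded because
#' the indicator-driven initial rise is not adaptation.
#'
#' @param trace numeric vector.
#' @param time frame times for `trace`, s (or a scalar frame rate in Hz, in
#'   which case times start at 0).
#' @param window analysis window, s.
#' @return slope in trace units per second.
#' @export
adaptation_slope <- function(trace, time, window = c(1, 9.75)) {
  if (length(time) == 1L) time <- (seq_along(trace) - 1L) / time
  idx <- frames_in_window(time, window)
  if (length(idx) < 3L) stop("need at least 3 samples in the slope window")
  ols_slope(trace[idx], time[idx])
}

#' Mean response within a window
#'
#' @param trace numeric vector.
#' @param time frame times, s (or a scalar frame rate in Hz).
#' @param window averaging window, s.
#' @return time-average of the trace over the window.
#' @export
mean_response <- function(trace, time, window = c(1, 10)) {
  if (length(time) == 1L) time <- (seq_along(trace) - 1L) / time
  idx <- frames_in_window(time, window)
  if (!length(idx)) stop("empty window")
  mean(trace[idx], na.rm = TRUE)
}

#' Iso- versus cross-orientation adapted responses
#'
#' For two-epoch trials (10 s adapter at the iso or cross orientation, then a
#' test grating at the iso orientation), computes per cell and per test
#' contrast the mean dF/F over the post-adaptation measurement window
#' (seconds 11-12 by default) separately for iso-adapter and cross-adapter
#' trials, paired per cell. Cells lacking either adapter condition are
#' excluded.
#'
#' @param tensor a `"trial_tensor"` cut over the full two-epoch trial, whose
#'   trial table has `adapter` (`"iso"`/`"cross"`) and `contrast` columns.
#' @param measure_window measurement window in trial time, s.
#' @return data.frame: `cell`, `contrast`, `iso`, `cross` (mean dF/F), and
#'   `difference` (`iso - cross`).
#' @export
iso_cross_adaptation <- function(tensor, measure_window = c(11, 12)) {
  trials <- attr(tensor, "trials")
  if (!all(c("iso", "cross") %in% trials$adapter))
    stop("tensor must contain both iso- and cross-adapter trials")
  tm <- attr(tensor, "time")
  idx <- frames_in_window(tm, measure_window)
  if (!length(idx)) stop("empty measurement window")
  resp <- apply(tensor[, , idx, drop = FALSE], c(1, 2), mean)
  out <- list()
  for (ct in sort(unique(trials$contrast))) {
    iso_j <- which(trials$adapter == "iso" & trials$contrast == ct)
    cross_j <- which(trials$adapter == "cross" & trials$contrast == ct)
    if (!length(iso_j) || !length(cross_j)) next
    iso_v <- rowMeans(resp[, iso_j, drop = FALSE], na.rm = TRUE)
    cross_v <- rowMeans(resp[, cross_j, drop = FALSE], na.rm = TRUE)
    out[[length(out) + 1L]] <-
      data.frame(cell = seq_len(nrow(resp)), contrast = ct,
                 iso = iso_v, cross = cross_v, difference = iso_v - cross_v)
  }
  do.call(rbind, out)
}

#' Suppressed-cell statistics
#'
#' Splits cells by the sign of their average (baseline-subtracted) stimulus
#' response: a negative average marks a suppressed cell. Reports the
#' suppressed fraction, the mean late-window decrease among suppressed cells,
#' and the empirical cumulative distribution of average responses.
#'
#' @param responses cells x trials matrix of baseline-subtracted response
#'   means (see [trial_responses()]).
#' @param tensor the matching `"trial_tensor"`, used for the late window.
#' @param late_window late analysis window, s (8.75-9.75 s for 10 s stimuli).
#' @return list: `avg_response` (per cell), `suppressed` (logical),
#'   `fraction_suppressed`, `late_decrease` (mean late-window value among
#'   suppressed cells), `ecdf` (function).
#' @export
suppressed_cell_stats <- function(responses, tensor,
                                  late_window = c(8.75, 9.75)) {
  avg <- rowMeans(responses, na.rm = TRUE)
  suppressed <- avg < 0
  tm <- attr(tensor, "time")
  idx <- frames_in_window(tm, late_window)
  late <- apply(tensor[, , idx, drop = FALSE], 1L, mean, na.rm = TRUE)
  list(avg_response = avg, suppressed = suppressed,
       fraction_suppressed = mean(suppressed),
       late_decrease = if (any(suppressed)) mean(late[suppressed]) else NA_real_,
       ecdf = stats::ecdf(avg))
}

#' Matched exclusion of initial-condition outliers
#'
#' Ranks the target cells by the absolute deviation of their session-1
#' response from the reference group's mean and removes the top
#' `ceiling(frac * N)`; used to match the initial responses of the
#' grating-relevant group to the grating-irrelevant reference.
#'
#' @param session1_responses numeric vector: per-cell session-1 responses of
#'   the target group.
#' @param reference_mean scalar: mean session-1 response of the reference
#'   (grating-irrelevant) group.
#' @param frac fraction to exclude, in `[0, 1)`.
#' @param ids optional cell identifiers.
#' @return list: `retained` (ids), `excluded` (ids), `ledger` (data.frame
#'   `id`, `response`, `deviation`, `excluded`, ordered by decreasing
#'   deviation).
#' @export
matched_exclusion <- function(session1_responses, reference_mean,
                              frac = 0.10, ids = NULL) {
  if (frac < 0 || frac >= 1) stop("frac must be in [0, 1)")
  n <- length(session1_responses)
  if (is.null(ids)) ids <- seq_len(n)
  dev <- abs(session1_responses - reference_mean)
  n_excl <- ceiling(frac * n)
  o <- order(dev, decreasing = TRUE)
  excluded_idx <- if (n_excl > 0) o[seq_len(n_excl)] else integer()
  ledger <- data.frame(id = ids[o], response = session1_responses[o],
                       deviation = dev[o],
                       excluded = seq_len(n) <= n_excl)
  list(retained = ids[setdiff(seq_len(n), excluded_idx)],
       excluded = ids[excluded_idx], ledger = ledger)
}

#' Split trials of a session into four contiguous quarters
#'
#' Quarters are near-equal by trial order; remainders go to the earliest
#' quarters.
#'
#' @param n number of trials.
#' @return integer vector of quarter labels (1-4), length `n`.
#' @export
quarter_labels <- function(n) {
  stopifnot(n >= 4L)
  base <- n %/% 4L
  extra <- n %% 4L
  sizes <- rep(base, 4L) + (seq_len(4L) <= extra)
  rep(seq_len(4L), times = sizes)
}

#' Exponential fit y = a + b * exp(-t / tau) by profiled least squares
#'
#' `tau` is profiled over a log-spaced grid within `tau_bounds` and refined
#' with [stats::optimize()]; `a` and `b` are solved linearly for each `tau`.
#' If the residual-sum-of-squares profile is flat in `tau` (a constant
#' sequence), the fit is flagged unidentifiable.
#'
#' @param y observed sequence.
#' @param t time/bin index (default `seq_along(y)`).
#' @param tau_bounds allowed range of `tau`, in units of `t`.
#' @return list: `a`, `b`, `tau`, `fitted`, `rss`, `converged`,
#'   `identifiable`.
#' @export
fit_exponential <- function(y, t = seq_along(y), tau_bounds = c(0.1, 100)) {
  stopifnot(length(y) >= 4L, length(y) == length(t))
  solve_tau <- function(tau) {
    X <- cbind(1, exp(-t / tau))
    f <- stats::lm.fit(X, y)
    list(coef = f$coefficients, rss = sum(f$residuals^2))
  }
  grid <- exp(seq(log(tau_bounds[1]), log(tau_bounds[2]), length.out = 40))
  rss_grid <- vapply(grid, function(tau) solve_tau(tau)$rss, numeric(1))
  k <- which.min(rss_grid)
  lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
  opt <- stats::optimize(function(tau) solve_tau(tau)$rss, c(lo, hi))
  tau <- opt$minimum
  sol <- solve_tau(tau)
  flat_rss <- sum((y - mean(y))^2)
  identifiable <- diff(range(rss_grid)) > 1e-10 * max(flat_rss, 1e-12) &&
    flat_rss > 0
  list(a = unname(sol$coef[1]), b = unname(sol$coef[2]), tau = tau,
       fitted = sol$coef[1] + sol$coef[2] * exp(-t / tau),
       rss = sol$rss, converged = TRUE, identifiable = identifiable)
}

#' Session trajectory of a per-trial metric
#'
#' Splits each session's trials (in presentation order) into four contiguous
#' quarters, averages the per-trial metric within each quarter, and fits
#' `y = a + b * exp(-t / tau)` to the concatenated quarter sequence (`t` =
#' quarter-bin index across sessions). Because OLS slopes are linear in the
#' data, the quarter mean of per-trial slopes equals the slope of the
#' quarter-averaged trace.
#'
#' @param values per-trial metric (e.g. per-trial slope or mean response).
#' @param sessions session label per trial.
#' @param order optional within-dataset presentation order (default: input
#'   order).
#' @return list of class `"session_trajectory"`: `bins` (data.frame
#'   `session`, `quarter`, `bin`, `value`, `n_trials`, `sem`), `fit` (see
#'   [fit_exponential()]).
#' @export
session_trajectory <- function(values, sessions, order = seq_along(values)) {
  stopifnot(length(values) == length(sessions))
  o <- base::order(order)
  values <- values[o]; sessions <- sessions[o]
  sess <- unique(sessions)
  rows <- list()
  bin <- 0L
  for (s in sess) {
    v <- values[sessions == s]
    q <- quarter_labels(length(v))
    for (k in 1:4) {
      bin <- bin + 1L
      vk <- v[q == k]
      rows[[bin]] <- data.frame(session = s, quarter = k, bin = bin,
                                value = mean(vk, na.rm = TRUE),
                                n_trials = length(vk), sem = sem(vk))
    }
  }
  bins <- do.call(rbind, rows)
  fit <- fit_exponential(bins$value, bins$bin)
  structure(list(bins = bins, fit = fit), class = "session_trajectory")
}

#' @export
print.session_trajectory <- function(x, ...) {
  cat(sprintf("<session_trajectory> %d sessions x 4 quarters; exp fit a=%.3g b=%.3g tau=%.3g%s\n",
              nrow(x$bins) / 4, x$fit$a, x$fit$b, x$fit$tau,
              if (!x$fit$identifiable) " (tau unidentifiable)" else ""))
  invisible(x)
}
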
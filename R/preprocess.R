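# Preprocessing: trace filtering, the two dF/F variants, spike binning.

#' Sliding block filter (centered moving average)
#'
#' Centered moving average of `width_frames` samples. For even widths the
#' window extends one sample further forward than backward. At the trace
#' edges the window shrinks to the available samples, so the output has the
#' same length as the input. A constant trace is returned unchanged and
#' `width_frames = 1` is the identity.
#'
#' @param trace numeric vector, or a cells x frames matrix (filtered
#'   row-wise), or a [recording()] (filtered in place).
#' @param width_frames filter width in samples (>= 1, <= trace length).
#' @return filtered object of the same shape/class as the input.
#' @export
block_filter <- function(trace, width_frames = 20L) {
  if (inherits(trace, "recording")) {
    trace$values <- block_filter(trace$values, width_frames)
    return(trace)
  }
  if (is.matrix(trace))
    return(t(apply(trace, 1L, block_filter_vec, width_frames)))
  block_filter_vec(trace, width_frames)
}

#' @noRd
block_filter_vec <- function(x, w) {
  n <- length(x)
  w <- as.integer(w)
  if (w < 1L) stop("width_frames must be >= 1")
  if (w > n) stop("width_frames exceeds trace length")
  if (w == 1L) return(x)
  back <- (w - 1L) %/% 2L
  fwd <- w %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - back, 1L)
  hi <- pmin(i + fwd, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Pre-stimulus-baseline dF/F, trial-aligned
#'
#' Cuts the recording around each stimulus onset and converts fluorescence to
#' dF/F with a per-trial baseline: `F0` is the mean fluorescence over
#' `[onset - baseline_s, onset)` and `dF/F = (F - F0) / F0` over the whole cut
#' window. Cell/trial combinations with `F0 <= 0` are excluded (set to `NA`)
#' and listed in the `exclusions` attribute.
#'
#' @param rec a [recording()] of raw fluorescence.
#' @param trials a [trial_table()]; every trial must have at least
#'   `baseline_s` of pre-onset data.
#' @param baseline_s baseline length, s (2 s; 3 s for contrast tuning).
#' @param post_s length of the post-onset cut, s; defaults to the longest
#'   trial duration.
#' @return a `"trial_tensor"` of dF/F values with attributes `method =
#'   "prestim"`, `baseline_s`, and `exclusions` (data.frame `cell`, `trial`).
#' @export
dff_prestim <- function(rec, trials, baseline_s = 2, post_s = NULL) {
  stopifnot(baseline_s > 0)
  tensor <- cut_trials(rec, trials, pre_s = baseline_s, post_s = post_s)
  tm <- attr(tensor, "time")
  base_idx <- frames_in_window(tm, c(-baseline_s, 0))
  if (!length(base_idx)) stop("no frames in the baseline window")
  f0 <- rowMeans(tensor[, , base_idx, drop = FALSE], dims = 2L)
  bad <- which(f0 <= 0, arr.ind = TRUE)
  exclusions <- data.frame(cell = integer(), trial = integer())
  if (nrow(bad)) {
    exclusions <- data.frame(cell = bad[, 1], trial = bad[, 2])
    f0[bad] <- NA_real_
  }
  out <- sweep(sweep(tensor, c(1, 2), f0, "-"), c(1, 2), f0, "/")
  attributes(out) <- attributes(tensor)
  attr(out, "method") <- "prestim"
  attr(out, "baseline_s") <- baseline_s
  attr(out, "exclusions") <- exclusions
  out
}

#' Rolling-percentile dF/F
#'
#' For each frame, the 8th-percentile of the fluorescence distribution in a
#' +/- `half_window_s` window (truncated at the trace edges) is subtracted
#' from the raw signal, which is then divided by the median of the cell's
#' full-trace raw fluorescence. Output is invariant to multiplicative
#' rescaling of the raw trace.
#'
#' @param rec a [recording()] of raw fluorescence.
#' @param half_window_s window half-length, s.
#' @param percentile baseline percentile, as a fraction.
#' @return a [recording()] with additional class `"dff_matrix"` and
#'   attributes `method = "rolling_percentile"` and `params`. Cells whose
#'   full-trace median is not positive raise an error.
#' @export
dff_rolling_percentile <- function(rec, half_window_s = 15,
                                   percentile = 0.08) {
  stopifnot(inherits(rec, "recording"), half_window_s > 0,
            percentile >= 0, percentile <= 1)
  n_frames <- ncol(rec$values)
  halfwin <- round(half_window_s * rec$frame_rate)
  if (halfwin >= n_frames) stop("recording shorter than half_window_s")
  med <- apply(rec$values, 1L, stats::median)
  if (any(med <= 0))
    stop("cells with non-positive median fluorescence: ",
         paste(which(med <= 0), collapse = ", "))
  out <- rec$values
  for (i in seq_len(nrow(out))) {
    base <- roll_quantile_cpp(rec$values[i, ], halfwin, percentile)
    out[i, ] <- (rec$values[i, ] - base) / med[i]
  }
  res <- rec
  res$values <- out
  class(res) <- c("dff_matrix", "recording")
  attr(res, "method") <- "rolling_percentile"
  attr(res, "params") <- list(half_window_s = half_window_s,
                              percentile = percentile)
  res
}

#' Bin spike times into firing rates
#'
#' Half-open, contiguous, uniform bins `[left, right)` from `window[1]`; only
#' complete bins are kept. Rates are counts divided by the bin width, so
#' `sum(rate) * bin_s` equals the number of spikes inside the binned range.
#'
#' @param spike_times spike times, s (empty input allowed; ordering
#'   irrelevant).
#' @param window interval `c(left, right)` to bin over, s.
#' @param bin_s bin width, s (default 1/3 s).
#' @return list of class `"binned_rates"`: `rate` (spikes/s per bin),
#'   `counts`, `bin_left`, `bin_right`, `bin_s`.
#' @export
bin_spikes <- function(spike_times, window = c(0, 7), bin_s = 1 / 3) {
  stopifnot(bin_s > 0, length(window) == 2L, window[2] > window[1])
  n_bins <- floor((window[2] - window[1]) / bin_s + .time_eps)
  if (n_bins < 1L) stop("window shorter than one bin")
  left <- window[1] + (seq_len(n_bins) - 1L) * bin_s
  t <- spike_times[spike_times >= window[1] - .time_eps &
                     spike_times < window[1] + n_bins * bin_s - .time_eps]
  counts <- tabulate(floor((t - window[1]) / bin_s + .time_eps) + 1L, n_bins)
  structure(list(rate = counts / bin_s, counts = counts,
                 bin_left = left, bin_right = left + bin_s, bin_s = bin_s),
            class = "binned_rates")
}
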
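# Synthetic-data generator: imaging-style datasets with ground-truth
# adaptation parameters, for end-to-end validation of the pipeline.

#' Double-Gaussian direction tuning gain
#'
#' Direction tuning profile used by the generator: two Gaussian lobes in
#' wrapped angular distance, forced to peak 180 degrees apart with a common
#' width. Peak gain at the preferred direction is 1.
#'
#' @param direction stimulus direction(s), degrees.
#' @param pref preferred direction, degrees.
#' @param width common Gaussian width (sigma), degrees.
#' @param null_ratio amplitude of the null (opposite-direction) lobe relative
#'   to the preferred lobe, in `[0, 1]`.
#' @return numeric gain(s) in `[0, 1 + null_ratio]`.
#' @export
tuning_gain <- function(direction, pref, width, null_ratio = 0.3) {
  d1 <- dir_dist_deg(direction, pref)
  d2 <- dir_dist_deg(direction, pref + 180)
  exp(-d1^2 / (2 * width^2)) + null_ratio * exp(-d2^2 / (2 * width^2))
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic generators. The seed fixes all
#' randomness: two calls to a generator with identical configs give
#' bit-identical datasets.
#'
#' Default population parameters are free choices (response amplitudes and
#' noise levels are not constrained by published group statistics): baseline
#' fluorescence 1 a.u., peak stimulus response 0.4 dF/F with 0.15 spread,
#' tuning widths 25-40 degrees, frame-wise Gaussian noise SD 0.1, GCaMP-like
#' indicator time constant 0.6 s.
#'
#' @param n_cells number of cells.
#' @param frame_rate imaging frame rate, Hz.
#' @param trial_plan a [trial_table()] listing every stimulus event.
#' @param noise_sd frame-wise additive Gaussian noise SD (fluorescence a.u.).
#' @param calcium_tau indicator decay time constant, seconds; 0 disables the
#'   kernel convolution.
#' @param drift_amplitude amplitude of the slow sinusoidal drift (a.u.).
#' @param drift_period_s period of the drift, seconds.
#' @param seed integer seed.
#' @param baseline_f baseline fluorescence (a.u., > 0).
#' @param amplitude_mean,amplitude_sd population mean/SD of the peak response
#'   amplitude (dF/F units; amplitudes are truncated at 0.05).
#' @param tuning_width_range range of tuning widths (sigma, degrees).
#' @param null_ratio_range range of null-lobe relative amplitudes.
#' @param suppressed_frac fraction of cells with negative stimulus amplitude
#'   on the positive baseline (suppressed cells).
#' @param pv_frac fraction of PV cells.
#' @param slope_by_condition named numeric vector: per-condition adaptation
#'   slope in (fraction of response)/s; must cover every condition used by
#'   `trial_plan`.
#' @param slope_sd per-cell SD of the adaptation slope around its condition
#'   mean.
#' @param adaptation_mode `"linear"` (gain `1 + slope * t`, the default,
#'   matching a fitted-line readout) or `"exponential"` (gain
#'   `exp(slope * t)`).
#' @param iso_direction direction of the iso orientation, degrees.
#' @param iso_adapt_factor extra multiplicative factor applied to test-epoch
#'   responses after an iso-orientation adapter (1 = no orientation-specific
#'   adaptation; < 1 = iso adapts more).
#' @param state behavioral state label stored on the recording.
#' @param behavior list of behavior-generator parameters, see
#'   [behavior_config()].
#' @param spikes list of spike-generator parameters, see [spike_params()].
#'
#' @return A list of class `"simulation_config"`.
#' @export
simulation_config <- function(n_cells, frame_rate = 10, trial_plan,
                              noise_sd = 0.1, calcium_tau = 0.6,
                              drift_amplitude = 0.05, drift_period_s = 120,
                              seed = 1,
                              baseline_f = 1,
                              amplitude_mean = 0.4, amplitude_sd = 0.15,
                              tuning_width_range = c(25, 40),
                              null_ratio_range = c(0.1, 0.5),
                              suppressed_frac = 0, pv_frac = 0,
                              slope_by_condition = c(default = 0),
                              slope_sd = 0,
                              adaptation_mode = c("linear", "exponential"),
                              iso_direction = 0, iso_adapt_factor = 1,
                              state = "awake",
                              behavior = behavior_config(),
                              spikes = spike_params()) {
  adaptation_mode <- match.arg(adaptation_mode)
  if (!inherits(trial_plan, "trial_table") || nrow(trial_plan) == 0L)
    stop("trial_plan must be a non-empty trial_table")
  stopifnot(n_cells >= 1, frame_rate > 0, calcium_tau >= 0, baseline_f > 0)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  conds <- unique(trial_plan$condition)
  missing_conds <- setdiff(conds, names(slope_by_condition))
  if (length(missing_conds))
    stop("slope_by_condition lacks conditions: ",
         paste(missing_conds, collapse = ", "))
  structure(
    list(n_cells = as.integer(n_cells), frame_rate = frame_rate,
         trial_plan = trial_plan, noise_sd = noise_sd,
         calcium_tau = calcium_tau, drift_amplitude = drift_amplitude,
         drift_period_s = drift_period_s, seed = as.integer(seed),
         baseline_f = baseline_f, amplitude_mean = amplitude_mean,
         amplitude_sd = amplitude_sd, tuning_width_range = tuning_width_range,
         null_ratio_range = null_ratio_range,
         suppressed_frac = suppressed_frac, pv_frac = pv_frac,
         slope_by_condition = slope_by_condition, slope_sd = slope_sd,
         adaptation_mode = adaptation_mode, iso_direction = iso_direction,
         iso_adapt_factor = iso_adapt_factor, state = state,
         behavior = behavior, spikes = spikes),
    class = "simulation_config")
}

#' Sample the ground-truth cell population for a config
#'
#' @param config a [simulation_config()].
#' @return data.frame of class `"ground_truth"`: one row per cell with
#'   `cell_id`, `pref_direction`, `tuning_width`, `null_ratio`, `amplitude`
#'   (signed: negative for suppressed cells), `baseline`, `suppressed`,
#'   `cell_class`, and one `slope_<condition>` column per condition.
#' @keywords internal
#' @export
sample_ground_truth <- function(config) {
  n <- config$n_cells
  pref <- stats::runif(n, 0, 360)
  width <- stats::runif(n, config$tuning_width_range[1],
                        config$tuning_width_range[2])
  null_ratio <- stats::runif(n, config$null_ratio_range[1],
                             config$null_ratio_range[2])
  amp <- pmax(stats::rnorm(n, config$amplitude_mean, config$amplitude_sd),
              0.05)
  suppressed <- stats::runif(n) < config$suppressed_frac
  amp[suppressed] <- -amp[suppressed]
  cell_class <- ifelse(stats::runif(n) < config$pv_frac,
                       "PV", "putative_excitatory")
  truth <- data.frame(cell_id = paste0("cell_", seq_len(n)),
                      pref_direction = pref, tuning_width = width,
                      null_ratio = null_ratio,
                      amplitude = amp * config$baseline_f,
                      baseline = config$baseline_f,
                      suppressed = suppressed, cell_class = cell_class,
                      stringsAsFactors = FALSE)
  for (cond in names(config$slope_by_condition)) {
    truth[[paste0("slope_", cond)]] <-
      config$slope_by_condition[[cond]] + stats::rnorm(n, 0, config$slope_sd)
  }
  class(truth) <- c("ground_truth", "data.frame")
  truth
}

#' Within-trial adaptation gain
#' @noRd
adapt_gain <- function(t_rel, slope, mode) {
  if (mode == "linear") 1 + slope * t_rel else exp(slope * t_rel)
}

#' Deterministic (noise-free, unconvolved) fluorescence trace of one cell
#' @noRd
cell_clean_trace <- function(truth_row, config, time) {
  plan <- config$trial_plan
  f <- rep(truth_row$baseline, length(time))
  for (j in seq_len(nrow(plan))) {
    onset <- plan$onset[j]
    dur <- plan$duration[j]
    slope <- truth_row[[paste0("slope_", plan$condition[j])]]
    idx <- frames_in_window(time, c(onset, onset + dur))
    if (!length(idx)) next
    t_rel <- time[idx] - onset
    if (!is.na(plan$adapter[j])) {
      # two-epoch trial: adapter grating for the first half, test grating at
      # the iso direction for the second; adaptation carries across epochs
      half <- dur / 2
      adapter_dir <- if (plan$adapter[j] == "iso") config$iso_direction
                     else config$iso_direction + 90
      in1 <- t_rel < half - .time_eps
      g1 <- tuning_gain(adapter_dir, truth_row$pref_direction,
                        truth_row$tuning_width, truth_row$null_ratio)
      g2 <- tuning_gain(plan$direction[j], truth_row$pref_direction,
                        truth_row$tuning_width, truth_row$null_ratio)
      sig <- numeric(length(t_rel))
      sig[in1] <- truth_row$amplitude * g1 * 0.5 *
        adapt_gain(t_rel[in1], slope, config$adaptation_mode)
      iso_fac <- if (plan$adapter[j] == "iso") config$iso_adapt_factor else 1
      sig[!in1] <- truth_row$amplitude * g2 * (plan$contrast[j] / 100) *
        iso_fac * adapt_gain(t_rel[!in1], slope, config$adaptation_mode)
      f[idx] <- f[idx] + sig
    } else {
      g <- tuning_gain(plan$direction[j], truth_row$pref_direction,
                       truth_row$tuning_width, truth_row$null_ratio)
      f[idx] <- f[idx] + truth_row$amplitude * g * (plan$contrast[j] / 100) *
        adapt_gain(t_rel, slope, config$adaptation_mode)
    }
  }
  # rate clipped at zero: the generator's only nonlinearity
  pmax(f, 0)
}

#' Causal exponential (indicator) filter with unit DC gain
#' @noRd
calcium_filter <- function(x, tau, frame_rate) {
  if (tau <= 0) return(x)
  a <- exp(-1 / (frame_rate * tau))
  as.numeric(stats::filter((1 - a) * x, a, method = "recursive",
                           init = x[1]))
}

#' Simulate an imaging-style dataset
#'
#' Generates per-cell fluorescence traces: baseline plus a direction-tuned
#' response (double Gaussian, lobes 180 degrees apart, equal width) scaled by
#' a per-condition within-trial adaptation gain (`1 + slope * t` by default),
#' clipped at zero, convolved with an exponential indicator kernel, with
#' additive Gaussian noise and a slow sinusoidal drift. Also generates a
#' matching behavior trace and returns the ground-truth cell table.
#'
#' @param config a [simulation_config()].
#' @return A list of class `"generated_dataset"`: `recording` ([recording()]),
#'   `trials` (the trial plan), `behavior` (a `"behavior_trace"`), `truth`
#'   (the `"ground_truth"` table), `config`.
#' @export
simulate_imaging_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  plan <- config$trial_plan
  fr <- config$frame_rate
  t_end <- max(plan$onset + plan$duration) + 10
  time <- seq(0, t_end, by = 1 / fr)
  rec_values <- with_seed(config$seed, {
    truth <- sample_ground_truth(config)
    n <- config$n_cells
    phases <- stats::runif(n, 0, 2 * pi)
    vals <- matrix(NA_real_, n, length(time))
    for (i in seq_len(n)) {
      clean <- cell_clean_trace(truth[i, , drop = FALSE], config, time)
      clean <- calcium_filter(clean, config$calcium_tau, fr)
      drift <- config$drift_amplitude *
        sin(2 * pi * time / config$drift_period_s + phases[i])
      noise <- if (config$noise_sd > 0)
        stats::rnorm(length(time), 0, config$noise_sd) else 0
      vals[i, ] <- clean + drift + noise
    }
    list(truth = truth, vals = vals)
  })
  truth <- rec_values$truth
  rec <- recording(rec_values$vals, fr, cell_class = truth$cell_class,
                   state = config$state, cell_ids = truth$cell_id)
  behavior <- simulate_behavior(config)
  structure(list(recording = rec, trials = plan, behavior = behavior,
                 truth = truth, config = config),
            class = "generated_dataset")
}

#' @export
print.generated_dataset <- function(x, ...) {
  cat(sprintf("<generated_dataset> %d cells, %d trials, %d conditions, seed %d\n",
              nrow(x$truth), nrow(x$trials),
              length(unique(x$trials$condition)), x$config$seed))
  invisible(x)
}
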
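# Synthetic spike-train generator for the optogenetic silencing experiment:
# three stimulus conditions (adapted / control / LED+adapted), PV cells driven
# by the LED, putative excitatory cells silenced by it, and adaptation applied
# only to accumulated stimulus-driven activity.

#' Spike-generator parameters
#'
#' The adaptation model: within a trial, the stimulus-driven rate is scaled by
#' a gain that decreases linearly with the *accumulated* stimulus-driven
#' drive, down to a floor (the configured adaptation factor) reached after
#' `accum_ref_s` seconds of full drive. Because accumulation tracks the
#' effective (post-silencing) drive, optogenetic silencing during the first
#' half of the stimulus leaves the cell unadapted when the LED turns off.
#'
#' @param base_rate spontaneous rate, spikes/s.
#' @param stim_drive peak stimulus-driven rate at the preferred direction,
#'   spikes/s.
#' @param adapt_floor adapted/unadapted rate ratio reached after full
#'   accumulation (putative excitatory cells).
#' @param pv_adapt_floor same, for PV cells (close to 1: PV cells adapt less).
#' @param accum_ref_s seconds of full drive needed to reach the floor.
#' @param led_gain LED-driven rate added to PV cells at full LED intensity,
#'   spikes/s.
#' @param silencing_factor fraction of stimulus drive remaining in putative
#'   excitatory cells at full LED intensity (0 = complete silencing).
#' @param led_main_s duration of constant full-intensity LED, s.
#' @param led_ramp_s ramp at LED offset: intensity drops to 50% then decreases
#'   linearly to zero over this time.
#' @param dt time step of the rate grid used for Poisson draws, s.
#' @return list of class `"spike_params"`.
#' @export
spike_params <- function(base_rate = 2, stim_drive = 20,
                         adapt_floor = 0.5, pv_adapt_floor = 0.9,
                         accum_ref_s = 3.5,
                         led_gain = 30, silencing_factor = 0,
                         led_main_s = 3.5, led_ramp_s = 0.5,
                         dt = 0.002) {
  stopifnot(adapt_floor >= 0, adapt_floor <= 1, silencing_factor >= 0,
            silencing_factor <= 1, dt > 0)
  structure(as.list(environment()), class = "spike_params")
}

#' LED intensity profile at trial time t (1 = full)
#' @noRd
led_intensity <- function(t, sp) {
  l <- numeric(length(t))
  main <- t >= 0 & t < sp$led_main_s
  l[main] <- 1
  ramp <- t >= sp$led_main_s & t < sp$led_main_s + sp$led_ramp_s
  l[ramp] <- 0.5 * (1 - (t[ramp] - sp$led_main_s) / sp$led_ramp_s)
  l
}

#' Time at which the LED is completely off
#'
#' @param sp a [spike_params()].
#' @return seconds after stimulus onset (end of the offset ramp).
#' @export
led_off_time <- function(sp) sp$led_main_s + sp$led_ramp_s

#' Deterministic firing-rate profile of one cell for one trial
#'
#' The closed-form rate the Poisson spike generator draws from; exported so
#' that generated spike counts can be checked against the exact rate.
#'
#' @param truth_row one row of a `"ground_truth"` table.
#' @param trial_row one row of the trial plan (fields `condition`,
#'   `direction`, `duration`, `led`).
#' @param config a [simulation_config()].
#' @param t trial times (s, 0 at stimulus-block onset).
#' @return rate in spikes/s at each `t`.
#' @export
spike_rate_profile <- function(truth_row, trial_row, config, t) {
  sp <- config$spikes
  is_pv <- truth_row$cell_class == "PV"
  gain <- tuning_gain(trial_row$direction, truth_row$pref_direction,
                      truth_row$tuning_width, truth_row$null_ratio)
  d_full <- sp$stim_drive * gain
  dur <- trial_row$duration
  # stimulus epochs: control = grey for the first half, grating after
  stim_on <- if (trial_row$condition == "control")
    t >= dur / 2 & t < dur else t >= 0 & t < dur
  drive <- ifelse(stim_on, d_full, 0)
  led <- if (isTRUE(trial_row$led)) led_intensity(t, sp) else numeric(length(t))
  drive_eff <- if (is_pv) drive
               else drive * (1 - (1 - sp$silencing_factor) * led)
  # accumulated stimulus-driven activity -> linear adaptation gain with floor
  dt_step <- c(0, diff(t))
  accum <- cumsum(drive_eff * dt_step)
  floor_val <- if (is_pv) sp$pv_adapt_floor else sp$adapt_floor
  a_ref <- d_full * sp$accum_ref_s
  a <- if (a_ref > 0)
    pmax(floor_val, 1 - (1 - floor_val) * accum / a_ref) else rep(1, length(t))
  rate <- sp$base_rate + drive_eff * a + if (is_pv) sp$led_gain * led else 0
  pmax(rate, 0)
}

#' Simulate a spike dataset for the optogenetic silencing experiment
#'
#' Spike times are drawn from an inhomogeneous Poisson process with the
#' deterministic rate of [spike_rate_profile()]. PV cells increase their rate
#' under the LED; putative excitatory cells are silenced towards
#' `silencing_factor`. Adaptation accumulates only with effective
#' stimulus-driven activity, so the LED+adapted condition yields unadapted
#' responses after LED offset.
#'
#' @param config a [simulation_config()] whose trial plan contains the three
#'   conditions `adapted`, `control` and `led_adapted`, with `led = TRUE` on
#'   LED trials.
#' @return list of class `"spike_dataset"`: `spikes` (data.frame `cell_id`,
#'   `trial`, `condition`, `spike_time` — trial-relative seconds), `trials`,
#'   `truth`, `config`.
#' @export
simulate_spike_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  plan <- config$trial_plan
  need <- c("adapted", "control", "led_adapted")
  if (!all(need %in% plan$condition))
    stop("trial plan must contain conditions: ", paste(need, collapse = ", "))
  if (!any(plan$led[plan$condition == "led_adapted"]))
    stop("led_adapted trials must carry LED metadata (led = TRUE)")
  sp <- config$spikes
  with_seed(config$seed, {
    truth <- sample_ground_truth(config)
    out <- vector("list", config$n_cells * nrow(plan))
    k <- 0L
    for (i in seq_len(config$n_cells)) {
      tr_row <- truth[i, , drop = FALSE]
      for (j in seq_len(nrow(plan))) {
        dur <- plan$duration[j]
        t_grid <- seq(0, dur, by = sp$dt)
        t_grid <- t_grid[-length(t_grid)]
        rate <- spike_rate_profile(tr_row, plan[j, , drop = FALSE],
                                   config, t_grid)
        counts <- stats::rpois(length(t_grid), rate * sp$dt)
        n_sp <- sum(counts)
        if (n_sp == 0) next
        st <- rep(t_grid, counts) + stats::runif(n_sp, 0, sp$dt)
        k <- k + 1L
        out[[k]] <- data.frame(cell_id = tr_row$cell_id, trial = plan$trial[j],
                               condition = plan$condition[j],
                               spike_time = sort(st),
                               stringsAsFactors = FALSE)
      }
    }
    spikes <- if (k > 0) do.call(rbind, out[seq_len(k)]) else
      data.frame(cell_id = character(), trial = integer(),
                 condition = character(), spike_time = numeric())
    structure(list(spikes = spikes, trials = plan, truth = truth,
                   config = config),
              class = "spike_dataset")
  })
}

#' @export
print.spike_dataset <- function(x, ...) {
  cat(sprintf("<spike_dataset> %d cells, %d trials, %d spikes\n",
              nrow(x$truth), nrow(x$trials), nrow(x$spikes)))
  invisible(x)
}
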
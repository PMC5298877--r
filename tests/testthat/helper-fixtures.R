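# Shared fixtures: small synthetic datasets and hand-built containers.

# Small state-experiment dataset (awake/anesthetized).
quick_state_config <- function(seed = 1, n_cells = 25,
                               slopes = c(awake = 0.01, anesthetized = -0.05),
                               n_adapt = 8, noise_sd = 0.1, ...) {
  simulation_config(
    n_cells = n_cells,
    trial_plan = state_trial_plan(n_adapt_per_state = n_adapt),
    slope_by_condition = slopes, noise_sd = noise_sd, seed = seed, ...)
}

# Noise-free, indicator-free config: traces are the exact generative form.
clean_config <- function(seed = 1, n_cells = 5, ...) {
  quick_state_config(seed = seed, n_cells = n_cells, noise_sd = 0,
                     calcium_tau = 0, drift_amplitude = 0, ...)
}

# Minimal recording with known values.
toy_recording <- function(values, frame_rate = 10, ...) {
  recording(values, frame_rate, ...)
}

# Hand-built spike dataset for boundary tests: `spike_list` is a list of
# per-trial spike-time vectors per cell id.
manual_spike_dataset <- function(spike_list, plan, cell_class = NULL,
                                 sp = spike_params()) {
  rows <- list()
  for (cl in names(spike_list)) {
    for (j in seq_along(spike_list[[cl]])) {
      st <- spike_list[[cl]][[j]]
      if (!length(st)) next
      rows[[length(rows) + 1L]] <-
        data.frame(cell_id = cl, trial = plan$trial[j],
                   condition = plan$condition[j], spike_time = st)
    }
  }
  spikes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_id = character(), trial = integer(),
               condition = character(), spike_time = numeric())
  if (is.null(cell_class))
    cell_class <- rep("putative_excitatory", length(spike_list))
  truth <- data.frame(cell_id = names(spike_list), cell_class = cell_class)
  structure(list(spikes = spikes, trials = plan, truth = truth,
                 config = list(spikes = sp)),
            class = "spike_dataset")
}

# Brute-force moving-average oracle (explicit window loop).
oracle_block_filter <- function(x, w) {
  n <- length(x)
  back <- (w - 1) %/% 2
  fwd <- w %/% 2
  vapply(seq_len(n), function(i) {
    win <- max(1, i - back):min(n, i + fwd)
    mean(x[win])
  }, numeric(1))
}

# Exhaustive signed-rank p-value (all 2^n sign assignments of |d| ranks).
oracle_signed_rank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mean(abs(v_all - n * (n + 1) / 4) >= abs(v_obs - n * (n + 1) / 4) - 1e-9)
}

# Exhaustive rank-sum p-value (all choose(n, na) group assignments).
oracle_rank_sum_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n_a)])
  combos <- utils::combn(length(pooled), n_a)
  w_all <- apply(combos, 2L, function(idx) sum(r[idx]))
  mu <- n_a * (length(pooled) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}
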
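# Direction tuning: constrained double-Gaussian fits, iso/cross and
# horizontal classification, Z-score responsiveness rules.

#' Per-trial response amplitudes
#'
#' Mean dF/F over the response window for each cell and trial, optionally
#' with the mean over a pre-stimulus baseline window subtracted.
#'
#' @param tensor a `"trial_tensor"` (see [cut_trials()], [dff_prestim()]).
#' @param window response window `c(left, right)` in trial time, s.
#' @param baseline_window optional baseline window to subtract, s.
#' @return numeric matrix, cells x trials.
#' @export
trial_responses <- function(tensor, window, baseline_window = NULL) {
  tm <- attr(tensor, "time")
  idx <- frames_in_window(tm, window)
  if (!length(idx)) stop("empty response window")
  resp <- rowMeans(tensor[, , idx, drop = FALSE], dims = 2L)
  if (!is.null(baseline_window)) {
    bidx <- frames_in_window(tm, baseline_window)
    if (!length(bidx)) stop("empty baseline window")
    resp <- resp - rowMeans(tensor[, , bidx, drop = FALSE], dims = 2L)
  }
  resp
}

#' Average a response matrix into a tuning curve
#'
#' @param responses per-trial responses for one cell (numeric vector) or a
#'   cells x trials matrix.
#' @param directions stimulus direction per trial, degrees.
#' @return named vector (or cells x directions matrix) of mean responses per
#'   unique direction, directions sorted increasingly.
#' @export
tuning_curve <- function(responses, directions) {
  dirs <- sort(unique(wrap_deg(directions)))
  if (is.matrix(responses)) {
    out <- vapply(dirs, function(d)
      rowMeans(responses[, wrap_deg(directions) == d, drop = FALSE]),
      numeric(nrow(responses)))
    colnames(out) <- dirs
    return(out)
  }
  vapply(dirs, function(d) mean(responses[wrap_deg(directions) == d]),
         numeric(1)) |> stats::setNames(dirs)
}

# sigma bounds for the tuning fit (degrees)
.sigma_lo <- 2
.sigma_hi <- 120

#' @noRd
sigma_from_par <- function(s) .sigma_lo + (.sigma_hi - .sigma_lo) * stats::plogis(s)

#' @noRd
par_from_sigma <- function(sigma) stats::qlogis((sigma - .sigma_lo) / (.sigma_hi - .sigma_lo))

# Linear (variable-projection) solve of offset/amplitudes given (theta_p,
# sigma); returns coefficients and RSS.
#' @noRd
tuning_linear_solve <- function(theta_p, sigma, directions, y) {
  inv2 <- 1 / (2 * sigma^2)
  d1 <- abs(directions - theta_p) %% 360
  d1 <- pmin(d1, 360 - d1)
  d2 <- abs(directions - theta_p - 180) %% 360
  d2 <- pmin(d2, 360 - d2)
  X <- cbind(1, exp(-d1 * d1 * inv2), exp(-d2 * d2 * inv2))
  co <- tryCatch(solve(crossprod(X), crossprod(X, y)),
                 error = function(e) qr.coef(qr(X), y))
  co[is.na(co)] <- 0
  r <- y - X %*% co
  list(coef = as.numeric(co), rss = sum(r * r))
}

#' Fit a constrained double-Gaussian direction-tuning curve
#'
#' Least-squares fit of
#' `R(theta) = offset + amp_pref * G(theta; theta_p, sigma) + amp_null *
#' G(theta; theta_p + 180, sigma)`, where `G` is a Gaussian in wrapped
#' angular distance: the two lobes are forced to peak 180 degrees apart and
#' share one width. The nonlinear parameters `(theta_p, sigma)` are optimized
#' by Nelder-Mead with the linear parameters profiled out exactly, restarted
#' from each measured direction; the best-RSS fit wins, ties broken by the
#' smaller preferred direction. The fitted peak is relabeled so that
#' `amp_pref >= amp_null` and `theta_p` is reported in `[0, 360)`.
#'
#' @param mean_response_by_direction mean response per direction.
#' @param directions the measured directions, degrees (>= 5 distinct; 8 in
#'   the standard protocols).
#' @param sigma_init initial tuning width, degrees.
#' @return list of class `"tuning_fit"`: `pref_direction`, `width_sigma`,
#'   `amp_pref`, `amp_null`, `offset`, `rss`, `flat` (degenerate flat input:
#'   amplitudes 0, `pref_direction` `NA`), `converged`.
#' @export
fit_direction_tuning <- function(mean_response_by_direction, directions,
                                 sigma_init = 30) {
  y <- as.numeric(mean_response_by_direction)
  directions <- wrap_deg(directions)
  stopifnot(length(y) == length(directions))
  if (length(unique(directions)) < 5L)
    stop("need at least 5 distinct directions")
  flat_rss <- sum((y - mean(y))^2)
  if (flat_rss < 1e-20 * max(1, mean(y)^2)) {
    return(structure(list(pref_direction = NA_real_, width_sigma = NA_real_,
                          amp_pref = 0, amp_null = 0, offset = mean(y),
                          rss = flat_rss, flat = TRUE, converged = TRUE),
                     class = "tuning_fit"))
  }
  obj <- function(par) {
    tuning_rss_cpp(par[1], sigma_from_par(par[2]), directions, y)
  }
  best <- NULL
  for (th0 in directions) {
    opt <- stats::optim(c(th0, par_from_sigma(sigma_init)), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 200, reltol = 1e-9))
    cand <- list(par = opt$par, rss = opt$value,
                 converged = opt$convergence == 0L)
    if (is.null(best) || cand$rss < best$rss - 1e-12 ||
        (abs(cand$rss - best$rss) <= 1e-12 &&
         wrap_deg(cand$par[1]) < wrap_deg(best$par[1])))
      best <- cand
  }
  theta <- wrap_deg(best$par[1])
  sigma <- sigma_from_par(best$par[2])
  sol <- tuning_linear_solve(theta, sigma, directions, y)
  co <- sol$coef
  amp_pref <- co[2]; amp_null <- co[3]
  if (amp_null > amp_pref) {
    theta <- wrap_deg(theta + 180)
    tmp <- amp_pref; amp_pref <- amp_null; amp_null <- tmp
  }
  structure(list(pref_direction = theta, width_sigma = sigma,
                 amp_pref = unname(amp_pref), amp_null = unname(amp_null),
                 offset = unname(co[1]), rss = sol$rss, flat = FALSE,
                 converged = best$converged),
            class = "tuning_fit")
}

#' @export
print.tuning_fit <- function(x, ...) {
  if (x$flat) cat("<tuning_fit> flat (untuned)\n")
  else cat(sprintf(
    "<tuning_fit> pref %.1f deg, sigma %.1f deg, amps %.3g/%.3g, rss %.3g\n",
    x$pref_direction, x$width_sigma, x$amp_pref, x$amp_null, x$rss))
  invisible(x)
}

#' Predict a fitted tuning curve
#' @param fit a `"tuning_fit"`.
#' @param directions directions to evaluate, degrees.
#' @return predicted responses.
#' @export
predict_tuning <- function(fit, directions) {
  if (fit$flat) return(rep(fit$offset, length(directions)))
  fit$offset +
    fit$amp_pref * exp(-dir_dist_deg(directions, fit$pref_direction)^2 /
                         (2 * fit$width_sigma^2)) +
    fit$amp_null * exp(-dir_dist_deg(directions, fit$pref_direction + 180)^2 /
                         (2 * fit$width_sigma^2))
}

#' Classify a cell as iso- or cross-tuned
#'
#' The class is decided by the smaller wrapped orientation distance (mod 180
#' degrees) between the fitted peak and the iso orientation; an exact tie at
#' 45 degrees is broken toward iso.
#'
#' @param fit a `"tuning_fit"`.
#' @param iso_direction the iso orientation, degrees.
#' @return `"iso"`, `"cross"`, or `NA` for flat (unclassifiable) fits.
#' @export
assign_adaptation_class <- function(fit, iso_direction) {
  if (isTRUE(fit$flat) || is.na(fit$pref_direction)) return(NA_character_)
  if (ori_dist_deg(fit$pref_direction, iso_direction) <= 45) "iso" else "cross"
}

#' Is a cell tuned to the horizontal grating?
#'
#' TRUE iff the wrapped orientation distance (mod 180 degrees) between the
#' fitted peak and horizontal is at most 45 degrees (inclusive). Flat cells
#' are not tuned.
#'
#' @param fit a `"tuning_fit"`.
#' @param horizontal direction of the horizontal grating, degrees.
#' @return logical flag.
#' @export
classify_horizontal_tuned <- function(fit, horizontal = 0) {
  if (isTRUE(fit$flat) || is.na(fit$pref_direction)) return(FALSE)
  ori_dist_deg(fit$pref_direction, horizontal) <= 45
}

#' Trial-wise Z-score responsiveness
#'
#' Per trial, `Z = (mean response - mean baseline) / SD of baseline-window
#' frames`; a cell is responsive iff the fraction of trials with
#' `Z > threshold` is at least `min_frac` (inclusive). The default threshold
#' 2.58 is the two-sided standard-normal critical value for p < 0.01.
#' Trials with zero baseline SD are excluded with a warning.
#'
#' @param tensor a `"trial_tensor"` of dF/F values.
#' @param baseline_window,response_window windows in trial time, s.
#' @param trials optional trial indices to use (e.g. the preferred-direction
#'   trials); default all.
#' @param threshold Z threshold.
#' @param min_frac minimum fraction of supra-threshold trials.
#' @return list of class `"responsiveness"`: `z` (cells x used trials),
#'   `responsive` (logical per cell), `frac` (fraction of supra-threshold
#'   trials), `rule = "trialwise"`, plus the thresholds.
#' @export
classify_responsive_trialwise <- function(tensor,
                                          baseline_window = c(-2, 0),
                                          response_window = c(0, 2),
                                          trials = NULL,
                                          threshold = 2.58, min_frac = 0.5) {
  tm <- attr(tensor, "time")
  if (is.null(trials)) trials <- seq_len(dim(tensor)[2])
  if (length(trials) < 4L) stop("need at least 4 trials")
  bidx <- frames_in_window(tm, baseline_window)
  ridx <- frames_in_window(tm, response_window)
  if (!length(bidx) || !length(ridx)) stop("empty analysis window")
  sub <- tensor[, trials, , drop = FALSE]
  base_mean <- apply(sub[, , bidx, drop = FALSE], c(1, 2), mean)
  base_sd <- apply(sub[, , bidx, drop = FALSE], c(1, 2), stats::sd)
  resp_mean <- apply(sub[, , ridx, drop = FALSE], c(1, 2), mean)
  zero_sd <- is.finite(base_sd) & base_sd == 0
  if (any(zero_sd)) {
    warning(sum(zero_sd), " cell/trial(s) with zero baseline SD excluded")
    base_sd[zero_sd] <- NA_real_
  }
  z <- (resp_mean - base_mean) / base_sd
  frac <- rowMeans(z > threshold, na.rm = TRUE)
  frac[rowSums(is.finite(z)) == 0] <- NA_real_
  structure(list(z = z, responsive = !is.na(frac) & frac >= min_frac,
                 frac = frac, rule = "trialwise", threshold = threshold,
                 min_frac = min_frac),
            class = "responsiveness")
}

#' Session-wise Z-score responsiveness
#'
#' Per session, the session-mean response is tested against the session's
#' baseline distribution: `Z = (mean response - mean of per-trial baseline
#' means) / (SD of per-trial baseline means / sqrt(n_trials))`. A cell is
#' responsive iff `|Z| > threshold` in at least `min_frac` of the usable
#' sessions (two-sided, so suppressed cells qualify). The default threshold
#' 3.29 is the two-sided standard-normal critical value for p < 0.001.
#' Sessions with fewer than `min_trials` trials are excluded.
#'
#' @param responses cells x trials matrix of response-window means (not
#'   baseline-subtracted).
#' @param baselines cells x trials matrix of baseline-window means.
#' @param sessions session label per trial (>= 2 distinct sessions).
#' @param threshold |Z| threshold.
#' @param min_frac minimum fraction of supra-threshold sessions.
#' @param min_trials minimum trials for a session to be usable.
#' @return list of class `"responsiveness"`: `z` (cells x sessions),
#'   `responsive`, `frac`, `rule = "sessionwise"`, plus the thresholds.
#' @export
classify_responsive_sessionwise <- function(responses, baselines, sessions,
                                            threshold = 3.29, min_frac = 0.5,
                                            min_trials = 3L) {
  stopifnot(is.matrix(responses), dim(responses)[2] == length(sessions),
            all(dim(responses) == dim(baselines)))
  sess <- unique(sessions)
  if (length(sess) < 2L) stop("need at least 2 sessions")
  usable <- sess[vapply(sess, function(s) sum(sessions == s) >= min_trials,
                        logical(1))]
  if (!length(usable)) stop("no session has enough trials")
  z <- matrix(NA_real_, nrow(responses), length(usable),
              dimnames = list(NULL, usable))
  for (s in usable) {
    j <- sessions == s
    n <- sum(j)
    mu_r <- rowMeans(responses[, j, drop = FALSE])
    mu_b <- rowMeans(baselines[, j, drop = FALSE])
    sd_b <- apply(baselines[, j, drop = FALSE], 1L, stats::sd)
    z[, s] <- (mu_r - mu_b) / (sd_b / sqrt(n))
  }
  frac <- rowMeans(abs(z) > threshold, na.rm = TRUE)
  structure(list(z = z, responsive = !is.na(frac) & frac >= min_frac,
                 frac = frac, rule = "sessionwise", threshold = threshold,
                 min_frac = min_frac),
            class = "responsiveness")
}
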
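# Internal helpers shared across modules.

# Tolerance used when placing sample times into half-open windows; guards
# against decimal frame times (e.g. 0.1 s steps) not being exactly
# representable in binary.
.time_eps <- 1e-9

#' @noRd
frames_in_window <- function(time, window) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  which(time >= window[1] - .time_eps & time < window[2] - .time_eps)
}

#' Wrap an angle in degrees to [0, 360)
#' @noRd
wrap_deg <- function(x) {
  x <- x %% 360
  x[x < 0] <- x[x < 0] + 360
  x
}

#' Wrapped angular distance between two directions, in [0, 180]
#' @noRd
dir_dist_deg <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Orientation distance (directions 180 deg apart are identical), in [0, 90]
#' @noRd
ori_dist_deg <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

#' Ordinary least-squares slope of y against t (closed form)
#' @noRd
ols_slope <- function(y, t) {
  keep <- is.finite(y) & is.finite(t)
  y <- y[keep]; t <- t[keep]
  if (length(y) < 3L) stop("need at least 3 finite samples for a slope fit")
  tc <- t - mean(t)
  denom <- sum(tc^2)
  if (denom <= 0) stop("degenerate time window: all samples at one time")
  sum(tc * (y - mean(y))) / denom
}

#' @noRd
sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

#' Evaluate `code` under a fixed seed, restoring the caller's RNG state after.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
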
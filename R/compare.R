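# Rank-based group comparisons (the statistical unit is the cell unless
# stated otherwise by the caller).

#' Paired comparison (Wilcoxon signed-rank)
#'
#' Two-sided Wilcoxon signed-rank test on matched values. Zero differences
#' are dropped (the standard procedure); if every difference is zero the
#' result is flagged degenerate and no p-value is reported.
#'
#' @param values_a,values_b matched numeric vectors.
#' @param ids optional matched identifiers (checked for equality of length).
#' @param metric label of the compared metric.
#' @param groups labels of the two groups.
#' @return list of class `"comparison_result"`: `test = "signed_rank"`, `n`,
#'   `statistic`, `p_value`, `mean_a`, `mean_b`, `sem_a`, `sem_b`,
#'   `degenerate`, `metric`, `groups`.
#' @export
paired_compare <- function(values_a, values_b, ids = NULL,
                           metric = "value", groups = c("a", "b")) {
  stopifnot(length(values_a) == length(values_b))
  if (!is.null(ids)) stopifnot(length(ids) == length(values_a))
  keep <- is.finite(values_a) & is.finite(values_b)
  a <- values_a[keep]; b <- values_b[keep]
  d <- a - b
  degenerate <- all(d == 0) || length(d) == 0L
  if (degenerate) {
    stat <- NA_real_; p <- NA_real_
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
    stat <- unname(wt$statistic); p <- wt$p.value
  }
  structure(list(test = "signed_rank", n = length(a), statistic = stat,
                 p_value = p, mean_a = mean(a), mean_b = mean(b),
                 sem_a = sem(a), sem_b = sem(b), degenerate = degenerate,
                 metric = metric, groups = groups),
            class = "comparison_result")
}

#' Unpaired comparison (Wilcoxon rank-sum)
#'
#' Two-sided Wilcoxon rank-sum test with mid-ranks for ties.
#'
#' @param values_a,values_b numeric vectors (both non-empty).
#' @param metric label of the compared metric.
#' @param groups labels of the two groups.
#' @return list of class `"comparison_result"` with `test = "rank_sum"` and
#'   fields as in [paired_compare()] (`n` is `c(n_a, n_b)`).
#' @export
unpaired_compare <- function(values_a, values_b,
                             metric = "value", groups = c("a", "b")) {
  a <- values_a[is.finite(values_a)]
  b <- values_b[is.finite(values_b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  if (length(a) == 1L && length(b) == 1L) {
    # a single pair carries no discriminating power
    return(structure(list(test = "rank_sum", n = c(1L, 1L),
                          statistic = NA_real_, p_value = 1,
                          mean_a = a, mean_b = b,
                          sem_a = NA_real_, sem_b = NA_real_,
                          degenerate = TRUE, metric = metric,
                          groups = groups),
                     class = "comparison_result"))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  structure(list(test = "rank_sum", n = c(length(a), length(b)),
                 statistic = unname(wt$statistic), p_value = wt$p.value,
                 mean_a = mean(a), mean_b = mean(b),
                 sem_a = sem(a), sem_b = sem(b), degenerate = FALSE,
                 metric = metric, groups = groups),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  n_str <- paste(x$n, collapse = "/")
  p_str <- if (is.na(x$p_value)) "NA (degenerate)" else format.pval(x$p_value)
  cat(sprintf("<%s> %s: %s vs %s (n=%s): %.4g+-%.2g vs %.4g+-%.2g, p=%s\n",
              x$test, x$metric, x$groups[1], x$groups[2], n_str,
              x$mean_a, x$sem_a, x$mean_b, x$sem_b, p_str))
  invisible(x)
}

#' Collect comparison results into a data.frame
#' @param ... `"comparison_result"` objects.
#' @return data.frame, one row per comparison.
#' @export
comparison_table <- function(...) {
  res <- list(...)
  if (length(res) == 1L && is.list(res[[1]]) &&
      !inherits(res[[1]], "comparison_result")) res <- res[[1]]
  do.call(rbind, lapply(res, function(x)
    data.frame(metric = x$metric, test = x$test,
               group_a = x$groups[1], group_b = x$groups[2],
               n_a = x$n[1], n_b = x$n[length(x$n)],
               statistic = x$statistic, p_value = x$p_value,
               mean_a = x$mean_a, sem_a = x$sem_a,
               mean_b = x$mean_b, sem_b = x$sem_b,
               degenerate = x$degenerate)))
}
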
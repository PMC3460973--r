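## Decoy-population statistics: the protocol filters half of every decoy
## set by its final ranking score, unions the hybrid sets by that score,
## and summarises accuracy with bootstrap percentile estimates, rank-sum
## comparisons and five-number summaries.

## accept a decoy_set or a bare data frame with a score3 column
as_entries <- function(x) {
  if (inherits(x, "decoy_set")) x$entries else as.data.frame(x)
}

#' Keep the better-scoring half of a decoy set
#'
#' Eliminates the half of the predictions with higher score3: the
#' `floor(n/2)` lowest-score3 entries remain (800 -> 400, 100 -> 50), ties
#' broken stably by decoy id.
#'
#' @param ds a decoy set (or data frame with `score3` and `decoy_id`).
#' @return object of the same shape with the filtered entries.
#' @export
filter_lower_half <- function(ds) {
  entries <- as_entries(ds)
  n <- nrow(entries)
  if (n < 2L) stop("need at least 2 decoys to filter")
  ord <- order(entries$score3, entries$decoy_id)
  keep <- sort(ord[seq_len(n %/% 2L)])
  if (inherits(ds, "decoy_set")) {
    ds$entries <- entries[keep, , drop = FALSE]
    ds$conformations <- ds$conformations[keep]
    ds
  } else entries[keep, , drop = FALSE]
}

#' Union of two decoy sets by score3
#'
#' The hybrid result set: the `target_n` lowest-score3 members of the
#' union of the colony and MC decoys (800 of 800 + 100 in the full
#' protocol), ties broken stably by (label, decoy id).
#'
#' @param d1,d2 decoy sets.
#' @param target_n size of the union set.
#' @return decoy set labelled `"decoys12"`.
#' @export
union_best <- function(d1, d2, target_n) {
  e1 <- as_entries(d1); e2 <- as_entries(d2)
  if (nrow(e1) + nrow(e2) < target_n)
    stop("not enough decoys for a union of ", target_n)
  lab <- c(rep(d1$label %||% "A", nrow(e1)), rep(d2$label %||% "B", nrow(e2)))
  entries <- rbind(e1, e2)
  confs <- c(if (inherits(d1, "decoy_set")) d1$conformations else list(),
             if (inherits(d2, "decoy_set")) d2$conformations else list())
  ord <- order(entries$score3, lab, entries$decoy_id)[seq_len(target_n)]
  out <- structure(list(label = "decoys12",
                        entries = entries[ord, , drop = FALSE],
                        conformations = if (length(confs)) confs[ord] else list()),
                   class = "decoy_set")
  rownames(out$entries) <- NULL
  out
}

#' Bootstrap percentile estimate
#'
#' `folds` resamples with replacement of size `n`; the nearest-rank
#' p-quantile of each resample (for p = 0.10 and n = 400 this is the 40th
#' order statistic); mean and standard deviation across folds.
#'
#' @param values numeric vector, at least 10 values.
#' @param p percentile in `(0, 1)` (default 0.10).
#' @param folds number of bootstrap folds (default 50).
#' @param seed RNG seed.
#' @return list with `mean`, `sd` and the per-fold estimates `folds`.
#' @export
bootstrap_percentile <- function(values, p = 0.10, folds = 50L, seed = 1L) {
  n <- length(values)
  if (n < 10L) stop("need at least 10 values")
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  set.seed(seed)
  rank_idx <- max(1L, ceiling(p * n))
  est <- vapply(seq_len(folds), function(i) {
    resample <- values[sample.int(n, n, replace = TRUE)]
    sort(resample, partial = rank_idx)[rank_idx]
  }, numeric(1))
  list(mean = mean(est), sd = stats::sd(est), folds = est)
}

#' Rank-sum comparison of two decoy populations
#'
#' Two-sided Mann-Whitney U test; the pair is called significantly
#' different when `p < alpha`.
#'
#' @param A,B numeric vectors (at least 5 values each).
#' @param alpha significance level (default 0.05).
#' @return list with `statistic`, `p` and `significant`.
#' @export
compare_sets <- function(A, B, alpha = 0.05) {
  if (length(A) < 5L || length(B) < 5L) stop("need at least 5 values per set")
  wt <- suppressWarnings(stats::wilcox.test(A, B, alternative = "two.sided",
                                            exact = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       significant = wt$p.value < alpha)
}

#' Box-and-whisker summary of a value set
#'
#' The five-number summary (min, first quartile, median, third quartile,
#' max; quartiles by linear interpolation) plus the mean.
#'
#' @param values non-empty numeric vector.
#' @return named numeric vector `(min, q1, median, q3, max, mean)`.
#' @export
boxstats <- function(values) {
  if (length(values) < 1L) stop("empty value set")
  q <- stats::quantile(values, c(0, 0.25, 0.5, 0.75, 1), names = FALSE,
                       type = 7)
  c(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
    mean = mean(values))
}

#' Read a decoy score table written by [write_decoys()]
#'
#' @param path tab-separated score table.
#' @return data frame.
#' @export
read_score_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
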
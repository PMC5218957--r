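#' Activity quantification error
#'
#' Signed percent difference of the estimated activity relative to truth:
#' `100 * (estimated - true) / true`.
#'
#' @param estimated,true activities in MBq; `true > 0`.
#' @return signed percent error.
#' @export
quant_error <- function(estimated, true) {
  if (any(true <= 0)) stop("true activity must be positive")
  100 * (estimated - true) / true
}

#' Mann-Whitney (Wilcoxon rank-sum) comparison of two error samples
#'
#' Tie-corrected U statistic with a two-sided p-value, exact when the sample
#' is small and tie-free (via [stats::wilcox.test()]). Used to test whether
#' two scatter-correction methods yield the same accuracy distribution.
#'
#' @param a,b numeric error samples (each >= 3 values).
#' @return list with `U` (for sample `a`), `p`, and `significant`
#'   (p < 0.05).
#' @export
mann_whitney <- function(a, b) {
  if (length(a) < 3 || length(b) < 3)
    stop("each group needs at least 3 values")
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value,
       significant = wt$p.value < 0.05)
}

#' Mood's median test across segmentation-method error groups
#'
#' Counts values above versus not above the pooled grand median per group
#' and applies a chi-square test (no continuity correction) to the 2 x k
#' contingency table. Compares all segmentation methods at once.
#'
#' @param groups list of >= 2 nonempty numeric vectors.
#' @return list with `statistic`, `df`, `p`, `table`, `grand_median`,
#'   `significant` (p < 0.05).
#' @export
moods_median <- function(groups) {
  if (!is.list(groups) || length(groups) < 2 ||
      any(lengths(groups) == 0))
    stop("need a list of at least two nonempty groups")
  gm <- median(unlist(groups))
  above <- vapply(groups, function(g) sum(g > gm), numeric(1))
  below <- vapply(groups, function(g) sum(g <= gm), numeric(1))
  tab <- rbind(above = above, not_above = below)
  if (all(above == 0) || all(below == 0))
    stop("degenerate table: all values fall on one side of the grand median")
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab, grand_median = gm,
       significant = ct$p.value < 0.05)
}

#' Summarise quantification records by group
#'
#' Median, interquartile range, minimum and maximum of per-insert mean
#' errors for every (configuration, scatter method, segmentation method)
#' group; the raw content of the box plots.
#'
#' @param records a `QuantRecord` data.frame (see [run_study()]).
#' @return data.frame of group summaries.
#' @export
summarise_errors <- function(records) {
  per_insert <- aggregate(error_pct ~ config + scatter + segmentation + label,
                          data = records, FUN = mean)
  agg <- aggregate(error_pct ~ config + scatter + segmentation,
                   data = per_insert,
                   FUN = function(e) c(median = median(e), iqr = IQR(e),
                                       min = min(e), max = max(e),
                                       n = length(e)))
  cbind(agg[, c("config", "scatter", "segmentation")],
        as.data.frame(agg$error_pct))
}
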
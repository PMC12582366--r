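# Evaluation metrics: Pearson correlation for affinity regression, AUROC for
# binary in-vivo labels.

#' Pearson correlation coefficient
#'
#' Standard product-moment correlation with explicit failure on degenerate
#' input (a zero-variance vector never silently yields 0).
#'
#' @param x,y Equal-length numeric vectors, length >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  assert_that(length(x) == length(y), "length mismatch")
  assert_that(length(x) >= 3L, "need at least 3 observations")
  assert_that(all(is.finite(x)) && all(is.finite(y)), "non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort_invalid("zero-variance input: correlation undefined",
                  class = "affinitylm_undefined_metric")
  }
  stats::cor(x, y)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a random positive
#' outscores a random negative, ties counted half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1 or logical); both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels) | labels == 1)
  assert_that(length(scores) == length(labels), "length mismatch")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    abort_invalid("both classes must be present: AUROC undefined",
                  class = "affinitylm_undefined_metric")
  }
  r <- rank(scores)                      # average ranks handle ties as 1/2
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Assemble an evaluation report row
#'
#' @param metric `"pcc"` or `"auroc"`.
#' @param value Metric value.
#' @param n Number of evaluated records.
#' @param dataset_id,checkpoint_id Identifiers.
#' @param seed Seed in effect.
#' @return One-row data.frame with a timestamp.
#' @export
evaluation_report <- function(metric, value, n, dataset_id = NA_character_,
                              checkpoint_id = NA_character_, seed = NA_integer_) {
  if (metric == "pcc") assert_that(value >= -1 && value <= 1, "PCC out of range")
  if (metric == "auroc") assert_that(value >= 0 && value <= 1, "AUROC out of range")
  data.frame(metric = metric, value = value, n = as.integer(n),
             dataset_id = dataset_id, checkpoint_id = checkpoint_id,
             seed = seed, timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
             stringsAsFactors = FALSE)
}

#' Wilcoxon rank-sum comparison of two tools' per-dataset metrics
#'
#' Convenience wrapper for comparing paired evaluation results.
#' @param a,b Numeric metric vectors (paired by dataset).
#' @param paired Use the signed-rank test (default `TRUE`).
#' @return The `htest` object from [stats::wilcox.test()].
#' @export
compare_tools_wilcoxon <- function(a, b, paired = TRUE) {
  stats::wilcox.test(a, b, paired = paired, exact = FALSE)
}
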
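#' Significance stars for a p-value
#'
#' `"***"` for p < 0.01, `"**"` for p < 0.05, `"*"` for p < 0.1, `""`
#' otherwise (strict inequalities).
#'
#' @param p a p-value in `[0, 1]`.
#' @return a star string.
#' @export
star_label <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("p must be a single value in [0, 1]")
  if (p < 0.01) "***" else if (p < 0.05) "**" else if (p < 0.1) "*" else ""
}

#' Compare one fatigue feature between a condition and the reference
#'
#' Two-sided two-sample test of a per-subject (or per-segment) feature between
#' the reference viewing condition and a modified one. The default is Welch's
#' t-test (robust to unequal variances across viewing sessions); Student's t,
#' Mann-Whitney, and paired variants are available. Two identical zero-variance
#' samples are reported as p = 1 by convention (no evidence of a difference,
#' and the test statistic is undefined).
#'
#' @param ref numeric vector: feature values under the reference condition.
#' @param cond numeric vector: values under the modified condition.
#' @param test one of `"welch_t"`, `"student_t"`, `"mann_whitney"`,
#'   `"paired_t"`, `"wilcoxon"` (paired signed-rank).
#' @param feature_name label for the feature.
#' @param condition label for the modified condition.
#' @param ref_label label for the reference condition.
#' @return a `comparison_result`: one-row data frame with `feature`,
#'   `condition`, `mean`, `reference_mean`, `p_value`, `stars`.
#' @export
compare_to_reference <- function(ref, cond,
                                 test = c("welch_t", "student_t",
                                          "mann_whitney", "paired_t", "wilcoxon"),
                                 feature_name = "feature",
                                 condition = "modified",
                                 ref_label = "reference") {
  test <- match.arg(test)
  ref <- as.numeric(ref); cond <- as.numeric(cond)
  if (length(ref) < 2L || length(cond) < 2L)
    stop("each sample needs at least 2 values")
  paired <- test %in% c("paired_t", "wilcoxon")
  if (paired && length(ref) != length(cond))
    stop("paired tests require samples of equal length")
  p <- if (stats::sd(c(ref, cond)) == 0) {
    1  # identical constant samples: no difference detectable
  } else {
    switch(test,
      welch_t      = stats::t.test(cond, ref, var.equal = FALSE)$p.value,
      student_t    = stats::t.test(cond, ref, var.equal = TRUE)$p.value,
      mann_whitney = suppressWarnings(stats::wilcox.test(cond, ref))$p.value,
      paired_t     = stats::t.test(cond, ref, paired = TRUE)$p.value,
      wilcoxon     = suppressWarnings(stats::wilcox.test(cond, ref, paired = TRUE))$p.value)
  }
  if (is.na(p)) p <- 1
  res <- data.frame(feature = feature_name, condition = condition,
                    mean = mean(cond), reference_mean = mean(ref),
                    p_value = p, stars = star_label(p),
                    stringsAsFactors = FALSE)
  attr(res, "ref_label") <- ref_label
  class(res) <- c("comparison_result", class(res))
  res
}

#' Cross-tabulate comparison results as a feature-by-condition table
#'
#' Rows are features, columns the reference mean followed by each condition's
#' mean with its significance stars appended; means are formatted to 4 decimal
#' places, matching the conventional reporting style for these features.
#'
#' @param results a list of [compare_to_reference()] results (or one combined
#'   data frame).
#' @return a character data frame (row names = features).
#' @export
feature_table <- function(results) {
  if (is.data.frame(results)) results <- list(results)
  if (!length(results)) stop("need at least one comparison result")
  df <- do.call(rbind, lapply(results, as.data.frame))
  feats <- unique(df$feature)
  conds <- unique(df$condition)
  out <- data.frame(row.names = feats)
  out[["reference"]] <- vapply(feats, function(f)
    sprintf("%.4f", df$reference_mean[df$feature == f][1]), character(1))
  for (cn in conds) {
    out[[cn]] <- vapply(feats, function(f) {
      r <- df[df$feature == f & df$condition == cn, ]
      if (!nrow(r)) return("")
      sprintf("%.4f%s", r$mean[1], r$stars[1])
    }, character(1))
  }
  out
}
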
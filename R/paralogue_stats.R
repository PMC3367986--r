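#' Per-OG target/reference copy-number ratios
#'
#' One log2 ratio per orthologue group with at least one gene in each
#' species; groups absent in one species have an undefined log2 ratio and
#' are returned separately rather than entering the distribution.
#'
#' @param count_table Data frame with `og_id`, `n_reference`, `n_target`
#'   (e.g. from [og_count_table()]).
#' @return List with `ratios` (data frame adding `log2_ratio`) and
#'   `excluded` (rows with a zero count).
#' @export
compute_ratios <- function(count_table) {
  .need_cols(count_table, c("og_id", "n_reference", "n_target"), "count_table")
  if (any(count_table$n_reference < 0) || any(count_table$n_target < 0)) {
    stop("counts must be non-negative")
  }
  keep <- count_table$n_reference >= 1 & count_table$n_target >= 1
  ratios <- count_table[keep, c("og_id", "n_reference", "n_target")]
  ratios$log2_ratio <- log2(ratios$n_target / ratios$n_reference)
  rownames(ratios) <- NULL
  excluded <- count_table[!keep, c("og_id", "n_reference", "n_target")]
  rownames(excluded) <- NULL
  list(ratios = ratios, excluded = excluded)
}

#' Summarise the log2 copy-number ratio distribution
#'
#' Mean and standard deviation of the per-OG log2 ratios, plus the k-SD
#' classification thresholds on both the log2 and the fold-change scale.
#'
#' @param ratios Data frame with a `log2_ratio` column (or a numeric vector
#'   of log2 ratios).
#' @param estimator `"sample"` (n-1, default) or `"population"` (n).
#' @param k Threshold width in standard deviations (default 2).
#' @return Object of class `ratio_summary`: list with `mean_log2`,
#'   `sd_log2`, `n_ogs`, `k`, `estimator`, `upper`/`lower` (log2 thresholds)
#'   and `fold_upper`/`fold_lower`.
#' @export
distribution_summary <- function(ratios, estimator = c("sample", "population"),
                                 k = 2) {
  estimator <- match.arg(estimator)
  x <- if (is.data.frame(ratios)) {
    .need_cols(ratios, "log2_ratio", "ratios")
    ratios$log2_ratio
  } else as.numeric(ratios)
  if (length(x) < 2) stop("need at least 2 ratios to summarise")
  if (k <= 0) stop("k must be positive")
  m <- mean(x)
  n <- length(x)
  s <- if (estimator == "sample") stats::sd(x) else
    sqrt(sum((x - m)^2) / n)
  out <- list(mean_log2 = m, sd_log2 = s, n_ogs = n, k = k,
              estimator = estimator,
              upper = m + k * s, lower = m - k * s,
              fold_upper = 2^(m + k * s), fold_lower = 2^(m - k * s))
  class(out) <- "ratio_summary"
  out
}

#' Classify OGs as paralogue-rich, paralogue-less or typical
#'
#' An OG is paralogue-rich when its log2 ratio lies strictly more than k
#' standard deviations above the mean, paralogue-less when strictly more
#' than k below, and typical otherwise.
#'
#' @param ratios Data frame with `log2_ratio` (from [compute_ratios()]).
#' @param summary A `ratio_summary`.
#' @return `ratios` with a `class` column in \{rich, less, typical\}.
#' @export
classify_paralogue <- function(ratios, summary) {
  stopifnot(inherits(summary, "ratio_summary"))
  .need_cols(ratios, "log2_ratio", "ratios")
  cls <- rep("typical", nrow(ratios))
  cls[ratios$log2_ratio > summary$upper] <- "rich"
  cls[ratios$log2_ratio < summary$lower] <- "less"
  ratios$class <- cls
  ratios
}

#' Fold-change value of a classification threshold
#'
#' The k-SD log2 thresholds expressed as plain fold changes:
#' `2^(mean + k*sd)` (upper) or `2^(mean - k*sd)` (lower).
#'
#' @param summary A `ratio_summary`.
#' @param direction `"upper"` or `"lower"`.
#' @return Numeric fold change.
#' @export
fold_threshold <- function(summary, direction = c("upper", "lower")) {
  stopifnot(inherits(summary, "ratio_summary"))
  direction <- match.arg(direction)
  if (direction == "upper") summary$fold_upper else summary$fold_lower
}

#' @export
print.ratio_summary <- function(x, ...) {
  cat(sprintf(
    "log2 copy-number ratio over %d OGs: mean %.3f, sd %.3f (%s)\n",
    x$n_ogs, x$mean_log2, x$sd_log2, x$estimator))
  cat(sprintf("k = %g thresholds: log2 [%.3f, %.3f], fold [%.3f, %.3f]\n",
              x$k, x$lower, x$upper, x$fold_lower, x$fold_upper))
  invisible(x)
}
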
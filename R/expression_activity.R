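#' Construct an expression matrix with its activity rule
#'
#' Wraps a genes-by-conditions matrix of non-negative values together with
#' the dataset-specific transcriptional-activity rule and the subset of
#' conditions that are flower tissues. Two rules exist: `raw_reads` (a gene
#' is active when some condition has at least 2 reads) and `normalized`
#' (active when some condition exceeds 0).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene IDs),
#'   conditions in columns (colnames = condition labels).
#' @param rule `"raw_reads"` or `"normalized"`.
#' @param flower_conditions Character vector of condition labels forming the
#'   flower subset (may be empty).
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, rule = c("raw_reads", "normalized"),
                              flower_conditions = character()) {
  rule <- match.arg(rule)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have gene rownames and condition colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene labels")
  if (anyDuplicated(colnames(values))) stop("duplicate condition labels")
  if (any(values < 0)) stop("expression values must be non-negative")
  bad <- setdiff(flower_conditions, colnames(values))
  if (length(bad)) {
    stop("unknown flower condition label(s): ", paste(bad, collapse = ", "))
  }
  structure(list(values = values, rule = rule,
                 flower_conditions = flower_conditions),
            class = "expr_matrix")
}

#' Read an expression TSV into an `expr_matrix`
#'
#' Expects a header row, gene IDs in the first column and one column per
#' condition.
#'
#' @param path TSV path.
#' @inheritParams expression_matrix
#' @return An `expr_matrix`.
#' @export
read_expression_tsv <- function(path, rule = c("raw_reads", "normalized"),
                                flower_conditions = character()) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, rule = rule, flower_conditions = flower_conditions)
}

# internal: activity of each row of a matrix under a rule
.rule_active <- function(values, rule) {
  mx <- apply(values, 1, max)
  if (rule == "raw_reads") mx >= 2 else mx > 0
}

#' Call transcriptional activity per gene
#'
#' @param em An `expr_matrix`.
#' @return Data frame (`gene_id`, `active`).
#' @export
call_active <- function(em) {
  stopifnot(inherits(em, "expr_matrix"))
  data.frame(gene_id = rownames(em$values),
             active = unname(.rule_active(em$values, em$rule)),
             stringsAsFactors = FALSE)
}

#' Combine per-dataset activity calls
#'
#' A gene is active overall when it is active under either dataset's rule
#' (OR over the non-missing calls).
#'
#' @param raw Data frame from [call_active()] on the raw-reads dataset, or
#'   `NULL`.
#' @param normalized Likewise for the normalized dataset.
#' @return Data frame (`gene_id`, `active_raw`, `active_normalized`,
#'   `active_any`).
#' @export
combine_activity <- function(raw = NULL, normalized = NULL) {
  if (is.null(raw) && is.null(normalized)) {
    stop("at least one of raw, normalized is required")
  }
  genes <- sort(unique(c(raw$gene_id, normalized$gene_id)))
  a_raw <- if (is.null(raw)) rep(NA, length(genes)) else
    raw$active[match(genes, raw$gene_id)]
  a_nrm <- if (is.null(normalized)) rep(NA, length(genes)) else
    normalized$active[match(genes, normalized$gene_id)]
  any <- mapply(function(x, y) isTRUE(x) || isTRUE(y), a_raw, a_nrm)
  data.frame(gene_id = genes, active_raw = a_raw, active_normalized = a_nrm,
             active_any = unname(any), stringsAsFactors = FALSE)
}

#' Flag genes expressed in flower tissues
#'
#' Re-applies the dataset's activity rule restricted to the flower-condition
#' columns. When `calls` already carries a `flower_expressed` column (from
#' another dataset), the flags are OR-ed, so a gene counts as flower
#' expressed when either dataset supports it.
#'
#' @param calls Data frame with a `gene_id` column.
#' @param em The `expr_matrix` the calls came from.
#' @param flower_conditions Condition labels to use; defaults to the
#'   matrix's own flower subset.
#' @return `calls` with a logical `flower_expressed` column.
#' @export
flag_flower_expressed <- function(calls, em,
                                  flower_conditions = em$flower_conditions) {
  stopifnot(inherits(em, "expr_matrix"))
  .need_cols(calls, "gene_id", "calls")
  bad <- setdiff(flower_conditions, colnames(em$values))
  if (length(bad)) {
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  }
  flo <- rep(FALSE, nrow(calls))
  if (length(flower_conditions)) {
    sub <- em$values[, flower_conditions, drop = FALSE]
    act <- .rule_active(sub, em$rule)
    idx <- match(calls$gene_id, rownames(em$values))
    flo <- ifelse(is.na(idx), FALSE, act[idx])
  }
  if ("flower_expressed" %in% names(calls)) {
    calls$flower_expressed <- calls$flower_expressed | flo
  } else {
    calls$flower_expressed <- unname(flo)
  }
  calls
}

#' Summarise activity calls
#'
#' @param calls Data frame with an `active_any` (or `active`) column.
#' @return Named list: `n_genes`, `n_active`, `pct_active` (one decimal),
#'   and flower counts when available.
#' @export
activity_summary <- function(calls) {
  act <- if ("active_any" %in% names(calls)) calls$active_any else calls$active
  if (is.null(act)) stop("calls has no activity column")
  out <- list(n_genes = length(act), n_active = sum(act),
              pct_active = round(100 * sum(act) / length(act), 1))
  if ("flower_expressed" %in% names(calls)) {
    out$n_flower_expressed <- sum(calls$flower_expressed)
  }
  out
}

#' Z-score each gene's expression profile
#'
#' Rows are centred and scaled with the population (divide-by-n) standard
#' deviation, the convention of the clustering tools this mirrors.
#' Zero-variance rows map to all zeros rather than NaN.
#'
#' @param x Numeric matrix or `expr_matrix`.
#' @param estimator `"population"` (default) or `"sample"`.
#' @return Matrix of the same shape.
#' @export
zscore_rows <- function(x, estimator = c("population", "sample")) {
  estimator <- match.arg(estimator)
  values <- if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
  if (ncol(values) < 2) stop("z-scoring needs at least 2 conditions")
  mu <- rowMeans(values)
  cen <- values - mu
  n <- ncol(values)
  denom <- if (estimator == "population") n else n - 1
  sd <- sqrt(rowSums(cen^2) / denom)
  out <- cen / ifelse(sd > 0, sd, 1)
  out[sd == 0, ] <- 0
  out
}

#' Hierarchical clustering of expression profiles
#'
#' Distances default to correlation distance (1 - Pearson r) with average
#' linkage, the common choice for expression-pattern clustering. Pairs
#' involving a zero-variance profile get distance 1 with a warning. Tie
#' handling follows [stats::hclust()], which is deterministic for a fixed
#' input ordering.
#'
#' @param x Numeric matrix (genes in rows) or `expr_matrix`.
#' @param distance `"pearson_correlation"` or `"euclidean"`.
#' @param linkage `"average"` or `"complete"`.
#' @return Object of class `expr_dendrogram`: list with the `hclust` fit and
#'   the settings used.
#' @export
hierarchical_cluster <- function(x,
                                 distance = c("pearson_correlation", "euclidean"),
                                 linkage = c("average", "complete")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  values <- if (inherits(x, "expr_matrix")) x$values else as.matrix(x)
  if (nrow(values) < 2) stop("clustering needs at least 2 genes")
  if (distance == "pearson_correlation") {
    sds <- apply(values, 1, stats::sd)
    r <- suppressWarnings(stats::cor(t(values)))
    d <- 1 - r
    if (any(sds == 0)) {
      warning("zero-variance profile(s); their correlation distances set to 1")
      d[sds == 0, ] <- 1
      d[, sds == 0] <- 1
    }
    diag(d) <- 0
    D <- stats::as.dist(d)
  } else {
    D <- stats::dist(values, method = "euclidean")
  }
  fit <- stats::hclust(D, method = linkage)
  structure(list(hclust = fit, distance = distance, linkage = linkage),
            class = "expr_dendrogram")
}

#' Cut a dendrogram into flat clusters
#'
#' @param dend An `expr_dendrogram`.
#' @param k Number of clusters, or
#' @param h Cut height.
#' @return Named integer vector of cluster labels.
#' @export
cut_clusters <- function(dend, k = NULL, h = NULL) {
  stopifnot(inherits(dend, "expr_dendrogram"))
  stats::cutree(dend$hclust, k = k, h = h)
}

#' Export a dendrogram as Newick text
#'
#' @param dend An `expr_dendrogram`.
#' @return Newick string.
#' @export
dendrogram_newick <- function(dend) {
  stopifnot(inherits(dend, "expr_dendrogram"))
  ape::write.tree(ape::as.phylo(dend$hclust))
}

#' Adjusted Rand index between two partitions
#'
#' Quantifies agreement between expression-derived clusters and
#' sequence-similarity groups (OG membership). 1 for identical partitions,
#' approximately 0 at chance.
#'
#' @param flat_clusters Named vector of cluster labels (names = gene IDs).
#' @param og_membership Named vector of group labels over the same genes.
#' @return Adjusted Rand index in \[-1, 1\].
#' @export
cluster_og_concordance <- function(flat_clusters, og_membership) {
  if (is.null(names(flat_clusters)) || is.null(names(og_membership))) {
    stop("both partitions must be named by gene ID")
  }
  if (!setequal(names(flat_clusters), names(og_membership))) {
    stop("the two partitions cover different gene sets")
  }
  og_membership <- og_membership[names(flat_clusters)]
  tab <- table(flat_clusters, og_membership)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)   # degenerate partitions
  (sum_ij - expected) / (max_index - expected)
}
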
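#' Per-chromosome fraction of flagged genes
#'
#' For each chromosome, the number of genes, the number belonging to the
#' flagged set (e.g. members of paralogue-rich OGs) and their fraction.
#' Optionally joins an externally supplied percentage of recently duplicated
#' segments per chromosome (an input column, never computed here).
#'
#' @param genes Data frame with `gene_id`, `chrom` (and coordinates).
#' @param flagged Character vector of flagged gene IDs; must all be present
#'   in `genes`.
#' @param pct_duplicated Optional data frame (`chrom`, `pct`).
#' @return Data frame (`chrom`, `n_genes`, `n_flagged`, `fraction`, and
#'   `pct_duplicated` when supplied), sorted by chromosome.
#' @export
per_chromosome_fraction <- function(genes, flagged, pct_duplicated = NULL) {
  .need_cols(genes, c("gene_id", "chrom"), "genes")
  if (any(is.na(genes$chrom))) stop("every gene needs a chromosome")
  missing <- setdiff(flagged, genes$gene_id)
  if (length(missing)) {
    stop("flagged gene(s) absent from the catalogue: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  chroms <- sort(unique(genes$chrom))
  n_genes <- as.integer(table(factor(genes$chrom, levels = chroms)))
  fl <- genes$gene_id %in% flagged
  n_flagged <- as.integer(table(factor(genes$chrom[fl], levels = chroms)))
  out <- data.frame(chrom = chroms, n_genes = n_genes, n_flagged = n_flagged,
                    fraction = n_flagged / n_genes, stringsAsFactors = FALSE)
  if (!is.null(pct_duplicated)) {
    .need_cols(pct_duplicated, c("chrom", "pct"), "pct_duplicated")
    out$pct_duplicated <- pct_duplicated$pct[match(out$chrom,
                                                   pct_duplicated$chrom)]
  }
  rownames(out) <- NULL
  out
}

#' Pearson product-moment correlation with validation
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0) stop("zero variance in x")
  if (stats::sd(y) == 0) stop("zero variance in y")
  stats::cor(x, y, method = "pearson")
}

#' Sliding-window scan for clusters of flagged genes
#'
#' Windows of `window_size` bp tile each chromosome at `step` bp. A gene
#' belongs to a window when its start coordinate lies inside it (so genes
#' straddling a boundary are counted once per window set unambiguously).
#' Windows are ranked by flagged-gene count, ties broken by chromosome and
#' start.
#'
#' @param genes Data frame with `gene_id`, `chrom`, `start` (1-based), and
#'   optionally `og_id` for the contributing-OG report.
#' @param flagged Character vector of flagged gene IDs.
#' @param window_size Window width in bp (default 1.4 Mb).
#' @param step Step between window starts in bp (default 100 kb); must not
#'   exceed `window_size`.
#' @param chrom_lengths Optional named vector of chromosome lengths;
#'   defaults to the maximum gene start per chromosome.
#' @return Data frame of windows: `chrom`, `window_start`, `window_end`
#'   (1-based inclusive), `bed_start`, `bed_end` (0-based half-open),
#'   `n_flagged_in_window`, `contributing_ogs`, ranked by count descending.
#' @export
window_scan <- function(genes, flagged, window_size = 1400000L,
                        step = 100000L, chrom_lengths = NULL) {
  .need_cols(genes, c("gene_id", "chrom", "start"), "genes")
  if (window_size <= 0 || step <= 0) stop("window_size and step must be positive")
  if (step > window_size) stop("step must not exceed window_size")
  has_og <- "og_id" %in% names(genes)
  fl <- genes[genes$gene_id %in% flagged, , drop = FALSE]
  chroms <- sort(unique(genes$chrom))
  pieces <- lapply(chroms, function(ch) {
    g <- genes[genes$chrom == ch, , drop = FALSE]
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths)) {
      chrom_lengths[[ch]]
    } else max(g$start)
    starts <- seq(1L, max(1L, len), by = step)
    f <- fl[fl$chrom == ch, , drop = FALSE]
    cnt <- vapply(starts, function(s) {
      sum(f$start >= s & f$start <= s + window_size - 1)
    }, integer(1))
    ogs <- if (has_og) {
      vapply(starts, function(s) {
        hit <- f$start >= s & f$start <= s + window_size - 1
        paste(sort(unique(f$og_id[hit])), collapse = ",")
      }, character(1))
    } else rep("", length(starts))
    data.frame(chrom = ch, window_start = starts,
               window_end = starts + window_size - 1,
               bed_start = starts - 1L, bed_end = starts + window_size - 1L,
               n_flagged_in_window = cnt, contributing_ogs = ogs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(-out$n_flagged_in_window, out$chrom, out$window_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
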
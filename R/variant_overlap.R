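#' Gene models with CDS features and derived promoters
#'
#' All coordinates are 1-based inclusive (GFF3 convention). CDS intervals
#' are merged when overlapping and must fall inside the gene body. The
#' promoter is the 1 kb (by default) strictly upstream of the gene body,
#' strand-aware, truncated at position 1 and at the chromosome end when
#' chromosome lengths are known; it never overlaps its own gene body.
#'
#' @param genes Data frame: `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (`"+"` or `"-"`).
#' @param cds Data frame: `gene_id`, `start`, `end`.
#' @param promoter_length Upstream length in bp (default 1000).
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return Object of class `gene_models`: list with `genes` (including
#'   promoter columns `prom_start`/`prom_end`, NA when width 0) and `cds`.
#' @export
gene_models <- function(genes, cds, promoter_length = 1000L,
                        chrom_lengths = NULL) {
  .need_cols(genes, c("gene_id", "chrom", "start", "end", "strand"), "genes")
  .need_cols(cds, c("gene_id", "start", "end"), "cds")
  if (any(genes$start > genes$end)) stop("gene start > end")
  if (any(genes$start < 1)) stop("gene coordinates must be positive")
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in models")
  # merge overlapping CDS per gene and check bounds
  merged <- do.call(rbind, lapply(split(cds, cds$gene_id), function(x) {
    g <- genes[genes$gene_id == x$gene_id[1], , drop = FALSE]
    if (nrow(g) == 0) stop("CDS for unknown gene: ", x$gene_id[1])
    if (any(x$start < g$start | x$end > g$end)) {
      stop("CDS outside gene bounds for ", x$gene_id[1])
    }
    x <- x[order(x$start), , drop = FALSE]
    s <- x$start[1]; e <- x$end[1]
    out_s <- c(); out_e <- c()
    for (i in seq_len(nrow(x))[-1]) {
      if (x$start[i] <= e + 1) {
        e <- max(e, x$end[i])
      } else {
        out_s <- c(out_s, s); out_e <- c(out_e, e)
        s <- x$start[i]; e <- x$end[i]
      }
    }
    data.frame(gene_id = x$gene_id[1], start = c(out_s, s),
               end = c(out_e, e), stringsAsFactors = FALSE)
  }))
  rownames(merged) <- NULL
  prom <- build_promoter(genes, length = promoter_length,
                         chrom_lengths = chrom_lengths)
  genes$prom_start <- prom$prom_start
  genes$prom_end <- prom$prom_end
  structure(list(genes = genes, cds = merged,
                 promoter_length = promoter_length),
            class = "gene_models")
}

#' Derive strand-aware promoter intervals
#'
#' Plus-strand gene `[s, e]` gets promoter `[s - length, s - 1]`; minus
#' strand gets `[e + 1, e + length]`; both truncated to valid chromosome
#' positions. A promoter of zero width (gene starting at position 1 on the
#' plus strand) is returned as NA.
#'
#' @param genes Data frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @param length Promoter length in bp.
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return Data frame (`gene_id`, `prom_start`, `prom_end`).
#' @export
build_promoter <- function(genes, length = 1000L, chrom_lengths = NULL) {
  .need_cols(genes, c("gene_id", "chrom", "start", "end", "strand"), "genes")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  plus <- genes$strand == "+"
  ps <- ifelse(plus, genes$start - length, genes$end + 1)
  pe <- ifelse(plus, genes$start - 1, genes$end + length)
  ps <- pmax(ps, 1)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[genes$chrom]
    pe <- ifelse(is.na(lim), pe, pmin(pe, lim))
  }
  empty <- ps > pe
  ps[empty] <- NA; pe[empty] <- NA
  data.frame(gene_id = genes$gene_id, prom_start = ps, prom_end = pe,
             stringsAsFactors = FALSE)
}

#' Categorise a SNP with respect to one gene model
#'
#' Categories partition the positions on the gene's chromosome: `CDS`
#' (inside a coding interval), `genic_noncoding` (inside the gene body but
#' outside every CDS — introns and untranslated gene sequence), `promoter`
#' (inside the 1 kb upstream interval) or `outside`. A SNP on a different
#' chromosome is `outside` with a warning.
#'
#' @param models A `gene_models` object.
#' @param gene_id Gene to categorise against.
#' @param chrom,pos SNP location.
#' @return One of `"CDS"`, `"genic_noncoding"`, `"promoter"`, `"outside"`.
#' @export
categorize_snp <- function(models, gene_id, chrom, pos) {
  stopifnot(inherits(models, "gene_models"))
  g <- models$genes[models$genes$gene_id == gene_id, , drop = FALSE]
  if (nrow(g) == 0) stop("unknown gene: ", gene_id)
  if (!identical(chrom, g$chrom)) {
    warning("SNP chromosome ", chrom, " differs from gene ", gene_id,
            " on ", g$chrom)
    return("outside")
  }
  cds <- models$cds[models$cds$gene_id == gene_id, , drop = FALSE]
  if (nrow(cds) && any(pos >= cds$start & pos <= cds$end)) return("CDS")
  if (pos >= g$start && pos <= g$end) return("genic_noncoding")
  if (!is.na(g$prom_start) && pos >= g$prom_start && pos <= g$prom_end) {
    return("promoter")
  }
  "outside"
}

#' Per-gene SNP report
#'
#' Counts SNPs per category for every gene and flags genes whose SNPs fall
#' only in non-coding sequence (gene body outside CDS) and/or promoters —
#' i.e. genes with at least one SNP but none in a CDS.
#'
#' @param snps Data frame: `chrom`, `pos` (and optionally `id`).
#' @param models A `gene_models` object.
#' @return Data frame per gene: `gene_id`, `n_snps_cds`,
#'   `n_snps_genic_noncoding`, `n_snps_promoter`, `noncoding_only`.
#' @export
gene_variant_report <- function(snps, models) {
  stopifnot(inherits(models, "gene_models"))
  .need_cols(snps, c("chrom", "pos"), "snps")
  g <- models$genes
  n <- nrow(g)
  n_cds <- n_nc <- n_pr <- integer(n)
  for (i in seq_len(n)) {
    s <- snps[snps$chrom == g$chrom[i], , drop = FALSE]
    if (nrow(s) == 0) next
    cds <- models$cds[models$cds$gene_id == g$gene_id[i], , drop = FALSE]
    in_cds <- rep(FALSE, nrow(s))
    for (j in seq_len(nrow(cds))) {
      in_cds <- in_cds | (s$pos >= cds$start[j] & s$pos <= cds$end[j])
    }
    in_body <- s$pos >= g$start[i] & s$pos <= g$end[i]
    in_prom <- !is.na(g$prom_start[i]) &
      s$pos >= g$prom_start[i] & s$pos <= g$prom_end[i]
    n_cds[i] <- sum(in_cds)
    n_nc[i] <- sum(in_body & !in_cds)
    n_pr[i] <- sum(in_prom)
  }
  data.frame(gene_id = g$gene_id, n_snps_cds = n_cds,
             n_snps_genic_noncoding = n_nc, n_snps_promoter = n_pr,
             noncoding_only = n_cds == 0 & (n_nc + n_pr) > 0,
             stringsAsFactors = FALSE)
}

#' Census of genes with only non-coding/promoter SNPs
#'
#' Over the universe of genes carrying at least one SNP (in CDS, gene body
#' or promoter), counts those whose SNPs all avoid CDS, and the percentage
#' of the universe they represent (one decimal).
#'
#' @param reports Data frame from [gene_variant_report()].
#' @return List: `count`, `n_universe`, `percentage`.
#' @export
census_noncoding_only <- function(reports) {
  .need_cols(reports, c("gene_id", "n_snps_cds", "n_snps_genic_noncoding",
                        "n_snps_promoter", "noncoding_only"), "reports")
  universe <- reports[reports$n_snps_cds + reports$n_snps_genic_noncoding +
                        reports$n_snps_promoter > 0, , drop = FALSE]
  if (nrow(universe) == 0) stop("empty universe: no gene carries a SNP")
  cnt <- sum(universe$noncoding_only)
  list(count = cnt, n_universe = nrow(universe),
       percentage = round(100 * cnt / nrow(universe), 1))
}

#' Overlap structural variants with genes and promoters
#'
#' A gene is flagged for an SV type when the SV interval intersects the gene
#' body, or — when `include_promoter` — the gene body or its promoter
#' (closed-interval intersection). Enabling the promoter can only add flags.
#'
#' @param svs Data frame: `chrom`, `start`, `end`, `type` (one of
#'   `deletion`, `insertion`, `inversion`), optional `id`.
#' @param models A `gene_models` object.
#' @param include_promoter Include promoter intervals in the overlap test.
#' @return Data frame per gene: logical columns `deletion`, `insertion`,
#'   `inversion`, plus `sv_overlap_types` (comma-separated).
#' @export
sv_overlap <- function(svs, models, include_promoter = FALSE) {
  stopifnot(inherits(models, "gene_models"))
  .need_cols(svs, c("chrom", "start", "end", "type"), "svs")
  if (any(svs$start > svs$end)) stop("SV interval start > end")
  g <- models$genes
  types <- c("deletion", "insertion", "inversion")
  flags <- matrix(FALSE, nrow(g), length(types),
                  dimnames = list(g$gene_id, types))
  for (i in seq_len(nrow(svs))) {
    if (!svs$type[i] %in% types) next
    same <- g$chrom == svs$chrom[i]
    body <- same & svs$start[i] <= g$end & svs$end[i] >= g$start
    hit <- body
    if (include_promoter) {
      prom <- same & !is.na(g$prom_start) &
        svs$start[i] <= g$prom_end & svs$end[i] >= g$prom_start
      hit <- hit | prom
    }
    flags[hit, svs$type[i]] <- TRUE
  }
  out <- data.frame(gene_id = g$gene_id, flags, stringsAsFactors = FALSE)
  out$sv_overlap_types <- apply(flags, 1, function(x) {
    paste(types[x], collapse = ",")
  })
  rownames(out) <- NULL
  out
}

#' Fisher's exact enrichment test on a gene subset
#'
#' Tests whether flagged genes (e.g. SV- or SNP-carrying) are enriched or
#' depleted in a subset (e.g. flowering genes) relative to the rest of the
#' background, via the two-sided Fisher's exact test on the 2x2 table.
#' The reported odds ratio is the sample (cross-product) odds ratio.
#'
#' @param subset_flagged,subset_total Flagged and total counts in the subset.
#' @param background_flagged,background_total Flagged and total counts in
#'   the whole background (which contains the subset).
#' @return List: `odds_ratio`, `p_value`, `table` (the 2x2 matrix).
#' @export
enrichment_test <- function(subset_flagged, subset_total,
                            background_flagged, background_total) {
  cnt <- c(subset_flagged, subset_total, background_flagged, background_total)
  if (any(cnt < 0)) stop("counts must be non-negative")
  if (subset_flagged > subset_total ||
      background_flagged > background_total ||
      subset_total > background_total ||
      subset_flagged > background_flagged ||
      (subset_total - subset_flagged) >
        (background_total - background_flagged)) {
    stop("inconsistent counts: subset must be contained in background")
  }
  a <- subset_flagged
  b <- subset_total - subset_flagged
  c_ <- background_flagged - subset_flagged
  d <- (background_total - subset_total) - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("subset", "rest"),
                                c("flagged", "not_flagged")))
  p <- stats::fisher.test(tab)$p.value
  or <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c_)
  list(odds_ratio = or, p_value = p, table = tab)
}

#' Read gene models from GFF3
#'
#' Consumes `gene` and `CDS` features; gene IDs come from the `ID=`
#' attribute of gene features, CDS are attached via their `Parent=`
#' attribute (transcript suffixes of the form `.n` are stripped).
#'
#' @param path GFF3 file.
#' @inheritParams gene_models
#' @return A `gene_models` object.
#' @export
read_gene_models_gff3 <- function(path, promoter_length = 1000L,
                                  chrom_lengths = NULL) {
  gff <- ape::read.gff(path, GFF3 = TRUE)
  attr1 <- function(x, key) {
    m <- regmatches(x, regexpr(paste0(key, "=[^;]+"), x))
    ifelse(lengths(regmatches(x, gregexpr(paste0(key, "=[^;]+"), x))) > 0,
           sub(paste0("^", key, "="), "", m), NA_character_)
  }
  gn <- gff[gff$type == "gene", , drop = FALSE]
  genes <- data.frame(
    gene_id = attr1(as.character(gn$attributes), "ID"),
    chrom = as.character(gn$seqid), start = gn$start, end = gn$end,
    strand = as.character(gn$strand), stringsAsFactors = FALSE)
  cd <- gff[gff$type == "CDS", , drop = FALSE]
  cds <- data.frame(
    gene_id = sub("\\.\\d+$", "",
                  attr1(as.character(cd$attributes), "Parent")),
    start = cd$start, end = cd$end, stringsAsFactors = FALSE)
  gene_models(genes, cds, promoter_length = promoter_length,
              chrom_lengths = chrom_lengths)
}

#' Read SNPs and structural variants from a minimal TSV
#'
#' Columns: `chrom`, `start`, `end`, `type` (`SNP`, `deletion`, `insertion`,
#' `inversion`), optional `id`. SNP rows must have `start == end`.
#'
#' @param path TSV file.
#' @return List with `snps` (`chrom`, `pos`, `id`) and `svs`
#'   (`chrom`, `start`, `end`, `type`, `id`).
#' @export
read_variants_tsv <- function(path) {
  v <- read_tsv(path)
  .need_cols(v, c("chrom", "start", "end", "type"), "variants")
  if (!"id" %in% names(v)) v$id <- paste0("var", seq_len(nrow(v)))
  is_snp <- v$type == "SNP"
  if (any(is_snp & v$start != v$end)) stop("SNP rows must have start == end")
  list(snps = data.frame(chrom = v$chrom[is_snp], pos = v$start[is_snp],
                         id = v$id[is_snp], stringsAsFactors = FALSE),
       svs = v[!is_snp, c("chrom", "start", "end", "type", "id")])
}

#' Read SNPs and structural variants from a VCF
#'
#' SNPs are records with single-base REF and ALT and no `SVTYPE`; structural
#' variants carry `SVTYPE` (`DEL`, `INS`, `INV`) and an `END` INFO field.
#'
#' @param path VCF file.
#' @return Same shape as [read_variants_tsv()].
#' @export
read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- as.character(v@fix[, "INFO"])
  info[is.na(info)] <- ""
  get_info <- function(key) {
    out <- rep(NA_character_, length(info))
    hit <- regexpr(paste0("(^|;)", key, "=[^;]+"), info)
    out[hit > 0] <- sub(paste0("^;?", key, "="), "", regmatches(info, hit))
    out
  }
  svtype <- get_info("SVTYPE")
  endpos <- suppressWarnings(as.integer(get_info("END")))
  pos <- as.integer(fix$POS)
  is_sv <- !is.na(svtype)
  type_map <- c(DEL = "deletion", INS = "insertion", INV = "inversion")
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                paste0("var", seq_along(pos)), fix$ID)
  list(
    snps = data.frame(chrom = fix$CHROM[!is_sv], pos = pos[!is_sv],
                      id = ids[!is_sv], stringsAsFactors = FALSE),
    svs = data.frame(chrom = fix$CHROM[is_sv], start = pos[is_sv],
                     end = ifelse(is.na(endpos[is_sv]), pos[is_sv],
                                  endpos[is_sv]),
                     type = unname(type_map[svtype[is_sv]]),
                     id = ids[is_sv], stringsAsFactors = FALSE)
  )
}
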
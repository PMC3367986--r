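#' Simulation configuration
#'
#' One configuration object drives every fixture generator. A single root
#' `seed` derives an independent, deterministic stream per stage (see
#' [derive_seed()]), so stages re-run in isolation reproduce the full-run
#' output byte for byte.
#'
#' Defaults encode the study conditions this generator emulates: 11,344
#' orthologue groups whose per-OG log2(target/reference) copy-number ratios
#' follow a normal law with mean 1.03 and SD 0.88; reference per-OG counts
#' from a shifted Poisson (1 + Pois(0.83), mean about 1.83 genes per OG);
#' negative-binomial expression counts over 14 tissue conditions with
#' planted co-expression clusters; a 20-chromosome genome with uniform gene
#' placement and one planted 1 Mb cluster of 60 paralogue-rich genes; and
#' SNP/SV tables with controllable per-category counts.
#'
#' @param seed Root integer seed.
#' @param n_ogs Number of orthologue groups.
#' @param log2_ratio_mean,log2_ratio_sd Parameters of the log2 copy-number
#'   ratio law.
#' @param ref_count_lambda Poisson rate for reference counts (shifted by 1).
#' @param k Threshold width (SDs) used to record true OG classes.
#' @param link_only_frac Fraction of target genes per OG assigned via
#'   annotation link instead of membership.
#' @param synth_og_frac Fraction of OGs converted to the synthesized-ID case
#'   (reference gene without membership).
#' @param flowering_og_frac Fraction of OGs whose reference genes go on the
#'   flowering list.
#' @param branch_noise_sd SD of additive branch-length noise in gene trees.
#' @param n_conditions,n_expr_clusters,nb_mean,nb_dispersion,n_zero_genes
#'   Expression generator: number of tissue conditions, planted clusters,
#'   negative-binomial mean and dispersion, and all-zero genes.
#' @param n_chromosomes,chromosome_length,genes_per_chrom,gene_length,gene_spacing
#'   Genome layout (bp; genes on a uniform grid).
#' @param cluster_chrom,cluster_start,cluster_span,cluster_size Planted
#'   chromosomal cluster of flagged genes.
#' @param background_flag_rate Fraction of off-cluster genes flagged.
#' @param n_snp_cds,n_snp_genic_noncoding,n_snp_promoter,n_snp_outside
#'   Planted SNP counts per category.
#' @param n_sv_body,n_sv_promoter,n_sv_none Planted structural variants
#'   overlapping a gene body, a promoter only, or nothing.
#' @param promoter_length Promoter length in bp.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_ogs = 11344L,
                              log2_ratio_mean = 1.03,
                              log2_ratio_sd = 0.88,
                              ref_count_lambda = 0.83,
                              k = 2,
                              link_only_frac = 0.1,
                              synth_og_frac = 0.02,
                              flowering_og_frac = 0.01,
                              branch_noise_sd = 0,
                              n_conditions = 14L,
                              n_expr_clusters = 3L,
                              nb_mean = 50,
                              nb_dispersion = 0.3,
                              n_zero_genes = 3L,
                              n_chromosomes = 20L,
                              chromosome_length = 5e6,
                              genes_per_chrom = 300L,
                              gene_length = 3000L,
                              gene_spacing = 10000L,
                              cluster_chrom = "Chr16",
                              cluster_start = 2e6,
                              cluster_span = 1e6,
                              cluster_size = 60L,
                              background_flag_rate = 0.02,
                              n_snp_cds = 30L,
                              n_snp_genic_noncoding = 30L,
                              n_snp_promoter = 30L,
                              n_snp_outside = 10L,
                              n_sv_body = 10L,
                              n_sv_promoter = 5L,
                              n_sv_none = 5L,
                              promoter_length = 1000L) {
  if (log2_ratio_sd < 0) stop("log2_ratio_sd must be non-negative")
  if (branch_noise_sd < 0 || nb_dispersion < 0 || background_flag_rate < 0) {
    stop("rates and noise parameters must be non-negative")
  }
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic orthologue-group universe
#'
#' Per-OG reference counts are 1 + Poisson(lambda); target counts are
#' `max(1, round(n_ref * 2^z))` with `z ~ N(mean, sd)`, so realized log2
#' ratios follow the configured law up to integer rounding (checked to
#' recover mean and SD within 3 standard errors at the default size). True
#' OG classes (rich/less/typical) are recorded from the generating `z`.
#' Also emits the assignment-stage inputs: a membership table, an
#' annotation-link table (a fraction of target genes are link-only, a
#' fraction of OGs exercise the synthesized-ID path) and a flowering list,
#' plus the expected unified OG per gene.
#'
#' @param config A `sim_config`.
#' @return List: `counts` (og_id, n_reference, n_target), `genes` (catalogue
#'   with expected merged OG and source), `memberships`, `links`,
#'   `flowering`, `truth` (per-OG generating ratio and true class).
#' @export
generate_og_universe <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "og_universe"))
  n <- config$n_ogs
  if (n < 2) stop("n_ogs must be at least 2")
  n_ref <- 1L + stats::rpois(n, config$ref_count_lambda)
  z <- stats::rnorm(n, config$log2_ratio_mean, config$log2_ratio_sd)
  n_tgt <- pmax(1L, as.integer(round(n_ref * 2^z)))
  og_id <- sprintf("OG5_S%05d", seq_len(n))
  counts <- data.frame(og_id = og_id, n_reference = n_ref,
                       n_target = n_tgt, stringsAsFactors = FALSE)
  true_class <- rep("typical", n)
  true_class[z > config$log2_ratio_mean + config$k * config$log2_ratio_sd] <- "rich"
  true_class[z < config$log2_ratio_mean - config$k * config$log2_ratio_sd] <- "less"
  truth <- data.frame(og_id = og_id, generating_log2 = z,
                      realized_log2 = log2(n_tgt / n_ref),
                      true_class = true_class, stringsAsFactors = FALSE)

  ref_ids <- sprintf("AT%dG%05d", 1 + (seq_len(sum(n_ref)) %% 5),
                     10 * seq_len(sum(n_ref)))
  tgt_ids <- sprintf("Glyma%02dg%05d", 1 + (seq_len(sum(n_tgt)) %% 20),
                     10 * seq_len(sum(n_tgt)))
  genes <- data.frame(
    gene_id = c(ref_ids, tgt_ids),
    species = c(rep("reference", sum(n_ref)), rep("target", sum(n_tgt))),
    og_id = c(rep(og_id, n_ref), rep(og_id, n_tgt)),
    stringsAsFactors = FALSE)

  # assignment-stage inputs: link-only targets, synthesized-OG cases
  genes$expected_og <- genes$og_id
  genes$source <- "membership"
  synth_ogs <- sample(og_id, max(0L, round(config$synth_og_frac * n)))
  for (og in synth_ogs) {
    idx <- which(genes$og_id == og)
    refs <- idx[genes$species[idx] == "reference"]
    tgts <- idx[genes$species[idx] == "target"]
    anchor <- genes$gene_id[refs[1]]
    sid <- paste0("OG5_", anchor)
    genes$expected_og[c(refs[1], tgts)] <- sid
    genes$source[refs[1]] <- "synthesized"
    genes$source[tgts] <- "link"
  }
  normal_ogs <- setdiff(og_id, synth_ogs)
  cand <- which(genes$species == "target" & genes$og_id %in% normal_ogs)
  link_only <- sample(cand, round(config$link_only_frac * length(cand)))
  genes$source[link_only] <- "link"

  first_ref <- tapply(genes$gene_id[genes$species == "reference"],
                      genes$og_id[genes$species == "reference"],
                      function(x) x[1])
  linked <- genes$source == "link"
  links <- data.frame(target_gene = genes$gene_id[linked],
                      reference_gene = unname(first_ref[genes$og_id[linked]]),
                      stringsAsFactors = FALSE)
  in_member <- genes$source == "membership" |
    (genes$source == "link" & !genes$og_id %in% synth_ogs)
  # link-only targets of normal OGs keep no membership row; synthesized-OG
  # members (ref and targets) have none either, except extra refs
  keep <- genes$source == "membership"
  memberships <- data.frame(gene_id = genes$gene_id[keep],
                            og_id = genes$og_id[keep],
                            stringsAsFactors = FALSE)

  flowering_ogs <- sample(og_id, max(1L, round(config$flowering_og_frac * n)))
  # list most, not all, reference genes of flowering OGs, so some members
  # remain "additional" flowering candidates found by co-membership
  flowering <- unlist(lapply(flowering_ogs, function(og) {
    refs <- genes$gene_id[genes$species == "reference" & genes$og_id == og]
    keep <- stats::runif(length(refs)) < 0.8
    if (!any(keep)) keep[1] <- TRUE
    refs[keep]
  }))
  list(counts = counts, genes = genes, memberships = memberships,
       links = links, flowering = flowering,
       flowering_ogs = sort(flowering_ogs), truth = truth)
}

# internal: join subtrees ultrametrically; x is list of (label-or-newick, height)
.join_random <- function(nodes, step) {
  while (length(nodes) > 1) {
    pick <- sample(length(nodes), 2)
    a <- nodes[[pick[1]]]; b <- nodes[[pick[2]]]
    h <- max(a$h, b$h) + step
    merged <- list(
      str = sprintf("(%s:%s,%s:%s)", a$str, format(h - a$h, digits = 10),
                    b$str, format(h - b$h, digits = 10)),
      h = h)
    nodes <- c(nodes[-pick], list(merged))
  }
  nodes[[1]]
}

#' Simulate a gene tree with known orthology
#'
#' Emulates duplication-driven gene-family structure inside one OG: each
#' target gene descends from (is planted as the orthologue of) one reference
#' gene; the tree is built ultrametrically with within-orthologue joins far
#' shallower than the backbone joining orthologue clades, so at zero branch
#' noise the closest reference gene of every target leaf is its planted
#' anchor and the clade rule recovers it exactly. Additive Gaussian noise
#' (truncated at 0) perturbs every branch when `branch_noise_sd > 0`.
#'
#' @param members Data frame with `gene_id`, `species` (the OG members).
#' @param config A `sim_config` (uses `branch_noise_sd` and the tree seed
#'   stream; pass a distinct `seed` per OG for independent trees).
#' @return List: `tree` ([ape::phylo]), `newick` (text), `truth`
#'   (data frame `target_gene`, `true_anchor`).
#' @export
generate_gene_tree <- function(members, config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  .need_cols(members, c("gene_id", "species"), "members")
  if (nrow(members) < 2) stop("need at least 2 members for a tree")
  set.seed(derive_seed(config$seed, "trees"))
  refs <- members$gene_id[members$species == "reference"]
  tgts <- members$gene_id[members$species == "target"]

  if (length(refs) == 0) {
    all <- lapply(members$gene_id, function(x) list(str = x, h = 0))
    root <- .join_random(all, step = 0.1)
    truth <- data.frame(target_gene = tgts,
                        true_anchor = NA_character_,
                        stringsAsFactors = FALSE)
  } else {
    anchor <- refs[sample.int(length(refs), length(tgts), replace = TRUE)]
    clades <- lapply(refs, function(r) {
      tips <- c(r, tgts[anchor == r])
      .join_random(lapply(tips, function(x) list(str = x, h = 0)), step = 0.1)
    })
    root <- .join_random(clades, step = 5)
    truth <- data.frame(target_gene = tgts, true_anchor = anchor,
                        stringsAsFactors = FALSE)
  }
  newick <- paste0(root$str, ";")
  tree <- ape::read.tree(text = newick)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  if (config$branch_noise_sd > 0) {
    tree$edge.length <- pmax(
      0, tree$edge.length + stats::rnorm(length(tree$edge.length),
                                         0, config$branch_noise_sd))
  }
  newick <- ape::write.tree(tree)
  list(tree = tree, newick = newick, truth = truth)
}

#' Simulate an expression matrix with planted co-expression clusters
#'
#' Genes of a planted cluster share a condition-profile template (a distinct
#' block of high-expression conditions per cluster); counts are drawn
#' negative-binomially around the template. With `nb_dispersion = 0` counts
#' equal the (rounded) template exactly. A configurable number of genes is
#' forced all-zero to exercise inactivity calls. The first condition is the
#' flower tissue.
#'
#' @param config A `sim_config`.
#' @param gene_ids Optional gene IDs; defaults to
#'   `n_expr_clusters * 10 + n_zero_genes` synthetic IDs.
#' @return List: `em` (an `expr_matrix`, rule `raw_reads`), `labels` (named
#'   planted-cluster labels, 0 for forced-zero genes), `zero_genes`.
#' @export
generate_expression <- function(config = simulation_config(),
                                gene_ids = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "expression"))
  kcl <- config$n_expr_clusters
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("Glyma%02dg%05d", 1 + (seq_len(kcl * 10 + config$n_zero_genes) %% 20),
                        77000 + 10 * seq_len(kcl * 10 + config$n_zero_genes))
  }
  n_genes <- length(gene_ids)
  if (kcl > n_genes) stop("more clusters than genes")
  nc <- config$n_conditions
  conds <- c("flower", sprintf("tissue%02d", seq_len(nc - 1)))
  n_zero <- min(config$n_zero_genes, n_genes - 1)
  labels <- c(rep(seq_len(kcl), length.out = n_genes - n_zero),
              rep(0L, n_zero))
  names(labels) <- gene_ids
  # distinct high-expression condition block per cluster
  blocks <- split(seq_len(nc), cut(seq_len(nc), kcl, labels = FALSE))
  m <- matrix(0, n_genes, nc, dimnames = list(gene_ids, conds))
  for (i in seq_len(n_genes)) {
    if (labels[i] == 0) next
    mu <- rep(0.5, nc)
    mu[blocks[[labels[i]]]] <- config$nb_mean
    if (config$nb_dispersion == 0) {
      m[i, ] <- round(mu)
    } else {
      m[i, ] <- stats::rnbinom(nc, mu = mu, size = 1 / config$nb_dispersion)
    }
  }
  em <- expression_matrix(m, rule = "raw_reads", flower_conditions = "flower")
  list(em = em, labels = labels,
       zero_genes = gene_ids[labels == 0])
}

#' Simulate gene coordinates, a planted gene cluster, and variant tables
#'
#' Genes are placed without overlap on a uniform grid across the configured
#' chromosomes, each with two CDS exons separated by an intron. A planted
#' cluster of flagged (paralogue-rich) genes occupies a configured span on
#' one chromosome, with background genes flagged at a low rate elsewhere.
#' SNPs are planted with known per-category counts (CDS, intronic,
#' promoter, intergenic) relative to a paired gene; SVs are planted to
#' overlap a gene body, a promoter only, or nothing. Per-gene SV overlap
#' truth is recorded by direct interval arithmetic over all genes.
#'
#' @param config A `sim_config`.
#' @return List: `genes` (catalogue with `og_id` and `flagged`), `models`
#'   (a `gene_models`), `snps`, `svs`, `snp_truth` (paired gene and true
#'   category per SNP), `sv_truth` (per-gene body/promoter overlap flags),
#'   `cluster` (the planted span), `chrom_lengths`.
#' @export
generate_genome_and_variants <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "genome"))
  gpc <- config$genes_per_chrom
  if (config$gene_spacing * gpc + 2 * config$promoter_length >
      config$chromosome_length) {
    stop("infeasible packing: chromosome too short for the gene grid")
  }
  if (config$gene_length + 2 * config$promoter_length >= config$gene_spacing) {
    stop("infeasible packing: gene_spacing too small for gene plus promoter")
  }
  chroms <- sprintf("Chr%02d", seq_len(config$n_chromosomes))
  if (!config$cluster_chrom %in% chroms) {
    stop("cluster_chrom not among the simulated chromosomes")
  }
  genes <- do.call(rbind, lapply(chroms, function(ch) {
    start <- config$promoter_length + 1 +
      (seq_len(gpc) - 1) * config$gene_spacing
    data.frame(
      gene_id = sprintf("Glyma%sg%05d", sub("Chr", "", ch),
                        10 * seq_len(gpc)),
      chrom = ch, start = start, end = start + config$gene_length - 1,
      strand = sample(c("+", "-"), gpc, replace = TRUE),
      stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL

  span_lo <- config$cluster_start
  span_hi <- config$cluster_start + config$cluster_span - 1
  in_span <- genes$chrom == config$cluster_chrom &
    genes$start >= span_lo & genes$start <= span_hi
  if (sum(in_span) < config$cluster_size) {
    stop("infeasible packing: planted span holds fewer genes than cluster_size")
  }
  flagged <- rep(FALSE, nrow(genes))
  planted <- sample(which(in_span), config$cluster_size)
  flagged[planted] <- TRUE
  off <- which(!in_span)
  bg <- sample(off, round(config$background_flag_rate * length(off)))
  flagged[bg] <- TRUE
  genes$og_id <- "OG5_SIMBG"
  genes$og_id[planted] <- rep(c("OG5_SIMRICH1", "OG5_SIMRICH2"),
                              length.out = length(planted))
  genes$og_id[bg] <- "OG5_SIMRICH3"
  genes$flagged <- flagged

  # two CDS exons with an intron between them
  cds <- rbind(
    data.frame(gene_id = genes$gene_id, start = genes$start,
               end = genes$start + 999, stringsAsFactors = FALSE),
    data.frame(gene_id = genes$gene_id, start = genes$start + 2000,
               end = genes$end, stringsAsFactors = FALSE))
  chrom_lengths <- stats::setNames(rep(config$chromosome_length,
                                       length(chroms)), chroms)
  models <- gene_models(genes[, c("gene_id", "chrom", "start", "end",
                                  "strand")],
                        cds, promoter_length = config$promoter_length,
                        chrom_lengths = chrom_lengths)

  set.seed(derive_seed(config$seed, "variants"))
  g <- models$genes
  plant_snp <- function(n, category) {
    if (n == 0) {
      return(data.frame(chrom = character(), pos = integer(),
                        gene_id = character(), true_category = character()))
    }
    idx <- sample(nrow(g), n, replace = TRUE)
    pos <- vapply(idx, function(i) {
      switch(category,
        CDS = g$start[i] + sample.int(1000, 1) - 1L,
        genic_noncoding = g$start[i] + 1000L + sample.int(1000, 1) - 1L,
        promoter = g$prom_start[i] +
          sample.int(g$prom_end[i] - g$prom_start[i] + 1L, 1) - 1L,
        outside = g$end[i] + config$promoter_length + sample.int(1000, 1))
    }, numeric(1))
    data.frame(chrom = g$chrom[idx], pos = as.integer(pos),
               gene_id = g$gene_id[idx], true_category = category,
               stringsAsFactors = FALSE)
  }
  snp_truth <- rbind(plant_snp(config$n_snp_cds, "CDS"),
                     plant_snp(config$n_snp_genic_noncoding, "genic_noncoding"),
                     plant_snp(config$n_snp_promoter, "promoter"),
                     plant_snp(config$n_snp_outside, "outside"))
  snp_truth$id <- sprintf("snp%04d", seq_len(nrow(snp_truth)))
  snps <- snp_truth[, c("chrom", "pos", "id")]

  sv_types <- c("deletion", "insertion", "inversion")
  plant_sv <- function(n, where) {
    if (n == 0) {
      return(data.frame(chrom = character(), start = integer(),
                        end = integer(), type = character()))
    }
    idx <- sample(nrow(g), n, replace = TRUE)
    s <- integer(n); e <- integer(n)
    for (j in seq_len(n)) {
      i <- idx[j]
      if (where == "body") {
        s[j] <- g$start[i] + 100L; e[j] <- s[j] + 500L
      } else if (where == "promoter") {
        s[j] <- g$prom_start[i]; e[j] <- g$prom_start[i] + 200L
      } else {
        s[j] <- g$end[i] + config$promoter_length + 1500L
        e[j] <- s[j] + 200L
      }
    }
    data.frame(chrom = g$chrom[idx], start = s, end = e,
               type = sample(sv_types, n, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  svs <- rbind(plant_sv(config$n_sv_body, "body"),
               plant_sv(config$n_sv_promoter, "promoter"),
               plant_sv(config$n_sv_none, "none"))
  svs$id <- sprintf("sv%04d", seq_len(nrow(svs)))
  # per-gene overlap truth by direct interval arithmetic
  sv_truth <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
    same <- svs$chrom == g$chrom[i]
    body <- same & svs$start <= g$end[i] & svs$end >= g$start[i]
    prom <- same & !is.na(g$prom_start[i]) &
      svs$start <= g$prom_end[i] & svs$end >= g$prom_start[i]
    data.frame(gene_id = g$gene_id[i],
               body_overlap = any(body),
               promoter_overlap = any(prom),
               stringsAsFactors = FALSE)
  }))
  list(genes = genes, models = models, snps = snps, svs = svs,
       snp_truth = snp_truth, sv_truth = sv_truth,
       cluster = list(chrom = config$cluster_chrom, start = span_lo,
                      end = span_hi,
                      planted_genes = genes$gene_id[planted]),
       chrom_lengths = chrom_lengths)
}

#' Write a complete fixture bundle to disk
#'
#' Emits every file the pipeline stages consume — membership/link/flowering
#' TSVs, per-OG Newick trees, expression TSV, gene coordinate TSV and GFF3,
#' variant TSV — plus ground-truth TSVs, all plain text. Files round-trip
#' through the package's own readers.
#'
#' @param config A `sim_config`.
#' @param dir Output directory (created if needed).
#' @param n_trees Number of small OGs to emit trees for (kept modest so the
#'   bundle stays light).
#' @return Invisibly, a list of the generated objects and file paths.
#' @export
write_fixture_bundle <- function(config = simulation_config(), dir,
                                 n_trees = 20L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  uni <- generate_og_universe(config)
  write_tsv6(uni$memberships, file.path(dir, "memberships.tsv"))
  write_tsv6(uni$links, file.path(dir, "links.tsv"))
  write_tsv6(data.frame(gene_id = uni$flowering), file.path(dir, "flowering.tsv"))
  write_tsv6(uni$counts, file.path(dir, "og_counts.tsv"))
  write_tsv6(uni$truth, file.path(dir, "og_truth.tsv"))
  write_tsv6(uni$genes, file.path(dir, "og_genes.tsv"))

  tree_dir <- file.path(dir, "trees")
  dir.create(tree_dir, showWarnings = FALSE)
  # trees for the first OGs with >= 4 members and both species
  sizes <- table(uni$genes$og_id)
  cand <- names(sizes)[sizes >= 4]
  cand <- cand[cand %in% uni$genes$og_id[uni$genes$species == "reference"] &
                 cand %in% uni$genes$og_id[uni$genes$species == "target"]]
  # flowering OGs first: they are the ones the clade rule is for
  cand <- c(sort(intersect(cand, uni$flowering_ogs)),
            sort(setdiff(cand, uni$flowering_ogs)))
  cand <- utils::head(cand, n_trees)
  tree_truth <- list()
  for (i in seq_along(cand)) {
    og <- cand[i]
    members <- uni$genes[uni$genes$og_id == og, c("gene_id", "species")]
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    gt <- generate_gene_tree(members, cfg_i)
    writeLines(gt$newick, file.path(tree_dir, paste0(og, ".nwk")))
    if (nrow(gt$truth)) {
      gt$truth$og_id <- og
      tree_truth[[og]] <- gt$truth
    }
  }
  tt <- if (length(tree_truth)) do.call(rbind, tree_truth) else
    data.frame(target_gene = character(), true_anchor = character(),
               og_id = character())
  rownames(tt) <- NULL
  write_tsv6(tt, file.path(dir, "tree_truth.tsv"))

  expr <- generate_expression(config)
  edf <- data.frame(gene_id = rownames(expr$em$values), expr$em$values,
                    check.names = FALSE)
  write_tsv6(edf, file.path(dir, "expression.tsv"))
  write_tsv6(data.frame(gene_id = names(expr$labels),
                        cluster = unname(expr$labels)),
             file.path(dir, "expression_truth.tsv"))

  gen <- generate_genome_and_variants(config)
  write_tsv6(gen$genes, file.path(dir, "genes.tsv"))
  g <- gen$genes
  gff <- c("##gff-version 3",
           sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   g$chrom, g$start, g$end, g$strand, g$gene_id),
           sprintf("%s\tsim\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                   rep(g$chrom, 2),
                   c(g$start, g$start + 2000L), c(g$start + 999L, g$end),
                   rep(g$strand, 2), rep(g$gene_id, 2)))
  writeLines(gff, file.path(dir, "genes.gff3"))
  vtab <- rbind(
    data.frame(chrom = gen$snps$chrom, start = gen$snps$pos,
               end = gen$snps$pos, type = "SNP", id = gen$snps$id,
               stringsAsFactors = FALSE),
    gen$svs[, c("chrom", "start", "end", "type", "id")])
  write_tsv6(vtab, file.path(dir, "variants.tsv"))
  write_tsv6(gen$snp_truth, file.path(dir, "snp_truth.tsv"))
  write_tsv6(gen$sv_truth, file.path(dir, "sv_truth.tsv"))
  invisible(list(universe = uni, expression = expr, genome = gen,
                 dir = dir, tree_ogs = cand))
}
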
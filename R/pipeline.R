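#' Build a pipeline configuration
#'
#' Collects input paths, stage toggles and parameters for [run_pipeline()].
#' Inputs are validated lazily at run time (fail-fast before any stage
#' executes).
#'
#' @param out_dir Output directory.
#' @param stages Stages to run, in dependency order a subset of
#'   `c("assign", "classify", "express", "paralogue", "distribute",
#'   "variants")`.
#' @param inputs Named list of input paths: `links`, `memberships`,
#'   `flowering` (assign); `trees_dir` (classify); `expression` (express);
#'   `genes` (distribute); `gff`, `variants` (variants); optional
#'   `pct_duplicated`, `flags`, `subset`.
#' @param params Named list of parameters; recognised: `tolerance` (1e-9),
#'   `k` (2), `window` (1400000), `step` (100000), `promoter_length` (1000),
#'   `expression_rule` ("raw_reads"), `flower_conditions` ("flower"),
#'   `cut_k` (3), `include_promoter` (TRUE).
#' @param seed Integer seed recorded in the manifest (the pipeline stages
#'   are deterministic; the seed matters only when inputs are simulated).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, stages = c("assign", "classify",
                                                "express", "paralogue",
                                                "distribute", "variants"),
                            inputs = list(), params = list(), seed = 1L) {
  defaults <- list(tolerance = 1e-9, k = 2, window = 1400000, step = 100000,
                   promoter_length = 1000, expression_rule = "raw_reads",
                   flower_conditions = "flower", cut_k = 3,
                   include_promoter = TRUE)
  params <- utils::modifyList(defaults, params)
  known <- c("assign", "classify", "express", "paralogue", "distribute",
             "variants")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(list(out_dir = out_dir, stages = stages, inputs = inputs,
                 params = params, seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with keys `out_dir`, `stages`, `inputs`, `params`,
#'   `seed`.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the yaml package")
  }
  y <- yaml::read_yaml(path)
  pipeline_config(out_dir = y$out_dir,
                  stages = y$stages %||% c("assign", "classify", "express",
                                           "paralogue", "distribute",
                                           "variants"),
                  inputs = y$inputs %||% list(),
                  params = y$params %||% list(),
                  seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# required input keys per stage
.stage_inputs <- list(
  assign = c("links", "memberships", "flowering"),
  classify = c("trees_dir"),
  express = c("expression"),
  paralogue = character(),          # consumes the assign stage's output
  distribute = c("genes"),
  variants = c("gff", "variants")
)

#' Run the pipeline end to end
#'
#' Executes the enabled stages in dependency order (assign, classify,
#' express, paralogue, distribute, variants), writing one TSV per product
#' into the output directory and a JSON run manifest recording the package
#' version, parameters, input checksums and per-stage row counts. All float
#' output is serialised at 6 significant digits, so re-running on identical
#' inputs reproduces byte-identical files. Validation is fail-fast: missing
#' inputs for any enabled stage abort before the first stage runs.
#'
#' @param config A `pipeline_config` or the path to a YAML config.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  order <- c("assign", "classify", "express", "paralogue", "distribute",
             "variants")
  stages <- order[order %in% config$stages]

  # fail fast: every enabled stage's inputs must exist before anything runs
  for (st in stages) {
    for (key in .stage_inputs[[st]]) {
      p <- config$inputs[[key]]
      if (is.null(p) || !file.exists(p)) {
        stop("stage '", st, "' is enabled but input '", key,
             "' is missing", if (!is.null(p)) paste0(" (", p, ")"))
      }
    }
    if (st %in% c("classify", "paralogue") && !"assign" %in% stages) {
      stop("stage '", st, "' requires the assign stage")
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  cat("", file = log_path)
  logln <- function(...) {
    cat(sprintf("[%s] %s\n", format(Sys.time(), "%H:%M:%S"),
                paste0(...)), file = log_path, append = TRUE)
  }
  manifest <- list(
    package = "orthoflora",
    version = as.character(utils::packageVersion("orthoflora")),
    seed = config$seed,
    parameters = config$params,
    inputs = lapply(Filter(function(p) is.character(p) && file.exists(p) &&
                             !dir.exists(p), config$inputs),
                    function(p) unname(tools::md5sum(p))),
    stages = list()
  )
  p <- config$params
  out <- function(name) file.path(config$out_dir, name)
  state <- new.env(parent = emptyenv())

  for (st in stages) {
    t0 <- Sys.time()
    rows <- switch(st,
      assign = {
        links <- read_tsv(config$inputs$links)
        memberships <- read_tsv(config$inputs$memberships)
        flowering <- read_tsv(config$inputs$flowering)[[1]]
        merged <- merge_og_assignments(links, memberships)
        flo <- flag_flowering_ogs(merged$assignments, flowering)
        write_tsv6(merged$assignments, out("og_map.tsv"))
        write_tsv6(flo$ogs, out("flowering_ogs.tsv"))
        write_tsv6(og_count_table(merged$assignments), out("og_counts.tsv"))
        state$assignments <- merged$assignments
        state$flowering <- flowering
        state$flowering_ogs <- flo$ogs$og_id[flo$ogs$contains_flowering]
        nrow(merged$assignments)
      },
      classify = {
        trees <- list.files(config$inputs$trees_dir, pattern = "\\.nwk$",
                            full.names = TRUE)
        res <- list()
        for (tf in trees) {
          og <- sub("\\.nwk$", "", basename(tf))
          members <- state$assignments[state$assignments$og_id == og,
                                       c("gene_id", "species")]
          if (nrow(members) == 0) next
          tree <- parse_newick(file = tf)
          cls <- classify_og(members, tree, state$flowering,
                             tolerance = p$tolerance)
          if (nrow(cls)) { cls$og_id <- og; res[[og]] <- cls }
        }
        # small flowering OGs without trees
        sizes <- table(state$assignments$og_id)
        small <- intersect(names(sizes)[sizes < 4], state$flowering_ogs)
        small <- setdiff(small, names(res))
        for (og in small) {
          members <- state$assignments[state$assignments$og_id == og,
                                       c("gene_id", "species")]
          cls <- classify_og(members, NULL, state$flowering)
          if (nrow(cls)) { cls$og_id <- og; res[[og]] <- cls }
        }
        cls <- if (length(res)) do.call(rbind, res) else
          data.frame(target_gene = character(), status = character(),
                     og_id = character())
        rownames(cls) <- NULL
        write_tsv6(cls, out("clade_assignments.tsv"))
        nrow(cls)
      },
      express = {
        em <- read_expression_tsv(config$inputs$expression,
                                  rule = p$expression_rule,
                                  flower_conditions = p$flower_conditions)
        calls <- flag_flower_expressed(call_active(em), em)
        write_tsv6(calls, out("activity.tsv"))
        z <- zscore_rows(em)
        write_tsv6(data.frame(gene_id = rownames(z), z, check.names = FALSE),
                   out("zscores.tsv"))
        active <- calls$gene_id[calls$active]
        if (length(active) >= 2) {
          dend <- hierarchical_cluster(em$values[active, , drop = FALSE])
          writeLines(dendrogram_newick(dend), out("dendrogram.nwk"))
          k <- min(p$cut_k, length(active))
          cl <- cut_clusters(dend, k = k)
          write_tsv6(data.frame(gene_id = names(cl), cluster = unname(cl)),
                     out("clusters.tsv"))
        }
        nrow(calls)
      },
      paralogue = {
        counts <- og_count_table(state$assignments)
        rat <- compute_ratios(counts)
        summ <- distribution_summary(rat$ratios, k = p$k)
        classed <- classify_paralogue(rat$ratios, summ)
        write_tsv6(classed, out("ratios.tsv"))
        write_tsv6(rat$excluded, out("ratios_excluded.tsv"))
        write_tsv6(data.frame(mean_log2 = summ$mean_log2,
                              sd_log2 = summ$sd_log2, n_ogs = summ$n_ogs,
                              k = summ$k, upper = summ$upper,
                              lower = summ$lower,
                              fold_upper = summ$fold_upper,
                              fold_lower = summ$fold_lower),
                   out("ratio_summary.tsv"))
        state$rich_ogs <- classed$og_id[classed$class == "rich"]
        nrow(classed)
      },
      distribute = {
        genes <- read_tsv(config$inputs$genes)
        flagged <- if (!is.null(config$inputs$flags)) {
          read_tsv(config$inputs$flags)[[1]]
        } else if ("flagged" %in% names(genes)) {
          genes$gene_id[as.logical(genes$flagged)]
        } else if (!is.null(state$rich_ogs) && "og_id" %in% names(genes)) {
          genes$gene_id[genes$og_id %in% state$rich_ogs]
        } else {
          stop("distribute stage: no flagged-gene source available")
        }
        pct <- if (!is.null(config$inputs$pct_duplicated)) {
          read_tsv(config$inputs$pct_duplicated)
        } else NULL
        summ <- per_chromosome_fraction(genes, flagged, pct)
        if (!is.null(pct) && nrow(summ) >= 3) {
          summ_r <- pearson_r(summ$fraction, summ$pct_duplicated)
          write_tsv6(data.frame(pearson_r = summ_r), out("fraction_vs_dup.tsv"))
        }
        write_tsv6(summ, out("chromosome_summary.tsv"))
        wins <- window_scan(genes, flagged, window_size = p$window,
                            step = p$step)
        write_tsv6(wins, out("windows.tsv"))
        nrow(summ)
      },
      variants = {
        models <- read_gene_models_gff3(config$inputs$gff,
                                        promoter_length = p$promoter_length)
        vars <- read_variants_tsv(config$inputs$variants)
        rep <- gene_variant_report(vars$snps, models)
        write_tsv6(rep, out("snp_report.tsv"))
        cen <- census_noncoding_only(rep)
        write_tsv6(data.frame(count = cen$count,
                              n_universe = cen$n_universe,
                              percentage = cen$percentage),
                   out("snp_census.tsv"))
        svf <- sv_overlap(vars$svs, models,
                          include_promoter = p$include_promoter)
        write_tsv6(svf, out("sv_flags.tsv"))
        if (!is.null(config$inputs$subset)) {
          subset <- read_tsv(config$inputs$subset)[[1]]
          flagged_genes <- svf$gene_id[svf$sv_overlap_types != ""]
          et <- enrichment_test(
            sum(subset %in% flagged_genes), length(subset),
            length(flagged_genes), nrow(svf))
          write_tsv6(data.frame(odds_ratio = et$odds_ratio,
                                p_value = et$p_value),
                     out("sv_enrichment.tsv"))
        }
        nrow(rep)
      })
    manifest$stages[[st]] <- list(rows_out = rows)
    logln(sprintf("stage %-10s rows_out=%d wall=%.2fs", st, rows,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
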
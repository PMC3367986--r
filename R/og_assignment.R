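#' Select the longest isoform per locus
#'
#' Protein-level comparative analyses use one representative sequence per
#' locus; the representative is the longest isoform, with length ties broken
#' by the lexicographically smallest isoform identifier so the choice is
#' deterministic.
#'
#' @param isoforms_by_locus Named list; each element is a named character
#'   vector of protein sequences for one locus (names are isoform IDs).
#' @return Named character vector of one sequence per locus, with the chosen
#'   isoform IDs in attribute `"isoform_id"`.
#' @export
select_longest_isoform <- function(isoforms_by_locus) {
  if (!is.list(isoforms_by_locus) || is.null(names(isoforms_by_locus))) {
    stop("isoforms_by_locus must be a named list")
  }
  chosen <- character(length(isoforms_by_locus))
  ids <- character(length(isoforms_by_locus))
  for (i in seq_along(isoforms_by_locus)) {
    locus <- names(isoforms_by_locus)[i]
    seqs <- isoforms_by_locus[[i]]
    if (length(seqs) == 0) {
      stop("locus '", locus, "' has an empty isoform list")
    }
    if (is.null(names(seqs))) {
      names(seqs) <- paste0(locus, ".", seq_along(seqs))
    }
    len <- nchar(seqs)
    best <- which(len == max(len))
    # tie: lexicographically smallest isoform ID
    pick <- best[order(names(seqs)[best])][1]
    chosen[i] <- seqs[[pick]]
    ids[i] <- names(seqs)[pick]
  }
  names(chosen) <- names(isoforms_by_locus)
  attr(chosen, "isoform_id") <- ids
  chosen
}

#' Read isoform sequences from FASTA, grouped by locus
#'
#' Sequence names of the form `<locus>.<n>` are grouped under `<locus>`;
#' names without an isoform suffix are their own locus.
#'
#' @param path FASTA file path.
#' @param isoform_pattern Regular expression removed from a sequence name to
#'   obtain its locus.
#' @return Named list of named character vectors, ready for
#'   [select_longest_isoform()].
#' @export
read_isoforms_fasta <- function(path, isoform_pattern = "\\.\\d+$") {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package")
  }
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  locus <- sub(isoform_pattern, "", names(seqs))
  split(seqs, locus)
}

#' Unify annotation homologue links with orthologue-group memberships
#'
#' Two sources place genes into orthologue groups (OGs): a per-gene
#' annotation link (target gene -> closest reference gene) and a pre-computed
#' OG membership table. A linked target gene inherits its reference gene's
#' OG; link-derived assignment takes precedence over the target gene's own
#' membership. A reference gene that is linked but has no membership OG is
#' given a synthesised ID `"OG5_" + locus`, and its linked target genes join
#' it. Genes with neither a link nor a membership are reported unassigned.
#'
#' @param links Data frame with columns `target_gene`, `reference_gene`;
#'   at most one row per target gene.
#' @param memberships Data frame with columns `gene_id`, `og_id`, or a named
#'   character vector mapping gene to OG.
#' @param genes Optional catalogue of known gene IDs (character vector or a
#'   data frame with a `gene_id` column). When supplied, a link naming a gene
#'   outside the catalogue is an error.
#' @param species_prefixes Prefix map for species inference.
#' @return List with `assignments` (data frame `gene_id`, `species`, `og_id`,
#'   `source` in \{link, membership, synthesized\}), `synthesized_ogs`
#'   (character vector of new OG IDs) and `unassigned` (gene IDs with
#'   neither link nor membership).
#' @export
merge_og_assignments <- function(links, memberships, genes = NULL,
                                 species_prefixes = default_species_prefixes()) {
  if (is.data.frame(memberships)) {
    .need_cols(memberships, c("gene_id", "og_id"), "memberships")
    member_map <- stats::setNames(as.character(memberships$og_id),
                                  as.character(memberships$gene_id))
  } else {
    member_map <- memberships
  }
  if (anyDuplicated(names(member_map))) {
    stop("memberships assigns some gene to more than one OG")
  }
  if (nrow(as.data.frame(links)) > 0) {
    .need_cols(links, c("target_gene", "reference_gene"), "links")
  } else {
    links <- data.frame(target_gene = character(), reference_gene = character())
  }
  dup <- unique(links$target_gene[duplicated(links$target_gene)])
  if (length(dup)) {
    stop("multiple links for target gene(s): ", paste(dup, collapse = ", "))
  }
  if (!is.null(genes)) {
    known <- if (is.data.frame(genes)) genes$gene_id else genes
    bad <- setdiff(unique(c(links$target_gene, links$reference_gene)), known)
    if (length(bad)) {
      stop("link names unknown gene(s): ", paste(bad, collapse = ", "))
    }
  }

  all_genes <- unique(c(names(member_map), links$target_gene,
                        links$reference_gene,
                        if (is.data.frame(genes)) genes$gene_id else genes))
  og <- unname(member_map[all_genes])
  names(og) <- all_genes
  src <- ifelse(is.na(og), NA_character_, "membership")
  names(src) <- all_genes

  input_ogs <- unique(unname(member_map))
  synthesized <- character(0)
  for (i in seq_len(nrow(links))) {
    tg <- links$target_gene[i]
    rg <- links$reference_gene[i]
    ref_og <- unname(member_map[rg])
    if (is.na(ref_og)) {
      sid <- paste0("OG5_", rg)
      if (sid %in% input_ogs) {
        stop("synthesized OG ID collides with an input OG ID: ", sid)
      }
      if (!sid %in% synthesized) synthesized <- c(synthesized, sid)
      if (is.na(og[rg]) || src[rg] == "synthesized") {
        og[rg] <- sid
        src[rg] <- "synthesized"
      }
      ref_og <- sid
    }
    # link precedence over the target gene's own membership
    og[tg] <- ref_og
    src[tg] <- "link"
  }

  assigned <- !is.na(og)
  assignments <- data.frame(
    gene_id = all_genes[assigned],
    species = infer_species(all_genes[assigned], species_prefixes),
    og_id = unname(og[assigned]),
    source = unname(src[assigned]),
    stringsAsFactors = FALSE
  )
  assignments <- assignments[order(assignments$gene_id), , drop = FALSE]
  rownames(assignments) <- NULL
  list(assignments = assignments,
       synthesized_ogs = sort(synthesized),
       unassigned = sort(all_genes[!assigned]))
}

#' Flag orthologue groups that contain listed flowering genes
#'
#' An OG is a flowering OG when at least one of its reference-species members
#' is on the curated flowering-gene list. Reference members of flowering OGs
#' that are not themselves listed are reported as additional reference genes
#' (candidates guilt-by-association). Listed genes found in no OG are
#' reported as orphans, not errors.
#'
#' @param assignments Data frame from [merge_og_assignments()] (`gene_id`,
#'   `species`, `og_id`).
#' @param flowering_list Character vector of reference-species gene IDs.
#' @return List with `ogs` (per-OG data frame: counts, `contains_flowering`,
#'   `additional_reference_genes` comma-separated), `summary` (named list of
#'   headline counts) and `orphans`.
#' @export
flag_flowering_ogs <- function(assignments, flowering_list) {
  .need_cols(assignments, c("gene_id", "species", "og_id"), "assignments")
  flowering_list <- unique(as.character(flowering_list))
  counts <- og_count_table(assignments)
  by_og <- split(assignments, assignments$og_id)
  is_flo <- logical(nrow(counts))
  addl <- character(nrow(counts))
  names(is_flo) <- names(addl) <- counts$og_id
  for (og in names(by_og)) {
    m <- by_og[[og]]
    refs <- m$gene_id[m$species == "reference"]
    listed <- intersect(refs, flowering_list)
    is_flo[og] <- length(listed) > 0
    if (is_flo[og]) {
      addl[og] <- paste(sort(setdiff(refs, flowering_list)), collapse = ",")
    }
  }
  ogs <- counts
  ogs$contains_flowering <- unname(is_flo[ogs$og_id])
  ogs$additional_reference_genes <- unname(addl[ogs$og_id])

  in_any_og <- flowering_list %in% assignments$gene_id
  flo_ogs <- ogs$og_id[ogs$contains_flowering]
  n_addl <- sum(vapply(strsplit(ogs$additional_reference_genes[ogs$contains_flowering],
                                ",", fixed = TRUE),
                       function(x) sum(nzchar(x)), integer(1)))
  n_target_flo <- sum(assignments$species == "target" &
                        assignments$og_id %in% flo_ogs, na.rm = TRUE)
  list(
    ogs = ogs,
    summary = list(
      n_flowering_listed = length(flowering_list),
      n_flowering_listed_in_ogs = sum(in_any_og),
      n_flowering_ogs = length(flo_ogs),
      n_additional_reference_genes = n_addl,
      n_target_genes_in_flowering_ogs = n_target_flo
    ),
    orphans = sort(flowering_list[!in_any_og])
  )
}

#' Per-OG gene counts by species
#'
#' @param assignments Data frame with `gene_id`, `species`, `og_id`.
#' @return Data frame (`og_id`, `n_reference`, `n_target`, `n_other`),
#'   sorted by `og_id`.
#' @export
og_count_table <- function(assignments) {
  .need_cols(assignments, c("gene_id", "species", "og_id"), "assignments")
  a <- assignments[!is.na(assignments$og_id), , drop = FALSE]
  if (nrow(a) == 0) {
    return(data.frame(og_id = character(), n_reference = integer(),
                      n_target = integer(), n_other = integer()))
  }
  sp <- factor(ifelse(is.na(a$species), "other", a$species),
               levels = c("reference", "target", "other"))
  tab <- table(a$og_id, sp)
  out <- data.frame(
    og_id = rownames(tab),
    n_reference = as.integer(tab[, "reference"]),
    n_target = as.integer(tab[, "target"]),
    n_other = as.integer(tab[, "other"]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$og_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
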
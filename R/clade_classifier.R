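#' Parse a Newick gene tree
#'
#' Thin validated front end over [ape::read.tree()]. The input must be a
#' single Newick statement terminated by `;` with balanced parentheses and
#' unique leaf names. Internal node labels (bootstrap support out of 1000
#' replicates in the trees this workflow consumes) are preserved but never
#' used for classification. Trees without branch lengths get zero-length
#' edges with a warning, so topology-only trees degrade to clade membership
#' without distance tie-breaking.
#'
#' @param text Newick string, or `NULL` when `file` is given.
#' @param file Path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply either text or file")
    text <- paste(readLines(file, warn = FALSE), collapse = "")
  }
  text <- trimws(text)
  if (!nzchar(text)) stop("empty Newick input")
  if (!endsWith(text, ";")) {
    stop("Newick parse error: statement does not end in ';'")
  }
  # parenthesis balance with position reporting
  depth <- 0L
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("Newick parse error: unmatched ')' at position ", i)
      }
    }
  }
  if (depth != 0L) {
    stop("Newick parse error: ", depth,
         " unclosed '(' by position ", nchar(text))
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL)
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("Newick parse error: unreadable statement")
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("Newick parse error: duplicate leaf name(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting every edge to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch length in tree")
  }
  tree
}

#' Patristic distance between two leaves
#'
#' Sum of branch lengths along the unique path between two leaves; symmetric
#' and zero on the diagonal. Rooting-invariant.
#'
#' @param tree An [ape::phylo] tree.
#' @param a,b Leaf labels.
#' @return Non-negative numeric distance.
#' @export
patristic_distance <- function(tree, a, b) {
  m <- patristic_matrix(tree)
  for (x in c(a, b)) {
    if (!x %in% rownames(m)) stop("unknown leaf: ", x)
  }
  unname(m[a, b])
}

#' All-pairs patristic distance matrix
#'
#' @param tree An [ape::phylo] tree.
#' @return Symmetric matrix indexed by leaf label.
#' @export
patristic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  d <- ape::dist.nodes(tree)
  tips <- seq_along(tree$tip.label)
  m <- d[tips, tips, drop = FALSE]
  dimnames(m) <- list(tree$tip.label, tree$tip.label)
  m
}

# internal: tip labels under a node of a rooted tree
.tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, .tips_under, tree = tree), use.names = FALSE)
}

# internal: midpoint-root unrooted inputs so "clade" is well defined
.ensure_rooted <- function(tree) {
  if (ape::is.rooted(tree)) return(tree)
  if (all(tree$edge.length == 0)) {
    # midpoint undefined without lengths: root arbitrarily at first tip
    return(ape::root(tree, outgroup = tree$tip.label[1], resolve.root = TRUE))
  }
  phangorn::midpoint(tree)
}

#' Smallest clade containing a leaf and a reference-species leaf
#'
#' Walks rootward from the given leaf and returns the first (smallest) clade
#' that also contains at least one reference-species leaf. Unrooted inputs
#' are midpoint-rooted first.
#'
#' @param tree An [ape::phylo] tree.
#' @param leaf Leaf label of the gene of interest.
#' @param species_prefixes Prefix map for species inference.
#' @return List with `node` (internal node id in the rooted tree), `tips`
#'   (leaf labels in the clade) and `reference_tips`; `NULL` when the tree
#'   has no reference leaf at all.
#' @export
smallest_informative_clade <- function(tree, leaf,
                                       species_prefixes = default_species_prefixes()) {
  stopifnot(inherits(tree, "phylo"))
  if (!leaf %in% tree$tip.label) stop("unknown leaf: ", leaf)
  sp <- infer_species(tree$tip.label, species_prefixes)
  refs <- tree$tip.label[sp %in% "reference"]
  if (length(refs) == 0) return(NULL)
  tree <- .ensure_rooted(tree)
  node <- match(leaf, tree$tip.label)
  repeat {
    parent <- tree$edge[tree$edge[, 2] == node, 1]
    if (length(parent) == 0) break  # reached the root
    node <- parent
    tips <- .tips_under(tree, node)
    hit <- intersect(tips, refs)
    if (length(hit)) {
      return(list(node = node, tips = tips, reference_tips = hit))
    }
  }
  # root reached without a reference leaf: cannot happen when refs exist
  list(node = node, tips = tree$tip.label, reference_tips = refs)
}

#' Classify one target-species gene by the clade rule
#'
#' A target-species gene is called a flowering orthologue when its smallest
#' informative clade contains a flowering reference gene and no non-flowering
#' reference gene anywhere in the tree is equally close or closer (patristic
#' distance, absolute `tolerance` for equality). A non-flowering reference
#' gene that is closer or within tolerance demotes the call to
#' `other_orthologue`; a tree without reference leaves gives `unresolved`.
#'
#' @param tree An [ape::phylo] tree.
#' @param leaf Target-species leaf label.
#' @param flowering_set Character vector of flowering reference gene IDs.
#' @param tolerance Absolute distance tolerance for "equally close".
#' @param distance `"patristic"` (branch lengths) or `"topological"`
#'   (edge counts).
#' @param species_prefixes Prefix map for species inference.
#' @return One-row data frame: `target_gene`, `status`,
#'   `anchor_reference_genes` (comma-separated), `min_distance_flowering`,
#'   `min_distance_other`, `via_small_og_rule`.
#' @export
classify_target_gene <- function(tree, leaf, flowering_set,
                                 tolerance = 1e-9,
                                 distance = c("patristic", "topological"),
                                 species_prefixes = default_species_prefixes()) {
  distance <- match.arg(distance)
  stopifnot(inherits(tree, "phylo"))
  if (!leaf %in% tree$tip.label) stop("unknown leaf: ", leaf)
  sp <- infer_species(tree$tip.label, species_prefixes)
  if (!identical(sp[match(leaf, tree$tip.label)], "target")) {
    stop("leaf '", leaf, "' is not a target-species gene")
  }
  if (distance == "topological") {
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  refs <- tree$tip.label[sp %in% "reference"]
  row <- data.frame(target_gene = leaf, status = "unresolved",
                    anchor_reference_genes = "",
                    min_distance_flowering = NA_real_,
                    min_distance_other = NA_real_,
                    via_small_og_rule = FALSE, stringsAsFactors = FALSE)
  if (length(refs) == 0) return(row)

  clade <- smallest_informative_clade(tree, leaf, species_prefixes)
  m <- patristic_matrix(tree)
  flo_in_clade <- intersect(clade$reference_tips, flowering_set)
  other_refs <- setdiff(refs, flowering_set)  # whole tree

  d_flo <- if (length(flo_in_clade)) min(m[leaf, flo_in_clade]) else NA_real_
  d_other <- if (length(other_refs)) min(m[leaf, other_refs]) else NA_real_
  row$min_distance_flowering <- d_flo
  row$min_distance_other <- d_other

  if (length(flo_in_clade)) {
    if (!length(other_refs) || d_flo < d_other - tolerance) {
      row$status <- "flowering_orthologue"
      anchors <- flo_in_clade[m[leaf, flo_in_clade] <= d_flo + tolerance]
    } else {
      # a non-flowering reference gene is equally close or closer
      row$status <- "other_orthologue"
      anchors <- other_refs[m[leaf, other_refs] <= d_other + tolerance]
    }
  } else {
    # informative clade holds only non-flowering reference genes
    row$status <- "other_orthologue"
    near <- clade$reference_tips
    anchors <- near[m[leaf, near] <= min(m[leaf, near]) + tolerance]
  }
  row$anchor_reference_genes <- paste(sort(anchors), collapse = ",")
  row
}

#' Classify all target genes of one orthologue group
#'
#' Gene trees cannot be built for fewer than four sequences, so small OGs use
#' a shortcut: when a small OG's reference members are all flowering-listed,
#' every target member is a flowering orthologue (`via_small_og_rule`); when
#' a non-flowering reference member is present the target members stay
#' unresolved. OGs with four or more sequences require a tree and delegate
#' to [classify_target_gene()] per target leaf.
#'
#' @param og_members Data frame with columns `gene_id`, `species` for the
#'   OG's members.
#' @param tree An [ape::phylo] tree, or `NULL` for small OGs.
#' @param flowering_set Character vector of flowering reference gene IDs.
#' @param tolerance,distance,species_prefixes Passed to
#'   [classify_target_gene()].
#' @return Data frame with one row per target-species member.
#' @export
classify_og <- function(og_members, tree = NULL, flowering_set,
                        tolerance = 1e-9,
                        distance = c("patristic", "topological"),
                        species_prefixes = default_species_prefixes()) {
  distance <- match.arg(distance)
  .need_cols(og_members, c("gene_id", "species"), "og_members")
  targets <- og_members$gene_id[og_members$species == "target"]
  refs <- og_members$gene_id[og_members$species == "reference"]
  n_seq <- nrow(og_members)
  empty <- data.frame(target_gene = character(), status = character(),
                      anchor_reference_genes = character(),
                      min_distance_flowering = numeric(),
                      min_distance_other = numeric(),
                      via_small_og_rule = logical(),
                      stringsAsFactors = FALSE)
  if (length(targets) == 0) return(empty)

  if (n_seq < 4) {
    only_flowering <- length(refs) > 0 && all(refs %in% flowering_set)
    status <- if (only_flowering) "flowering_orthologue" else "unresolved"
    return(data.frame(
      target_gene = targets, status = status,
      anchor_reference_genes = if (only_flowering)
        paste(sort(refs), collapse = ",") else "",
      min_distance_flowering = NA_real_, min_distance_other = NA_real_,
      via_small_og_rule = only_flowering, stringsAsFactors = FALSE
    ))
  }
  if (is.null(tree)) {
    stop("OG has ", n_seq, " sequences but no tree was supplied")
  }
  present <- intersect(targets, tree$tip.label)
  out <- do.call(rbind, lapply(present, function(tg) {
    classify_target_gene(tree, tg, flowering_set, tolerance = tolerance,
                         distance = distance,
                         species_prefixes = species_prefixes)
  }))
  if (is.null(out)) empty else out
}
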
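# Independent oracles used across the suite. Each re-derives a quantity by
# the most direct method available (path walking, exhaustive enumeration,
# pair counting), sharing no code path with the package implementation.

# brute-force patristic distance: walk the unique a-b path over an
# adjacency list built from the edge table
oracle_path_distance <- function(tree, a, b) {
  n_node <- max(tree$edge)
  adj <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge))) {
    u <- tree$edge[i, 1]; v <- tree$edge[i, 2]; w <- tree$edge.length[i]
    adj[[u]] <- rbind(adj[[u]], c(v, w))
    adj[[v]] <- rbind(adj[[v]], c(u, w))
  }
  from <- match(a, tree$tip.label)
  to <- match(b, tree$tip.label)
  if (from == to) return(0)
  # iterative DFS carrying accumulated length
  stack <- list(list(node = from, prev = 0L, acc = 0))
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (cur$node == to) return(cur$acc)
    nb <- adj[[cur$node]]
    for (j in seq_len(nrow(nb))) {
      if (nb[j, 1] != cur$prev) {
        stack[[length(stack) + 1]] <- list(node = nb[j, 1], prev = cur$node,
                                           acc = cur$acc + nb[j, 2])
      }
    }
  }
  stop("leaves not connected")
}

oracle_distance_matrix <- function(tree) {
  tips <- tree$tip.label
  m <- matrix(0, length(tips), length(tips), dimnames = list(tips, tips))
  for (i in seq_along(tips)) {
    for (j in seq_along(tips)) {
      if (i < j) {
        m[i, j] <- m[j, i] <- oracle_path_distance(tree, tips[i], tips[j])
      }
    }
  }
  m
}

# tips under each internal node by frontier expansion over the edge table
oracle_tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  tips <- integer(0); frontier <- node
  while (length(frontier)) {
    ch <- tree$edge[tree$edge[, 1] %in% frontier, 2]
    tips <- c(tips, ch[ch <= ntip])
    frontier <- ch[ch > ntip]
  }
  tree$tip.label[sort(tips)]
}

# clade-rule classification re-derived from the full distance matrix and an
# exhaustive enumeration of clades containing the leaf
oracle_classify <- function(tree, leaf, flowering_set, tolerance = 1e-9) {
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  sp <- infer_species(tree$tip.label)
  refs <- tree$tip.label[sp %in% "reference"]
  if (length(refs) == 0) return(list(status = "unresolved", anchors = character()))
  ntip <- length(tree$tip.label)
  nodes <- (ntip + 1):max(tree$edge)
  best <- NULL; best_size <- Inf
  for (nd in nodes) {
    tips <- oracle_tips_under(tree, nd)
    if (leaf %in% tips && length(intersect(tips, refs)) > 0 &&
        length(tips) < best_size) {
      best <- tips; best_size <- length(tips)
    }
  }
  m <- oracle_distance_matrix(tree)
  flo <- intersect(intersect(best, refs), flowering_set)
  oth <- setdiff(refs, flowering_set)
  d_f <- if (length(flo)) min(m[leaf, flo]) else NA
  d_o <- if (length(oth)) min(m[leaf, oth]) else NA
  if (length(flo)) {
    if (!length(oth) || d_f < d_o - tolerance) {
      status <- "flowering_orthologue"
      anchors <- flo[m[leaf, flo] <= d_f + tolerance]
    } else {
      status <- "other_orthologue"
      anchors <- oth[m[leaf, oth] <= d_o + tolerance]
    }
  } else {
    status <- "other_orthologue"
    cr <- intersect(best, refs)
    anchors <- cr[m[leaf, cr] <= min(m[leaf, cr]) + tolerance]
  }
  list(status = status, anchors = sort(anchors))
}

# naive O(n^3) agglomeration; returns the cophenetic matrix, which is
# invariant to how ties are labelled
oracle_linkage_cophenetic <- function(D, method = c("average", "complete")) {
  method <- match.arg(method)
  n <- nrow(D)
  labs <- rownames(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = list(labs, labs))
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          sub <- D[clusters[[i]], clusters[[j]], drop = FALSE]
          d <- if (method == "average") mean(sub) else max(sub)
          if (d < best_d - 1e-12) { best_d <- d; best <- c(i, j) }
        }
      }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_d; coph[b, a] <- best_d
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# adjusted Rand by direct pair counting
oracle_ari <- function(a, b) {
  stopifnot(length(a) == length(b))
  n11 <- n10 <- n01 <- n00 <- 0
  n <- length(a)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s1 <- a[i] == a[j]; s2 <- b[i] == b[j]
      if (s1 && s2) n11 <- n11 + 1
      else if (s1) n10 <- n10 + 1
      else if (s2) n01 <- n01 + 1
      else n00 <- n00 + 1
    }
  }
  num <- 2 * (n11 * n00 - n10 * n01)
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(0)
  num / den
}

# two-sided Fisher p by exhaustive hypergeometric enumeration over all
# tables with the observed margins
oracle_fisher_p <- function(a, b, c_, d) {
  m <- a + c_; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# random tree with integer branch lengths for distance oracles
random_int_tree <- function(n_tips, labels = NULL) {
  tr <- ape::rtree(n_tips, tip.label = labels)
  tr$edge.length <- sample(1:9, nrow(tr$edge), replace = TRUE)
  tr
}
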
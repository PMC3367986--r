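test_that("Newick parsing preserves leaves, lengths and support labels", {
  tr <- parse_newick("(A:1,B:2);")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_setequal(tr$edge.length, c(1, 2))
  tr2 <- parse_newick("((A:1,B:1)950:1,C:2);")
  expect_true("950" %in% tr2$node.label)
  expect_error(parse_newick("((A:1,B:1;"), "unclosed")
  expect_error(parse_newick("(A:1,B:2)"), "';'")
  expect_error(parse_newick("(A:1,A:2);"), "duplicate")
  expect_warning(tr3 <- parse_newick("(A,(B,C));"), "branch lengths")
  expect_equal(sum(tr3$edge.length), 0)
})

test_that("patristic distance equals the closed form on two leaves", {
  tr <- parse_newick("(A:1,B:2);")
  expect_equal(patristic_distance(tr, "A", "B"), 3)
  expect_equal(patristic_distance(tr, "A", "A"), 0)
  expect_error(patristic_distance(tr, "A", "Z"), "unknown leaf")
})

test_that("patristic distances match a brute-force path oracle on random trees", {
  set.seed(101)
  for (rep in 1:200) {
    tr <- random_int_tree(sample(4:9, 1))
    m <- patristic_matrix(tr)
    o <- oracle_distance_matrix(tr)
    expect_equal(m[rownames(o), colnames(o)], o)
  }
})

test_that("distances are symmetric and satisfy the triangle inequality", {
  set.seed(202)
  for (rep in 1:25) {
    tr <- random_int_tree(6)
    m <- patristic_matrix(tr)
    expect_equal(m, t(m))
    tips <- rownames(m)
    for (a in tips) for (b in tips) for (c in tips) {
      expect_lte(m[a, b], m[a, c] + m[c, b] + 1e-9)
    }
  }
})

test_that("the smallest informative clade is found, incl. the root case", {
  tr <- parse_newick("((Glyma01g1:1,AT1G1:1):1,AT2G2:5);")
  cl <- smallest_informative_clade(tr, "Glyma01g1")
  expect_setequal(cl$tips, c("Glyma01g1", "AT1G1"))
  tr2 <- parse_newick("((Glyma01g1:1,Glyma01g2:1):1,AT1G1:1);")
  cl2 <- smallest_informative_clade(tr2, "Glyma01g1")
  expect_setequal(cl2$tips, c("Glyma01g1", "Glyma01g2", "AT1G1"))
  # 8-leaf tree: exhaustive check over all clades containing the leaf
  set.seed(7)
  labs <- c(sprintf("Glyma01g%d", 1:4), sprintf("AT1G%d", 1:4))
  tr3 <- random_int_tree(8, labels = sample(labs))
  got <- smallest_informative_clade(tr3, "Glyma01g1")
  rooted <- if (ape::is.rooted(tr3)) tr3 else phangorn::midpoint(tr3)
  ntip <- length(rooted$tip.label)
  sizes <- Inf; best <- NULL
  for (nd in (ntip + 1):max(rooted$edge)) {
    tips <- oracle_tips_under(rooted, nd)
    if ("Glyma01g1" %in% tips && any(startsWith(tips, "AT")) &&
        length(tips) < sizes) {
      sizes <- length(tips); best <- tips
    }
  }
  expect_setequal(got$tips, best)
})

test_that("the clade rule classifies flowering vs other orthologues", {
  tr <- parse_newick("((Glyma01g1:1,AT1G1:1):1,AT2G2:5);")
  r <- classify_target_gene(tr, "Glyma01g1", flowering_set = "AT1G1")
  expect_equal(r$status, "flowering_orthologue")
  expect_equal(r$min_distance_flowering, 2)
  expect_equal(r$min_distance_other, 7)
  # equally close (within tolerance) excludes: "equally close or closer"
  tr2 <- parse_newick("((Glyma01g1:1,AT1G1:1):0,AT2G2:1);")
  r2 <- classify_target_gene(tr2, "Glyma01g1", flowering_set = "AT1G1")
  expect_equal(r2$status, "other_orthologue")
  expect_error(classify_target_gene(tr, "AT1G1", flowering_set = "AT1G1"),
               "not a target")
})

test_that("classification matches the distance-matrix oracle on simulated trees", {
  cfg <- simulation_config(seed = 9)
  n_ok <- 0; n_tot <- 0
  for (rep in 1:40) {
    cfg$seed <- 9 + rep
    n_ref <- sample(2:4, 1); n_tgt <- sample(2:6, 1)
    members <- data.frame(
      gene_id = c(sprintf("AT1G%02d%03d", rep, seq_len(n_ref)),
                  sprintf("Glyma01g%02d%03d", rep, seq_len(n_tgt))),
      species = c(rep("reference", n_ref), rep("target", n_tgt)))
    flowering <- members$gene_id[seq_len(max(1, n_ref %/% 2))]
    gt <- generate_gene_tree(members, cfg)
    for (tg in gt$truth$target_gene) {
      got <- classify_target_gene(gt$tree, tg, flowering)
      ora <- oracle_classify(gt$tree, tg, flowering)
      expect_equal(got$status, ora$status)
      expect_equal(strsplit(got$anchor_reference_genes, ",")[[1]],
                   ora$anchors)
      # planted-orthologue recovery at zero branch noise
      truth_anchor <- gt$truth$true_anchor[gt$truth$target_gene == tg]
      n_tot <- n_tot + 1
      exp_status <- if (truth_anchor %in% flowering) "flowering_orthologue"
        else "other_orthologue"
      if (got$status == exp_status &&
          truth_anchor %in% strsplit(got$anchor_reference_genes, ",")[[1]]) {
        n_ok <- n_ok + 1
      }
    }
  }
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("classification is invariant to leaf order and rerooting at zero tolerance", {
  txt <- "(((Glyma01g1:1,AT1G1:2):1,(Glyma01g2:1,AT2G9:1):2):1,AT3G5:4);"
  tr <- parse_newick(txt)
  base <- classify_target_gene(tr, "Glyma01g1", "AT1G1", tolerance = 0)
  # same topology written with leaves permuted
  perm <- parse_newick("(AT3G5:4,((AT2G9:1,Glyma01g2:1):2,(AT1G1:2,Glyma01g1:1):1):1);")
  r_perm <- classify_target_gene(perm, "Glyma01g1", "AT1G1", tolerance = 0)
  expect_equal(r_perm$status, base$status)
  expect_equal(r_perm$min_distance_flowering, base$min_distance_flowering)
  expect_equal(r_perm$min_distance_other, base$min_distance_other)
  # reroot along other edges: patristic distances are rooting-invariant
  for (tip in c("AT3G5", "Glyma01g2", "AT2G9")) {
    rr <- ape::root(ape::unroot(tr), outgroup = tip, resolve.root = TRUE)
    r2 <- classify_target_gene(rr, "Glyma01g1", "AT1G1", tolerance = 0)
    expect_equal(r2$min_distance_flowering, base$min_distance_flowering)
    expect_equal(r2$min_distance_other, base$min_distance_other)
    expect_equal(r2$status, base$status)
  }
})

test_that("small OGs follow the shortcut rule; large OGs delegate", {
  # 3 sequences, only flowering reference members
  m3 <- data.frame(gene_id = c("AT1G1", "Glyma01g1", "Glyma01g2"),
                   species = c("reference", "target", "target"))
  r <- classify_og(m3, NULL, flowering_set = "AT1G1")
  expect_true(all(r$status == "flowering_orthologue"))
  expect_true(all(r$via_small_og_rule))
  # 3 sequences including a non-flowering reference gene: unresolved
  m3b <- data.frame(gene_id = c("AT1G1", "AT2G2", "Glyma01g1"),
                    species = c("reference", "reference", "target"))
  rb <- classify_og(m3b, NULL, flowering_set = "AT1G1")
  expect_true(all(rb$status == "unresolved"))
  expect_false(any(rb$via_small_og_rule))
  # 4 sequences: per-leaf classification, tree required
  m4 <- data.frame(
    gene_id = c("AT1G1", "AT2G2", "Glyma01g1", "Glyma01g2"),
    species = c("reference", "reference", "target", "target"))
  expect_error(classify_og(m4, NULL, "AT1G1"), "no tree")
  tr <- parse_newick("((Glyma01g1:1,AT1G1:1):2,(Glyma01g2:1,AT2G2:1):2);")
  r4 <- classify_og(m4, tr, "AT1G1")
  expect_equal(nrow(r4), 2)
  by_hand <- rbind(classify_target_gene(tr, "Glyma01g1", "AT1G1"),
                   classify_target_gene(tr, "Glyma01g2", "AT1G1"))
  expect_equal(r4[order(r4$target_gene), ],
               by_hand[order(by_hand$target_gene), ],
               ignore_attr = TRUE)
})
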
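test_that("longest isoform is selected, with deterministic tie-breaking", {
  iso <- list(
    locusA = c(A.1 = strrep("M", 100), A.2 = strrep("M", 150)),
    locusB = c(B.1 = "MSEQ"),
    locusC = c(C.2 = strrep("K", 120), C.1 = strrep("Q", 120))
  )
  sel <- select_longest_isoform(iso)
  expect_equal(nchar(sel[["locusA"]]), 150)
  expect_equal(sel[["locusB"]], "MSEQ")
  # tie at 120: lexicographically smallest isoform ID wins
  expect_equal(attr(sel, "isoform_id")[3], "C.1")
  expect_equal(sel[["locusC"]], strrep("Q", 120))
  expect_error(select_longest_isoform(list(locusX = character())), "locusX")
})

test_that("a linked reference gene without membership gets a synthesized OG", {
  links <- data.frame(target_gene = c("Glyma01g00010", "Glyma01g00020"),
                      reference_gene = c("AT2G33835", "AT2G33835"))
  mem <- data.frame(gene_id = "Glyma01g00030", og_id = "OG5_100")
  m <- merge_og_assignments(links, mem)
  expect_equal(m$synthesized_ogs, "OG5_AT2G33835")
  a <- m$assignments
  expect_setequal(a$gene_id[a$og_id == "OG5_AT2G33835"],
                  c("AT2G33835", "Glyma01g00010", "Glyma01g00020"))
  expect_equal(a$source[a$gene_id == "AT2G33835"], "synthesized")
  expect_equal(a$source[a$gene_id == "Glyma01g00010"], "link")
})

test_that("an empty link table reproduces the membership map exactly", {
  mem <- data.frame(gene_id = c("AT1G10", "Glyma01g10", "Glyma01g20"),
                    og_id = c("OG5_1", "OG5_1", "OG5_2"))
  m <- merge_og_assignments(data.frame(), mem)
  expect_equal(m$assignments$og_id[match(mem$gene_id,
                                         m$assignments$gene_id)],
               mem$og_id)
  expect_length(m$synthesized_ogs, 0)
  expect_true(all(m$assignments$source == "membership"))
})

test_that("link precedence over membership matches a brute-force application", {
  # 10-gene toy: 3 target genes whose own membership conflicts with their
  # link-derived OG
  refs <- sprintf("AT1G%05d", 1:3)
  tgts <- sprintf("Glyma01g%05d", 1:7)
  mem <- data.frame(
    gene_id = c(refs, tgts[1:6]),
    og_id = c("OG5_A", "OG5_B", "OG5_C",
              "OG5_A", "OG5_B", "OG5_C", "OG5_C", "OG5_A", "OG5_B"))
  links <- data.frame(target_gene = c(tgts[1], tgts[4], tgts[6], tgts[7]),
                      reference_gene = c(refs[2], refs[3], refs[1], refs[1]))
  m <- merge_og_assignments(links, mem)
  # brute force: link-derived OG when a link exists, else own membership
  expected <- sapply(c(refs, tgts), function(g) {
    li <- links$reference_gene[links$target_gene == g]
    if (length(li)) mem$og_id[mem$gene_id == li] else {
      og <- mem$og_id[mem$gene_id == g]
      if (length(og)) og else NA
    }
  })
  got <- m$assignments$og_id[match(names(expected), m$assignments$gene_id)]
  expect_equal(unname(got), unname(expected))
  expect_error(merge_og_assignments(
    rbind(links, data.frame(target_gene = tgts[1], reference_gene = refs[1])),
    mem), "multiple links")
  expect_error(merge_og_assignments(links, mem, genes = c(refs, tgts[1:6])),
               "unknown gene")
})

test_that("merging preserves the partition and precedence properties", {
  set.seed(11)
  uni <- generate_og_universe(simulation_config(seed = 7, n_ogs = 60))
  m <- merge_og_assignments(uni$links, uni$memberships)
  a <- m$assignments
  # partition: each assigned gene exactly once; counts sum to gene total
  expect_false(anyDuplicated(a$gene_id) > 0)
  expect_equal(sum(og_count_table(a)[, -1]), nrow(a))
  # expected unified OG from the generator's ground truth
  expect_equal(a$og_id[match(uni$genes$gene_id, a$gene_id)],
               uni$genes$expected_og)
  # removing links reproduces the membership map exactly
  m0 <- merge_og_assignments(data.frame(), uni$memberships)
  expect_equal(sort(m0$assignments$gene_id), sort(uni$memberships$gene_id))
  expect_equal(m0$assignments$og_id[match(uni$memberships$gene_id,
                                          m0$assignments$gene_id)],
               uni$memberships$og_id)
  # removing memberships leaves only link-derived and synthesized OGs
  m1 <- merge_og_assignments(uni$links, data.frame(gene_id = character(),
                                                   og_id = character()))
  expect_true(all(m1$assignments$source %in% c("link", "synthesized")))
  # synthesized-ID format and no collision with input OG IDs
  expect_true(all(grepl("^OG5_AT", m$synthesized_ogs)))
  expect_length(intersect(m$synthesized_ogs, uni$memberships$og_id), 0)
})

test_that("flowering OGs are flagged with additional reference genes", {
  a <- data.frame(
    gene_id = c("AT1G1", "AT1G2", "Glyma01g1", "Glyma01g2", "Glyma02g1"),
    species = c("reference", "reference", "target", "target", "target"),
    og_id = c("OG5_1", "OG5_1", "OG5_1", "OG5_1", "OG5_2"))
  flo <- flag_flowering_ogs(a, c("AT1G1", "AT9G9"))
  ogs <- flo$ogs
  expect_true(ogs$contains_flowering[ogs$og_id == "OG5_1"])
  expect_equal(ogs$additional_reference_genes[ogs$og_id == "OG5_1"], "AT1G2")
  # OG with only target members is never flagged
  expect_false(ogs$contains_flowering[ogs$og_id == "OG5_2"])
  expect_equal(flo$orphans, "AT9G9")
  expect_equal(flo$summary$n_target_genes_in_flowering_ogs, 2)
  expect_equal(flo$summary$n_additional_reference_genes, 1)
})

test_that("flowering summary counts match exhaustive enumeration", {
  set.seed(21)
  uni <- generate_og_universe(simulation_config(seed = 13, n_ogs = 40))
  a <- merge_og_assignments(uni$links, uni$memberships)$assignments
  flo <- flag_flowering_ogs(a, uni$flowering)
  by_og <- split(a, a$og_id)
  exp_flagged <- vapply(by_og, function(m) {
    any(m$gene_id[m$species == "reference"] %in% uni$flowering)
  }, logical(1))
  expect_equal(sum(flo$ogs$contains_flowering), sum(exp_flagged))
  expect_equal(flo$summary$n_target_genes_in_flowering_ogs,
               sum(vapply(by_og[exp_flagged], function(m) {
                 sum(m$species == "target")
               }, numeric(1))))
})

test_that("OG count table gives exact cardinalities", {
  a <- data.frame(
    gene_id = c(sprintf("AT1G%d", 1:2), sprintf("Glyma01g%d", 1:16)),
    species = c(rep("reference", 2), rep("target", 16)),
    og_id = "OG5_150317")
  ct <- og_count_table(a)
  expect_equal(ct$n_reference, 2)
  expect_equal(ct$n_target, 16)
  expect_equal(nrow(og_count_table(a[0, ])), 0)
  # random map: row sums equal total gene count
  set.seed(3)
  a2 <- data.frame(gene_id = sprintf("Glyma%02dg%d", 1:50, 1:50),
                   species = sample(c("reference", "target", "other"), 50,
                                    replace = TRUE),
                   og_id = sample(sprintf("OG5_%d", 1:8), 50, replace = TRUE))
  a2$gene_id <- paste0(ifelse(a2$species == "reference", "AT", "Glyma"),
                       seq_len(50))
  ct2 <- og_count_table(a2)
  expect_equal(sum(ct2$n_reference + ct2$n_target + ct2$n_other), 50)
})
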
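toy_models <- function() {
  genes <- data.frame(
    gene_id = c("gPlus", "gMinus", "gEdge"),
    chrom = c("Chr01", "Chr01", "Chr02"),
    start = c(2000, 2000, 500), end = c(3000, 3000, 1400),
    strand = c("+", "-", "+"))
  cds <- data.frame(gene_id = c("gPlus", "gPlus", "gMinus", "gEdge"),
                    start = c(2000, 2600, 2100, 600),
                    end = c(2400, 3000, 2900, 900))
  gene_models(genes, cds)
}

test_that("promoters are strand-aware, upstream and truncated at 1", {
  m <- toy_models()$genes
  expect_equal(unlist(m[m$gene_id == "gPlus", c("prom_start", "prom_end")]),
               c(prom_start = 1000, prom_end = 1999))
  expect_equal(unlist(m[m$gene_id == "gMinus", c("prom_start", "prom_end")]),
               c(prom_start = 3001, prom_end = 4000))
  expect_equal(unlist(m[m$gene_id == "gEdge", c("prom_start", "prom_end")]),
               c(prom_start = 1, prom_end = 499))
  # promoter never overlaps its own gene body
  expect_true(all(m$prom_end < m$start | m$prom_start > m$end))
})

test_that("SNPs are categorised CDS / genic_noncoding / promoter / outside", {
  mod <- toy_models()
  expect_equal(categorize_snp(mod, "gPlus", "Chr01", 2200), "CDS")
  expect_equal(categorize_snp(mod, "gPlus", "Chr01", 2500), "genic_noncoding")
  expect_equal(categorize_snp(mod, "gPlus", "Chr01", 1500), "promoter")
  expect_equal(categorize_snp(mod, "gPlus", "Chr01", 5000), "outside")
  expect_warning(out <- categorize_snp(mod, "gPlus", "Chr02", 2200),
                 "differs")
  expect_equal(out, "outside")
  # 30 random SNPs vs exhaustive per-base membership oracle
  set.seed(9)
  pos <- sample(1:6000, 30)
  for (p in pos) {
    got <- categorize_snp(mod, "gPlus", "Chr01", p)
    in_cds <- (p >= 2000 && p <= 2400) || (p >= 2600 && p <= 3000)
    expected <- if (in_cds) "CDS"
      else if (p >= 2000 && p <= 3000) "genic_noncoding"
      else if (p >= 1000 && p <= 1999) "promoter"
      else "outside"
    expect_equal(got, expected)
  }
})

test_that("every position maps to exactly one category per gene", {
  mod <- toy_models()
  cats <- vapply(1:4500, function(p) categorize_snp(mod, "gMinus", "Chr01", p),
                 character(1))
  expect_setequal(unique(cats),
                  c("CDS", "genic_noncoding", "promoter", "outside"))
  # counts partition the scanned range
  expect_equal(sum(cats == "CDS"), 801)
  expect_equal(sum(cats == "genic_noncoding"), 1001 - 801)
  expect_equal(sum(cats == "promoter"), 1000)
})

test_that("per-gene reports and the non-coding-only census are consistent", {
  mod <- toy_models()
  snps <- data.frame(chrom = c("Chr01", "Chr01", "Chr01", "Chr02"),
                     pos = c(2200, 1500, 2500, 650))
  rep <- gene_variant_report(snps, mod)
  gp <- rep[rep$gene_id == "gPlus", ]
  expect_equal(gp$n_snps_cds, 1)
  expect_equal(gp$n_snps_promoter, 1)
  expect_equal(gp$n_snps_genic_noncoding, 1)
  expect_false(gp$noncoding_only)
  # gMinus: 2200 and 2500 are CDS, 2500 in its CDS too -> not noncoding-only
  expect_false(rep$noncoding_only[rep$gene_id == "gMinus"])
  expect_false(rep$noncoding_only[rep$gene_id == "gEdge"])  # CDS SNP
  cen <- census_noncoding_only(rep)
  expect_equal(cen$n_universe, 3)
  expect_equal(cen$count, 0)
  # synthetic 100-gene report vs exhaustive recount
  set.seed(12)
  fake <- data.frame(gene_id = sprintf("g%03d", 1:100),
                     n_snps_cds = rpois(100, 0.5),
                     n_snps_genic_noncoding = rpois(100, 1),
                     n_snps_promoter = rpois(100, 1))
  fake$noncoding_only <- fake$n_snps_cds == 0 &
    (fake$n_snps_genic_noncoding + fake$n_snps_promoter) > 0
  cen2 <- census_noncoding_only(fake)
  uni <- rowSums(fake[, 2:4]) > 0
  expect_equal(cen2$n_universe, sum(uni))
  expect_equal(cen2$count, sum(fake$noncoding_only[uni]))
  expect_equal(cen2$percentage,
               round(100 * cen2$count / cen2$n_universe, 1))
  # census consistency: noncoding-only + CDS-carrying + neither = universe
  u <- fake[uni, ]
  expect_equal(sum(u$noncoding_only) + sum(u$n_snps_cds > 0) +
                 sum(!u$noncoding_only & u$n_snps_cds == 0),
               nrow(u))
  expect_error(census_noncoding_only(fake[fake$n_snps_cds +
    fake$n_snps_genic_noncoding + fake$n_snps_promoter == 0, ]), "empty")
})

test_that("SV overlap honours the promoter toggle and is monotone", {
  mod <- toy_models()
  svs <- data.frame(chrom = "Chr01", start = 1500, end = 1700,
                    type = "deletion")
  off <- sv_overlap(svs, mod, include_promoter = FALSE)
  on <- sv_overlap(svs, mod, include_promoter = TRUE)
  expect_false(off$deletion[off$gene_id == "gPlus"])
  expect_true(on$deletion[on$gene_id == "gPlus"])
  # other chromosome never flagged
  expect_false(any(on[on$gene_id == "gEdge", c("deletion", "insertion",
                                               "inversion")] == TRUE))
  # 200 random SVs vs 20 genes: all-pairs brute-force oracle + monotonicity
  set.seed(33)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:20),
                      chrom = rep(c("Chr01", "Chr02"), 10),
                      start = sample(seq(2000, 90000, by = 4000), 20),
                      strand = sample(c("+", "-"), 20, replace = TRUE))
  genes$end <- genes$start + 1999
  cds <- data.frame(gene_id = genes$gene_id, start = genes$start,
                    end = genes$start + 500)
  mod2 <- gene_models(genes, cds)
  svs2 <- data.frame(chrom = sample(c("Chr01", "Chr02"), 200, replace = TRUE),
                     start = sample(1:95000, 200),
                     type = sample(c("deletion", "insertion", "inversion"),
                                   200, replace = TRUE))
  svs2$end <- svs2$start + sample(100:3000, 200, replace = TRUE)
  for (inc in c(FALSE, TRUE)) {
    got <- sv_overlap(svs2, mod2, include_promoter = inc)
    g <- mod2$genes
    for (i in seq_len(nrow(g))) {
      for (ty in c("deletion", "insertion", "inversion")) {
        vv <- svs2[svs2$type == ty & svs2$chrom == g$chrom[i], ]
        hit <- any(vv$start <= g$end[i] & vv$end >= g$start[i])
        if (inc && !is.na(g$prom_start[i])) {
          hit <- hit || any(vv$start <= g$prom_end[i] &
                              vv$end >= g$prom_start[i])
        }
        expect_equal(got[got$gene_id == g$gene_id[i], ty], hit)
      }
    }
  }
  no_prom <- sv_overlap(svs2, mod2, FALSE)
  with_prom <- sv_overlap(svs2, mod2, TRUE)
  for (ty in c("deletion", "insertion", "inversion")) {
    expect_true(all(with_prom[[ty] ] >= no_prom[[ty]]))
  }
})

test_that("Fisher enrichment equals hypergeometric enumeration", {
  r1 <- enrichment_test(5, 50, 50, 500)
  expect_equal(r1$odds_ratio, 1.0)
  expect_equal(r1$p_value, 1.0)
  r2 <- enrichment_test(10, 10, 10, 20)
  expect_equal(r2$odds_ratio, Inf)
  expect_equal(r2$p_value, oracle_fisher_p(10, 0, 0, 10), tolerance = 1e-9)
  r3 <- enrichment_test(3, 20, 30, 200)
  expect_equal(r3$p_value, oracle_fisher_p(3, 17, 27, 153), tolerance = 1e-9)
  set.seed(55)
  for (rep in 1:20) {
    bt <- sample(20:60, 1); bf <- sample(0:bt, 1)
    st <- sample(5:bt, 1)
    lo <- max(0, bf - (bt - st), st - (bt - bf))
    hi <- min(st, bf)
    if (lo > hi) next
    sf <- if (lo == hi) lo else sample(lo:hi, 1)
    r <- enrichment_test(sf, st, bf, bt)
    expect_equal(r$p_value,
                 oracle_fisher_p(sf, st - sf, bf - sf,
                                 (bt - st) - (bf - sf)),
                 tolerance = 1e-9)
  }
  expect_error(enrichment_test(5, 3, 10, 20), "inconsistent")
  expect_error(enrichment_test(-1, 3, 10, 20), "non-negative")
})

test_that("GFF3, variant TSV and VCF readers round-trip the fixtures", {
  dir <- withr::local_tempdir()
  cfg <- simulation_config(seed = 4, n_ogs = 30, n_chromosomes = 2,
                           genes_per_chrom = 40, cluster_chrom = "Chr01",
                           cluster_start = 1e5, cluster_span = 2e5,
                           cluster_size = 15)
  b <- write_fixture_bundle(cfg, dir, n_trees = 2)
  mod <- read_gene_models_gff3(file.path(dir, "genes.gff3"))
  expect_setequal(mod$genes$gene_id, b$genome$genes$gene_id)
  expect_equal(mod$genes$start[match(b$genome$genes$gene_id,
                                     mod$genes$gene_id)],
               b$genome$genes$start)
  v <- read_variants_tsv(file.path(dir, "variants.tsv"))
  expect_equal(nrow(v$snps), nrow(b$genome$snps))
  expect_equal(nrow(v$svs), nrow(b$genome$svs))
  # hand-written VCF: one SNP, one deletion with END
  vcf <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
           "Chr01\t2200\tsnp1\tA\tG\t.\tPASS\t.",
           "Chr01\t1500\tdel1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=1700")
  vp <- file.path(dir, "toy.vcf")
  writeLines(vcf, vp)
  vv <- read_variants_vcf(vp)
  expect_equal(vv$snps$pos, 2200)
  expect_equal(vv$svs$type, "deletion")
  expect_equal(vv$svs$end, 1700)
})
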
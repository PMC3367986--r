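#!/usr/bin/env Rscript
# Stage 7 — wild-relative variant overlap: categorise SNPs against gene
# models with 1 kb promoters, census genes whose SNPs avoid coding sequence,
# overlap structural variants with genes (with and without promoters), and
# test enrichment of SV-carrying genes in the flagged subset.
source(file.path("analysis", "common.R"))
ensure_fixtures()

models <- read_gene_models_gff3(file.path(FIXTURE_DIR, "genes.gff3"))
vars <- read_variants_tsv(file.path(FIXTURE_DIR, "variants.tsv"))
snp_truth <- read_tsv(file.path(FIXTURE_DIR, "snp_truth.tsv"))
genes <- read_tsv(file.path(FIXTURE_DIR, "genes.tsv"))

say("%d gene models, %d SNPs, %d SVs", nrow(models$genes),
    nrow(vars$snps), nrow(vars$svs))
got <- mapply(function(g, c, p) categorize_snp(models, g, c, p),
              snp_truth$gene_id, snp_truth$chrom, snp_truth$pos)
say("SNP categories reproduce the planted truth: %.1f%%",
    100 * mean(got == snp_truth$true_category))

report <- gene_variant_report(vars$snps, models)
cen <- census_noncoding_only(report)
say("%d of %d SNP-carrying genes (%.1f%%) have SNPs only outside CDS",
    cen$count, cen$n_universe, cen$percentage)

sv_body <- sv_overlap(vars$svs, models, include_promoter = FALSE)
sv_full <- sv_overlap(vars$svs, models, include_promoter = TRUE)
say("genes hit by an SV: %d (gene body), %d (body + promoter)",
    sum(sv_body$sv_overlap_types != ""), sum(sv_full$sv_overlap_types != ""))

flagged <- genes$gene_id[as.logical(genes$flagged)]
hit_genes <- sv_full$gene_id[sv_full$sv_overlap_types != ""]
et <- enrichment_test(sum(flagged %in% hit_genes), length(flagged),
                      length(hit_genes), nrow(sv_full))
say("SV enrichment in flagged genes: odds ratio %.2f, two-sided p = %.3f",
    et$odds_ratio, et$p_value)

write_tsv6(report, file.path(RESULTS_DIR, "snp_report.tsv"))
write_tsv6(data.frame(count = cen$count, n_universe = cen$n_universe,
                      percentage = cen$percentage),
           file.path(RESULTS_DIR, "snp_census.tsv"))
write_tsv6(sv_full, file.path(RESULTS_DIR, "sv_flags.tsv"))
say("wrote snp_report.tsv, snp_census.tsv, sv_flags.tsv under %s/",
    RESULTS_DIR)
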
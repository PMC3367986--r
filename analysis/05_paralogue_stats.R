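#!/usr/bin/env Rscript
# Stage 5 — paralogue copy-number statistics: per-OG log2(target/reference)
# ratios, their distribution summary, and the 2-SD rich/less classification.
# Verifies recovery of the generating parameters and reports the fold-change
# thresholds implied by the fitted distribution.
source(file.path("analysis", "common.R"))
ensure_fixtures()

counts <- read_tsv(file.path(FIXTURE_DIR, "og_counts.tsv"))
truth <- read_tsv(file.path(FIXTURE_DIR, "og_truth.tsv"))

rat <- compute_ratios(counts)
say("%d OGs enter the ratio distribution; %d excluded for a zero count",
    nrow(rat$ratios), nrow(rat$excluded))
summ <- distribution_summary(rat$ratios)
print(summ)
se_mean <- 0.88 / sqrt(nrow(rat$ratios))
say("generator mean 1.03 recovered within %.4f (3 SE = %.4f): %s",
    abs(summ$mean_log2 - 1.03), 3 * se_mean,
    ifelse(abs(summ$mean_log2 - 1.03) < 3 * se_mean, "yes", "NO"))

classed <- classify_paralogue(rat$ratios, summ)
tab <- table(classed$class)
say("classification: %d rich, %d less, %d typical OGs",
    tab["rich"], tab["less"], tab["typical"])
agree <- mean(classed$class ==
                truth$true_class[match(classed$og_id, truth$og_id)])
say("agreement with generating classes: %.1f%%", 100 * agree)
say("fold thresholds: rich beyond %.2f-fold, less below %.2f-fold",
    fold_threshold(summ, "upper"), fold_threshold(summ, "lower"))

# the published table of eight paralogue-rich flowering OGs as a cross-check
rich_tab <- read_tsv(system.file("extdata", "paralogue_rich_ogs.tsv",
                                 package = "orthoflora"))
rc <- classify_paralogue(compute_ratios(rich_tab)$ratios, summ)
say("published paralogue-rich OGs: %d/%d classified rich; %d target genes in total",
    sum(rc$class == "rich"), nrow(rc), sum(rich_tab$n_target))

write_tsv6(classed, file.path(RESULTS_DIR, "paralogue_classes.tsv"))
write_tsv6(data.frame(mean_log2 = summ$mean_log2, sd_log2 = summ$sd_log2,
                      n_ogs = summ$n_ogs, k = summ$k,
                      upper = summ$upper, lower = summ$lower,
                      fold_upper = summ$fold_upper,
                      fold_lower = summ$fold_lower),
           file.path(RESULTS_DIR, "ratio_summary.tsv"))
say("wrote paralogue_classes.tsv, ratio_summary.tsv under %s/", RESULTS_DIR)
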
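#!/usr/bin/env Rscript
# Stage 2 — unify annotation links with OG memberships, flag flowering OGs
# and tabulate per-OG per-species counts. Checks the unified map against the
# generator's expected assignment.
source(file.path("analysis", "common.R"))
ensure_fixtures()

links <- read_tsv(file.path(FIXTURE_DIR, "links.tsv"))
memberships <- read_tsv(file.path(FIXTURE_DIR, "memberships.tsv"))
flowering <- read_tsv(file.path(FIXTURE_DIR, "flowering.tsv"))$gene_id
truth <- read_tsv(file.path(FIXTURE_DIR, "og_genes.tsv"))

merged <- merge_og_assignments(links, memberships)
a <- merged$assignments
say("unified OG map: %d genes assigned, %d synthesized OGs, %d unassigned",
    nrow(a), length(merged$synthesized_ogs), length(merged$unassigned))
agree <- mean(a$og_id[match(truth$gene_id, a$gene_id)] == truth$expected_og)
say("agreement with generator ground truth: %.1f%%", 100 * agree)

flo <- flag_flowering_ogs(a, flowering)
s <- flo$summary
say("flowering list: %d genes; %d flowering OGs holding %d target genes and %d additional reference genes",
    s$n_flowering_listed, s$n_flowering_ogs,
    s$n_target_genes_in_flowering_ogs, s$n_additional_reference_genes)

write_tsv6(a, file.path(RESULTS_DIR, "og_map.tsv"))
write_tsv6(flo$ogs, file.path(RESULTS_DIR, "flowering_ogs.tsv"))
write_tsv6(og_count_table(a), file.path(RESULTS_DIR, "og_count_table.tsv"))
say("wrote og_map.tsv, flowering_ogs.tsv, og_count_table.tsv under %s/",
    RESULTS_DIR)
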
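#!/usr/bin/env Rscript
# Stage 3 — refine orthology from gene trees: for every emitted tree, apply
# the clade rule (a target gene in the smallest clade holding a flowering
# reference gene is a flowering orthologue unless a non-flowering reference
# gene is equally close or closer by patristic distance), and score the
# calls against the trees' planted anchors.
source(file.path("analysis", "common.R"))
ensure_fixtures()

genes <- read_tsv(file.path(FIXTURE_DIR, "og_genes.tsv"))
flowering <- read_tsv(file.path(FIXTURE_DIR, "flowering.tsv"))$gene_id
tree_truth <- read_tsv(file.path(FIXTURE_DIR, "tree_truth.tsv"))
tree_files <- list.files(file.path(FIXTURE_DIR, "trees"),
                         pattern = "\\.nwk$", full.names = TRUE)

res <- list()
for (tf in tree_files) {
  og <- sub("\\.nwk$", "", basename(tf))
  members <- genes[genes$og_id == og, c("gene_id", "species")]
  cls <- classify_og(members, parse_newick(file = tf), flowering)
  if (nrow(cls)) { cls$og_id <- og; res[[og]] <- cls }
}
cls <- do.call(rbind, res)
rownames(cls) <- NULL
say("classified %d target genes across %d trees", nrow(cls), length(res))
print(table(cls$status))

hit <- merge(cls, tree_truth, by = c("og_id", "target_gene"))
recovered <- mapply(function(anc, truth) {
  truth %in% strsplit(anc, ",")[[1]]
}, hit$anchor_reference_genes, hit$true_anchor)
say("planted anchors recovered: %d / %d (%.1f%%)",
    sum(recovered), nrow(hit), 100 * mean(recovered))

write_tsv6(cls, file.path(RESULTS_DIR, "clade_assignments.tsv"))
say("wrote clade_assignments.tsv under %s/", RESULTS_DIR)
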
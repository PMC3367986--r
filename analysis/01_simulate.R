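#!/usr/bin/env Rscript
# Stage 1 — simulate the full fixture bundle with known ground truth:
# an orthologue-group universe of 11,344 OGs whose log2(target/reference)
# copy-number ratios follow N(1.03, 0.88^2), annotation links and
# memberships (including synthesized-ID cases), per-OG gene trees with
# planted orthology, a negative-binomial expression matrix with planted
# co-expression clusters, a 20-chromosome genome with a planted 1 Mb
# cluster of paralogue-rich genes, and SNP/SV tables with known categories.
source(file.path("analysis", "common.R"))

cfg <- study_config()
say("simulating fixture bundle (seed %d) into %s ...", ROOT_SEED, FIXTURE_DIR)
bundle <- write_fixture_bundle(cfg, FIXTURE_DIR, n_trees = 40L)

uni <- bundle$universe
say("OG universe: %d OGs, %d reference genes, %d target genes",
    nrow(uni$counts), sum(uni$counts$n_reference), sum(uni$counts$n_target))
say("assignment inputs: %d membership rows, %d links, %d flowering genes",
    nrow(uni$memberships), nrow(uni$links), length(uni$flowering))
say("gene trees emitted for %d OGs; expression matrix %d x %d; genome %d genes",
    length(bundle$tree_ogs), nrow(bundle$expression$em$values),
    ncol(bundle$expression$em$values), nrow(bundle$genome$genes))
say("planted cluster: %s:%d-%d with %d flagged genes",
    bundle$genome$cluster$chrom, bundle$genome$cluster$start,
    bundle$genome$cluster$end, length(bundle$genome$cluster$planted_genes))
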
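Package: orthoflora
Title: Orthologue-Group Analysis of Flowering-Gene Families Between a
    Model and a Crop Genome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A comparative-genomics workflow for identifying and
    characterising crop (soybean-style) orthologues of model-plant
    (Arabidopsis-style) flowering regulatory genes. Unifies annotation
    homologue links with pre-computed orthologue-group memberships,
    refines orthology from Newick gene trees with a patristic-distance
    clade rule, calls transcriptional activity under dataset-specific
    read-count rules, summarises per-group paralogue copy-number ratios
    on the log2 scale with k-standard-deviation classification, scans
    chromosomes for clusters of paralogue-rich genes, and intersects
    SNPs and structural variants with gene bodies and 1-kb promoters.
    Includes a synthetic-data generator with known ground truth for
    every stage and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    vcfR,
    mclust,
    withr,
    igraph,
    yaml
Config/testthat/edition: 3
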
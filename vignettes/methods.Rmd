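---
title: "Methods: orthologue-group analysis of flowering-gene families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: orthologue-group analysis of flowering-gene families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette describes the models and procedures implemented in
`orthoflora`, the assumptions behind them, the tunable parameters, and what
the synthetic-data generator does and does not emulate. The workflow targets
a recurring comparative-genomics setting: a crop genome (the *target*
species, soybean-style `Glyma*` identifiers) is interrogated for orthologues
of curated flowering regulatory genes of a model plant (the *reference*
species, Arabidopsis-style `AT*` identifiers), using pre-computed orthologue
groups, gene trees, expression atlases and a wild-relative variant catalogue
as inputs.

## Orthologue-group unification

Two sources place genes into orthologue groups (OGs): a per-gene annotation
link (each target gene names its closest reference gene) and a pre-computed
OG membership table. `merge_og_assignments()` unifies them with a fixed
precedence: a linked target gene inherits its reference gene's OG, and only
unlinked genes fall back to their own membership. When a linked reference
gene has no membership OG, a synthesized identifier `OG5_<locus>` is minted
and the reference gene plus its linked targets form a new group; synthesized
IDs are checked against the input ID space so they can never collide. Genes
with neither source are retained in an explicit unassigned bucket rather
than dropped, so coverage gaps stay auditable. The `source` column
(`link` / `membership` / `synthesized`) records which rule fired for every
gene, because the two sources can genuinely disagree and the precedence is a
design decision, not a fact about the data.

Isoform selection (`select_longest_isoform()`) keeps the longest protein per
locus; length ties are broken by the lexicographically smallest isoform
identifier purely for determinism.

## The clade rule for orthologue refinement

An OG can contain several reference genes, only some of which are flowering
genes; the gene tree of the OG decides which target genes are close
orthologues of the flowering members. The rule implemented in
`classify_target_gene()` is:

* find the **smallest informative clade** — the smallest clade containing
  the target leaf and at least one reference-species leaf. Trees are
  midpoint-rooted when the input is unrooted, because "clade" is undefined
  on an unrooted tree. Midpoint rooting is itself a choice: guide trees from
  common alignment pipelines are unrooted and no rooting is recorded with
  them.
* if that clade holds a flowering reference gene, the target gene is a
  *flowering orthologue*, **unless** some non-flowering reference gene
  anywhere in the tree is equally close or closer. Closeness is patristic
  distance (sum of branch lengths); "equally close" uses an absolute
  tolerance (default `1e-9`) because branch lengths are floating point.
  A `distance = "topological"` switch replaces branch lengths with unit
  edges for trees whose lengths are unreliable.
* a clade whose reference members are all non-flowering gives
  *other orthologue*; a tree with no reference leaf gives *unresolved*.

Trees cannot be built from fewer than four sequences, so small OGs use a
shortcut (`classify_og()`): if all reference members of a small OG are
flowering-listed, every target member is accepted as a flowering orthologue
(`via_small_og_rule = TRUE`); if a non-flowering reference member is
present, the target members stay unresolved. Bootstrap support labels are
parsed and preserved but never used in classification — no support
threshold is part of the rule.

Missing branch lengths default to zero with a warning, which degrades the
rule to pure clade membership: distances all tie at zero and the tolerance
turns every comparison into "equally close", so topology-only trees never
produce a spurious distance-based call.

## Expression activity and clustering

Two dataset-specific activity rules are supported: under `raw_reads` a gene
is transcriptionally active when some tissue has at least 2 reads; under
`normalized` when some tissue exceeds 0. Calls from two datasets combine by
OR. Flower expression re-applies the dataset's own rule restricted to the
declared flower conditions; the flower subset is configuration, never
inferred from tissue labels, because atlas vocabularies ("DAF", "Root Hair")
are free-form.

Profiles are standardised per gene with the population (divide-by-*n*)
deviation — the convention of the classic expression-clustering tools this
mirrors — and clustered with correlation distance (1 − Pearson *r*) under
average linkage by default. Zero-variance profiles get z-scores of 0 and
correlation distance 1 to every other profile, an explicit convention that
avoids NaN propagation. Tie handling inside the agglomeration follows
`stats::hclust`, which is deterministic for a fixed input ordering; tests
compare dendrograms through their cophenetic matrices, which are invariant
to how equal-height merges are labelled. Agreement between expression
clusters and sequence-derived groups is quantified with the adjusted Rand
index (`cluster_og_concordance()`).

## Paralogue copy-number statistics

For every OG with at least one gene in each species the statistic is
`log2(n_target / n_reference)`. OGs missing one species are excluded (the
ratio is undefined) and reported separately. The distribution is summarised
by its mean and standard deviation — sample (n−1) SD by default, the
estimator is recorded — and an OG is *paralogue-rich* when its ratio lies
strictly more than `k` SDs above the mean (default `k = 2`), *paralogue-less*
strictly below. Strict inequality follows the "more than k SD" reading;
ratios exactly at a threshold are typical. The thresholds are also reported
as plain fold changes, `2^(mean ± k·sd)`: at the published genome-wide
parameters (mean 1.03, SD 0.88 in log2) the upper threshold is 6.92 ≈ 7-fold
and the lower 0.60. Note the lower value is noticeably above 0.5, so
"half or less" prose summaries of such thresholds are approximations; the
package reports the exact value.

## Genomic distribution

`per_chromosome_fraction()` reports the exact per-chromosome fraction of
flagged (e.g. paralogue-rich-OG) genes; the percentage of recently
duplicated segments per chromosome is an *input* column from an external
resource, never computed here. `window_scan()` tiles each chromosome with
windows (default 1.4 Mb wide, 100 kb step — the width follows the analysis
being reproduced, the step is a discretisation choice) and counts flagged
genes per window; a gene belongs to a window iff its *start* coordinate lies
inside, which is unambiguous for boundary-straddling genes. Windows are
ranked by count with deterministic tie-breaking, and coordinates are emitted
both 1-based inclusive and 0-based half-open (BED).

## Variant overlap

Gene models are 1-based inclusive (GFF3 convention) with CDS intervals
merged per gene. The promoter is the 1 kb strictly upstream of the gene
body, strand-aware, truncated at chromosome bounds, never overlapping its
own gene body (overlap with a *neighbouring* gene is allowed and simply
reported — each SNP is counted per gene independently). SNP categories
partition the chromosome per gene: `CDS`, `genic_noncoding` (gene body
outside every CDS; UTR status is not modelled, so this bucket covers introns
and untranslated gene sequence), `promoter`, `outside`. The census counts
genes whose SNPs all avoid CDS among genes carrying at least one SNP, with
the percentage reported at one decimal. SV overlap uses closed-interval
intersection against the gene body, optionally extended by the promoter —
enabling the promoter can only add flags. Enrichment of flagged genes in a
subset uses the two-sided Fisher's exact test with the sample
(cross-product) odds ratio; this is an artifact statistic — the analysis
being reproduced reported only a qualitative statement.

## The synthetic-data generator

The generator (`simulation_config()` and the `generate_*` functions) defines
the study conditions under which the workflow is validated:

* **OG universe** — 11,344 OGs; reference counts `1 + Poisson(0.83)` so the
  mean (≈1.83) matches roughly 20,700 reference genes over 11,344 groups;
  target counts `max(1, round(n_ref · 2^z))` with `z ~ N(1.03, 0.88²)`. The
  normal law in log2 space and its parameters are the published genome-wide
  values; the Poisson form for reference counts is this package's choice
  (only the ratio structure matters downstream). Integer rounding slightly
  perturbs realized ratios; linear nearest-integer rounding was chosen
  because it leaves mean and SD recoverable within 3 standard errors at
  this size, and true OG classes are recorded from the generating `z`, not
  the rounded counts.
* **gene trees** — each target gene is planted as the orthologue of one
  reference gene; trees are built ultrametrically with within-orthologue
  joins (step 0.1) far shallower than backbone joins (step 5), so at zero
  branch noise the planted anchor is provably the closest reference leaf
  and recovery is exact. Gaussian branch noise (truncated at 0) degrades
  this gracefully.
* **expression** — planted clusters share disjoint high-expression
  condition blocks; counts are negative-binomial around the template
  (dispersion 0 gives the template exactly); some genes are forced all-zero.
* **genome and variants** — genes on a uniform 10 kb grid (no overlap by
  construction), two CDS exons with an intron each; one planted 1 Mb
  cluster of 60 flagged genes on one chromosome plus 2% background flags;
  SNPs planted per category with known truth; SVs planted to hit a body, a
  promoter only, or nothing.

One root seed derives a fixed per-stream seed per stage, so the whole
bundle is byte-identical under a fixed seed and stages can be re-run in
isolation.

What the generator does **not** emulate: real sequence evolution (no
alignments; trees and tables only), tandem-duplication structure, gene
density variation along chromosomes, linkage between expression and tree
topology, or OrthoMCL's false-positive/negative behaviour. Passing the
recovery tests therefore shows the *inference chain* is correct under its
stated assumptions — not that those assumptions hold for any particular
genome release.

## Problem sizes and numerical conventions

The test suite and the analysis drivers use a full-size OG universe
(11,344 OGs — cheap, it is only count sampling) but deliberately small
instances elsewhere: 20–40 gene trees of 4–12 leaves, expression matrices of
tens of genes, genomes of a few thousand grid-placed genes, and tens to
hundreds of variants. These sizes make every brute-force oracle (path
walking, exhaustive clade enumeration, naive O(n³) linkage, all-pairs
interval checks, hypergeometric enumeration) affordable while exercising
every code path. Pipeline TSV output is serialised at 6 significant digits
for byte-stable reruns; distance tolerance defaults to `1e-9`; percentage
summaries round to one decimal.

## Known limitations

* The clade rule depends on the rooting of unrooted inputs; midpoint
  rooting is sensible for roughly clock-like families but can misplace the
  root under strong rate variation.
* "Closer" is branch-length based by default; for trees with unreliable
  lengths the topological switch changes calls.
* The promoter is a fixed-length upstream window; no TSS annotation is
  used.
* The enrichment test treats genes as exchangeable; no correction for gene
  length or SNP density is attempted.
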
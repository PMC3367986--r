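#!/usr/bin/env Rscript
# Stage 8 — the same chain end to end through the pipeline driver: one
# config, fail-fast validation, deterministic TSV outputs and a JSON run
# manifest with input checksums and per-stage row counts.
source(file.path("analysis", "common.R"))
ensure_fixtures()

cfg <- pipeline_config(
  out_dir = file.path(RESULTS_DIR, "pipeline"),
  inputs = list(links = file.path(FIXTURE_DIR, "links.tsv"),
                memberships = file.path(FIXTURE_DIR, "memberships.tsv"),
                flowering = file.path(FIXTURE_DIR, "flowering.tsv"),
                trees_dir = file.path(FIXTURE_DIR, "trees"),
                expression = file.path(FIXTURE_DIR, "expression.tsv"),
                genes = file.path(FIXTURE_DIR, "genes.tsv"),
                gff = file.path(FIXTURE_DIR, "genes.gff3"),
                variants = file.path(FIXTURE_DIR, "variants.tsv")),
  seed = ROOT_SEED)

manifest <- suppressWarnings(run_pipeline(cfg))
for (st in names(manifest$stages)) {
  say("stage %-10s rows_out = %d", st, manifest$stages[[st]]$rows_out)
}
say("manifest written to %s", file.path(cfg$out_dir, "manifest.json"))
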
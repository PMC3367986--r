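# Shared settings for the analysis drivers: one root seed, one fixture
# directory, one simulation configuration (the study conditions).
suppressPackageStartupMessages(library(orthoflora))

ROOT_SEED <- 42L
FIXTURE_DIR <- file.path("results", "fixtures")
RESULTS_DIR <- "results"

study_config <- function() {
  simulation_config(seed = ROOT_SEED, n_ogs = 11344L,
                    log2_ratio_mean = 1.03, log2_ratio_sd = 0.88)
}

ensure_fixtures <- function() {
  if (!file.exists(file.path(FIXTURE_DIR, "og_counts.tsv"))) {
    stop("fixtures not found under ", FIXTURE_DIR,
         "; run analysis/01_simulate.R first", call. = FALSE)
  }
  invisible(FIXTURE_DIR)
}

say <- function(...) cat(sprintf(...), "\n", sep = "")
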
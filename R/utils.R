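#' Default species prefix map
#'
#' Gene identifiers carry their species in a name prefix: `AT` for the
#' reference (model) species, `Glyma` for the target (crop) species, and
#' `Alyr_`, `Bradi`, `Medtr` or `AC` for the outgroup species that may appear
#' in gene trees. Longer prefixes are matched before shorter ones, so `AC`
#' never shadows `AT`.
#'
#' @return Named character vector mapping ID prefix to species role
#'   (`"reference"`, `"target"` or `"other"`).
#' @export
default_species_prefixes <- function() {
  c(Glyma = "target", Alyr_ = "other", Bradi = "other", Medtr = "other",
    AT = "reference", AC = "other")
}

#' Infer species role from gene identifiers
#'
#' @param ids Character vector of gene identifiers.
#' @param prefixes Named character vector mapping ID prefixes to species
#'   roles; see [default_species_prefixes()].
#' @return Character vector of species roles; `NA` where no prefix matches.
#' @export
infer_species <- function(ids, prefixes = default_species_prefixes()) {
  stopifnot(is.character(ids))
  # longest prefix wins (e.g. "Alyr_" before "AT" is irrelevant, but "AT"
  # must not swallow "AC...": exact prefix match, longest first)
  ord <- order(nchar(names(prefixes)), decreasing = TRUE)
  prefixes <- prefixes[ord]
  out <- rep(NA_character_, length(ids))
  for (p in names(prefixes)) {
    hit <- is.na(out) & startsWith(ids, p)
    out[hit] <- prefixes[[p]]
  }
  out
}

#' Derive a per-stream seed from a root seed
#'
#' All stochastic stages draw from streams seeded deterministically from one
#' root seed, so stages re-run in isolation reproduce the full-run output.
#' The derived value stays below 2^31 - 1.
#'
#' @param seed Integer root seed.
#' @param stream Stream name, one of the known stage streams.
#' @return Integer seed for `set.seed()`.
#' @export
derive_seed <- function(seed, stream) {
  offsets <- c(og_universe = 11L, trees = 23L, expression = 37L,
               genome = 53L, variants = 71L, pipeline = 89L)
  if (!stream %in% names(offsets)) {
    stop("unknown seed stream: ", stream)
  }
  (abs(as.integer(seed)) %% 21000000L) * 100L + offsets[[stream]]
}

#' Write a data frame as TSV with stable float formatting
#'
#' Numeric columns are serialised at 6 significant digits so repeated runs
#' produce byte-identical files.
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv6 <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.double(x[[j]])) x[[j]] <- signif(x[[j]], 6)
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with a header row
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

# internal: stop unless x is a data.frame containing the named columns
.need_cols <- function(x, cols, what) {
  if (!is.data.frame(x)) stop(what, " must be a data frame")
  miss <- setdiff(cols, names(x))
  if (length(miss)) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  }
  invisible(x)
}
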
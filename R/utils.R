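#' polytag: digital gene expression tag profiling
#'
#' Clean-tag filtering, one-mismatch tag-to-gene mapping, TPM
#' quantification, Audic-Claverie differential expression, mid-parent-value
#' non-additivity classification, enrichment and clustering, plus a
#' synthetic diploid/amphidiploid tag-library generator with ground truth.
#'
#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive a per-task integer seed from a master seed; stays below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 31 + 7919 * as.numeric(offset)) %% 2147483629)
}

# Tally a character vector into a named integer count vector (sorted keys).
count_sequences <- function(x) {
  if (length(x) == 0L) {
    return(structure(integer(0), names = character(0)))
  }
  r <- rle(sort(x))
  structure(as.integer(r$lengths), names = r$values)
}

# Round half away from zero, matching how percentages are printed in DGE
# summary tables (base round() is half-to-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

percent_of <- function(num, den, digits = 2) {
  ifelse(den > 0, round_half_up(100 * num / den, digits), 0)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n_seqs, lengths) {
  vapply(lengths, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
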
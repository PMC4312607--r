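#!/usr/bin/env Rscript
# Mid-parent-value analysis of the three amphidiploids: classify every
# expressed gene as above/below/at the MPV of its two diploid parents,
# break down by parental dominance, and score the classification against
# the simulation's ground truth.

suppressPackageStartupMessages(library(polytag))

lib_size <- function(sp) {
  read_tag_library(sprintf("results/sim/clean_%s.tsv", sp), sp,
                   clean = TRUE)$clean_total
}
prof <- function(sp) {
  d <- read.delim(sprintf("results/sim/profile_%s.tsv", sp),
                  stringsAsFactors = FALSE)
  structure(d, species = sp, library_size = lib_size(sp),
            class = c("expression_profile", "data.frame"))
}
truth <- read.delim("results/sim/truth.tsv", stringsAsFactors = FALSE)

for (am in names(amphidiploid_parents())) {
  par <- amphidiploid_parents()[[am]]
  res <- classify_nonadditive(prof(am), prof(par[1]), prof(par[2]))
  write_tsv(res$records, sprintf("results/mpv_records_%s.tsv", am))
  rp <- res$report
  write_tsv(rp$dominance, sprintf("results/mpv_report_%s.tsv", am))
  message(sprintf("%s (%s x %s): a = %d non-additive; above %.1f%%, below %.1f%%",
                  am, par[1], par[2], rp$a,
                  rp$directions$pct_of_a[1], rp$directions$pct_of_a[2]))

  tr <- truth[truth$species == am & !is.na(truth$additivity_class), ]
  dir_truth <- structure(ifelse(tr$additivity_class == "above_mpv", "above",
                         ifelse(tr$additivity_class == "below_mpv", "below",
                                "additive")), names = tr$gene_id)
  r <- res$records
  r$truth <- dir_truth[r$gene_id]
  na_r <- r[!is.na(r$truth) & r$truth %in% c("above", "below") &
              r$direction != "excluded", ]
  message(sprintf("  directional recovery of truly non-additive genes: %.1f%% (n=%d)",
                  100 * mean(na_r$direction == na_r$truth), nrow(na_r)))
}
message("\nWith tolerance 0 nearly every expressed gene deviates from the ",
        "MPV by sampling noise alone, as in published non-additivity tables; ",
        "the directional recovery shows the truly non-additive genes are ",
        "classified on the correct side.")
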
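#!/usr/bin/env Rscript
# Pairwise differential expression among the three diploids with the
# Audic-Claverie test (FDR <= 0.001, |log2 TPM ratio| >= 1), plus the
# expressed-gene Venn decomposition.

suppressPackageStartupMessages(library(polytag))

# library sizes are re-derived from the stored clean libraries
lib_size <- function(sp) {
  read_tag_library(sprintf("results/sim/clean_%s.tsv", sp), sp,
                   clean = TRUE)$clean_total
}
profiles <- lapply(c(P1 = "P1", P2 = "P2", P3 = "P3"), function(sp) {
  d <- read.delim(sprintf("results/sim/profile_%s.tsv", sp),
                  stringsAsFactors = FALSE)
  structure(d, species = sp, library_size = lib_size(sp),
            class = c("expression_profile", "data.frame"))
})

pairs <- list(c("P1", "P3"), c("P2", "P1"), c("P2", "P3"))
deg_summary <- list()
for (pr in pairs) {
  cmp <- paste(pr[1], "vs", pr[2])
  d <- call_degs(profiles[[pr[1]]], profiles[[pr[2]]])
  write_tsv(d, sprintf("results/degs_%s_vs_%s.tsv", pr[1], pr[2]))
  deg_summary[[cmp]] <- data.frame(
    comparison = cmp, n_tested = nrow(d),
    n_up = attr(d, "n_up"), n_down = attr(d, "n_down"))
  message(sprintf("%s: %d up, %d down (of %d tested genes)",
                  cmp, attr(d, "n_up"), attr(d, "n_down"), nrow(d)))
}
write_tsv(do.call(rbind, deg_summary), "results/deg_summary.tsv")

es <- expressed_sets(profiles, min_count = 1)
write_json_report(es$venn, "results/expressed_venn_diploids.json")
message(sprintf("co-expressed in all three diploids: %d genes",
                es$venn[["P1&P2&P3"]]))
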
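#!/usr/bin/env Rscript
# Term enrichment of the DEG sets (hypergeometric upper tail, BH q-values
# within namespace), keyword filtering of annotated DEGs, and hierarchical
# clustering of the top DEGs across the six libraries.
#
# Annotation is normally a user-supplied TSV (gene_id, term_id, namespace,
# label); here a synthetic annotation is generated with one enrichment
# signal planted: the genes most up-regulated in P2 vs P1 share a term.

suppressPackageStartupMessages(library(polytag))

set.seed(60)
genes <- read.delim("results/sim/profile_P1.tsv",
                    stringsAsFactors = FALSE)$gene_id

# synthetic flat annotation: 40 pathways of 40-200 genes each, plus a
# planted term covering the strongest up-calls of one comparison
degs <- read.delim("results/degs_P2_vs_P1.tsv", stringsAsFactors = FALSE)
up <- degs$gene_id[degs$call == "up"]
ann <- do.call(rbind, c(
  lapply(1:40, function(t) data.frame(
    gene_id = sample(genes, sample(40:200, 1)),
    term_id = sprintf("PW%04d", t), namespace = "pathway",
    label = sprintf("synthetic pathway %d", t), stringsAsFactors = FALSE)),
  list(data.frame(
    gene_id = unique(c(head(up, 40), sample(genes, 20))),
    term_id = "PW9001", namespace = "pathway",
    label = "planted up-regulated pathway", stringsAsFactors = FALSE)),
  list(data.frame(
    gene_id = sample(genes, 25), term_id = "GO9002", namespace = "go",
    label = "S-adenosylmethionine-dependent methyltransferase activity",
    stringsAsFactors = FALSE))
))
write_tsv(ann, "results/sim/annotation.tsv")
annotation <- read_annotation("results/sim/annotation.tsv")

universe <- genes
res <- enrich_terms(unique(degs$gene_id[degs$call != "not_significant"]),
                    universe, annotation)
write_tsv(res, "results/enrichment_P2_vs_P1.tsv")
message(sprintf("enrichment (P2 vs P1): %d terms tested, %d enriched at q <= 0.05",
                nrow(res), sum(res$enriched)))
message("top term: ", res$term_id[1], " (", res$label[1], "), q = ",
        signif(res$q_value[1], 3))

# keyword filtering across the three diploid comparisons
deg_tables <- lapply(list.files("results", "^degs_.*\\.tsv$",
                                full.names = TRUE), function(f) {
  d <- read.delim(f, stringsAsFactors = FALSE)
  structure(d, class = c("deg_table", "data.frame"))
})
names(deg_tables) <- sub("^degs_(.*)\\.tsv$", "\\1",
                         list.files("results", "^degs_.*\\.tsv$"))
kw <- keyword_filter(deg_tables, annotation,
                     c("methyltransferase", "methylase"))
write_json_report(kw$per_comparison, "results/methyltransferase_degs.json")
message("methyltransferase-annotated DEGs per comparison: ",
        paste(names(kw$per_comparison), lengths(kw$per_comparison),
              collapse = ", "))

# cluster the 60 strongest DEGs over all six expression profiles
species <- c("P1", "P2", "P3", names(amphidiploid_parents()))
tpm <- sapply(species, function(sp) {
  read.delim(sprintf("results/sim/profile_%s.tsv", sp),
             stringsAsFactors = FALSE)$tpm
})
rownames(tpm) <- genes
top <- degs$gene_id[order(degs$fdr)][1:60]
dend <- cluster_degs(tpm[top, ], distance = "one_minus_pearson")
hc <- as.hclust(dend)
write_tsv(data.frame(order = dend$order, gene = dend$labels[dend$order]),
          "results/deg_cluster_leaf_order.tsv")
write_tsv(data.frame(merge1 = dend$merge[, 1], merge2 = dend$merge[, 2],
                     height = dend$height),
          "results/deg_cluster_merges.tsv")
message(sprintf("clustered %d DEGs; merge heights span %.3f - %.3f",
                length(top), min(dend$height), max(dend$height)))
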
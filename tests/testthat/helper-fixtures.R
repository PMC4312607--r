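# Shared fixtures, built in code. The mid-scale simulation is computed once
# per test run and reused by the property tests.

make_reference <- function(sequences, ids = sprintf("G%03d", seq_along(sequences))) {
  structure(data.frame(gene_id = ids, sequence = sequences,
                       stringsAsFactors = FALSE),
            class = c("reference_set", "data.frame"))
}

make_profile <- function(counts, library_size, species = "X") {
  prof <- data.frame(gene_id = names(counts), count = as.numeric(counts),
                     stringsAsFactors = FALSE)
  prof$tpm <- prof$count * 1e6 / library_size
  structure(prof, species = species, library_size = library_size,
            class = c("expression_profile", "data.frame"))
}

published_tag_stats <- function() {
  utils::read.delim(system.file("extdata", "brassica_tag_stats.tsv",
                                package = "polytag"),
                    stringsAsFactors = FALSE)
}

published_nonadditive_counts <- function() {
  utils::read.delim(system.file("extdata", "brassica_nonadditive_counts.tsv",
                                package = "polytag"),
                    stringsAsFactors = FALSE)
}

# mid-scale simulated libraries reused across tests (800 genes, 1e5 tags)
sim_cache <- new.env(parent = emptyenv())
midscale_sim <- function() {
  if (is.null(sim_cache$mid)) {
    cfg <- sim_config(n_genes = 800, depth = 1e5, seed = 11)
    ref <- generate_reference(cfg)
    truth <- simulate_truth(ref, cfg)
    lib <- sample_tags(ref, truth, "P1", cfg)
    clean <- filter_raw_tags(lib)
    catalog <- build_catalog(ref)
    sim_cache$mid <- list(cfg = cfg, ref = ref, truth = truth, raw = lib,
                          clean = clean, catalog = catalog,
                          mapping = map_tags(clean, catalog))
  }
  sim_cache$mid
}
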
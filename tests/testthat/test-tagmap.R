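test_that("catalog construction matches a brute-force two-strand scan", {
  ref <- make_reference(c(
    "AAACATGTTTTTTTTTTTTTTTTTAAA",          # one sense site
    "GGGGGGGGGGGGGGGGGGGGGGGGGGG",          # no CATG on either strand
    paste0("CATG", strrep("AC", 12))        # site(s), check by scan
  ))
  catalog <- build_catalog(ref)
  for (i in seq_len(nrow(ref))) {
    want <- oracle_scan_tags(ref$sequence[i])
    got <- catalog$entries[catalog$entries$gene_id == ref$gene_id[i], ]
    expect_setequal(paste(got$tag, got$strand, got$offset),
                    paste(want$tag, want$strand, want$offset))
  }
  expect_false(ref$gene_id[2] %in% catalog$entries$gene_id)
  # every entry reproducible by substring extraction
  for (j in seq_len(nrow(catalog$entries))) {
    e <- catalog$entries[j, ]
    s <- ref$sequence[ref$gene_id == e$gene_id]
    if (e$strand == "antisense") {
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    expect_equal(substr(s, e$offset + 1, e$offset + 21), e$tag)
    expect_equal(substr(e$tag, 1, 4), "CATG")
  }
})

test_that("a tag window shared by two genes yields two entries under one key", {
  shared <- paste0("CATG", strrep("A", 8), strrep("C", 9))
  ref <- make_reference(c(paste0("GG", shared, "GG"),
                          paste0("TT", shared, "TTTT")))
  catalog <- build_catalog(ref)
  expect_equal(sum(catalog$entries$tag == shared & catalog$entries$strand == "sense"), 2)
  expect_equal(catalog$keys$n_genes[catalog$keys$tag == shared], 2)
})

test_that("map_tags agrees with the exhaustive Hamming oracle on a small catalog", {
  cfg <- sim_config(n_genes = 12, length_range = c(60, 120), seed = 77)
  ref <- generate_reference(cfg)
  catalog <- build_catalog(ref)
  expect_lte(nrow(catalog$keys), 200)

  set.seed(42)
  keys <- catalog$keys$tag
  queries <- unique(c(
    keys[1:5],                                        # exact hits
    vapply(keys[1:10], function(k) {                  # 1-mismatch variants
      p <- sample(5:21, 1)
      b <- setdiff(c("A", "C", "G", "T"), substr(k, p, p))[1]
      substr(k, p, p) <- b; k
    }, character(1)),
    vapply(1:10, function(i) paste0("CATG",           # random tags
      paste(sample(c("A", "C", "G", "T"), 17, replace = TRUE), collapse = "")),
      character(1))
  ))
  lib <- tag_library(structure(rep(2L, length(queries)), names = queries),
                     clean = TRUE)
  got <- map_tags(lib, catalog)$per_tag
  for (i in seq_len(nrow(got))) {
    want <- oracle_map_tag(got$tag[i], catalog)
    expect_equal(got$category[i], want$category, info = got$tag[i])
    expect_equal(got$gene_id[i], want$gene_id, info = got$tag[i])
    if (want$category != "unknown") {
      expect_equal(got$mismatch_used[i], want$mismatch_used, info = got$tag[i])
    }
  }
})

test_that("exact hits take precedence and gene-level ambiguity is used", {
  # gene A and B share tag T exactly; T is ambiguous even though a
  # 1-mismatch neighbour resolves uniquely elsewhere
  tA <- paste0("CATG", strrep("A", 17))
  tC <- paste0("CATG", strrep("C", 17))
  ref <- make_reference(c(paste0("GG", tA), paste0("CC", tA), paste0("AA", tC)),
                        ids = c("gA", "gB", "gC"))
  catalog <- build_catalog(ref)
  lib <- tag_library(structure(c(3L, 4L), names = c(tA, tC)), clean = TRUE)
  got <- map_tags(lib, catalog)$per_tag
  expect_equal(got$category[got$tag == tA], "ambiguous_gene")
  expect_equal(got$mismatch_used[got$tag == tA], 0L)
  expect_equal(got$category[got$tag == tC], "unambiguous_gene")

  # several positions within ONE gene still count as unambiguous
  t2 <- paste0("CATG", strrep("G", 17))
  refm <- make_reference(paste0(t2, "TT", t2), ids = "gMulti")
  libm <- tag_library(structure(2L, names = t2), clean = TRUE)
  gotm <- map_tags(libm, build_catalog(refm))$per_tag
  expect_equal(gotm$category, "unambiguous_gene")
  expect_equal(gotm$gene_id, "gMulti")
})

test_that("anchor handling during the mismatch search is configurable", {
  t0 <- paste0("CATG", strrep("A", 17))
  ref <- make_reference(paste0("GG", t0), ids = "gA")
  catalog <- build_catalog(ref)
  # a variable-position mismatch maps under either anchor policy
  qv <- t0; substr(qv, 10, 10) <- "G"
  libv <- tag_library(structure(2L, names = qv), clean = TRUE)
  expect_equal(map_tags(libv, catalog, fix_anchor = TRUE)$per_tag$category,
               "unambiguous_gene")
  expect_equal(map_tags(libv, catalog, fix_anchor = FALSE)$per_tag$category,
               "unambiguous_gene")
})

test_that("mapping categories partition the clean library", {
  sim <- midscale_sim()
  agg <- sim$mapping$aggregates
  expect_equal(sum(agg$total), sim$clean$clean_total)
  expect_equal(sum(agg$distinct), sim$clean$clean_distinct)
})

test_that("with no errors and no junk every clean tag maps (unknown = 0)", {
  cfg <- sim_config(n_genes = 150, depth = 3e4, error_rate = 0, junk_frac = 0,
                    frac_silent = 0, seed = 19)
  ref <- generate_reference(cfg)
  tr <- simulate_truth(ref, cfg)
  clean <- filter_raw_tags(sample_tags(ref, tr, "P2", cfg))
  mp <- map_tags(clean, build_catalog(ref))
  expect_equal(mp$aggregates$total[mp$aggregates$category == "unknown"], 0)
})

test_that("mapping summary reproduces published library percentages", {
  stats <- published_tag_stats()
  br <- stats[stats$species == "Br", ]
  s <- mapping_summary_from_counts(
    species = "Br",
    raw_total = br$raw_total, raw_distinct = br$raw_distinct,
    clean_total = br$clean_total, clean_distinct = br$clean_distinct,
    gene_total = br$gene_total, gene_distinct = br$gene_distinct,
    unambiguous_total = br$unambiguous_total,
    unambiguous_distinct = br$unambiguous_distinct,
    tag_mapped_genes = br$tag_mapped_genes,
    unambiguous_tag_mapped_genes = br$unambiguous_tag_mapped_genes,
    genome_total = br$genome_total, genome_distinct = br$genome_distinct,
    unknown_total = br$unknown_total, unknown_distinct = br$unknown_distinct,
    n_ref_genes = br$ref_genes
  )
  expect_equal(s$unambiguous_total_pct, 27.91)
  expect_equal(s$genome_total_pct, 40.51)
  expect_equal(s$unambiguous_distinct_pct, 29.52)
  expect_equal(s$tag_mapped_genes_pct, 46.20)
  expect_equal(s$unknown_total_pct, 26.84)

  # zero case
  s0 <- mapping_summary_from_counts(clean_total = 100, clean_distinct = 10,
                                    unambiguous_total = 0)
  expect_equal(s0$unambiguous_total_pct, 0)

  # full six-library check of every percentage column
  for (i in seq_len(nrow(stats))) {
    row <- stats[i, ]
    s <- mapping_summary_from_counts(
      clean_total = row$clean_total, clean_distinct = row$clean_distinct,
      unambiguous_total = row$unambiguous_total,
      unambiguous_distinct = row$unambiguous_distinct,
      tag_mapped_genes = row$tag_mapped_genes,
      unambiguous_tag_mapped_genes = row$unambiguous_tag_mapped_genes,
      genome_total = row$genome_total, genome_distinct = row$genome_distinct,
      unknown_total = row$unknown_total, unknown_distinct = row$unknown_distinct,
      n_ref_genes = row$ref_genes
    )
    expect_equal(s$unambiguous_total_pct,
                 c(27.91, 28.33, 24.87, 33.06, 26.15, 28.19)[i])
    expect_equal(s$genome_total_pct,
                 c(40.51, 19.87, 35.50, 37.17, 34.95, 25.84)[i])
    expect_equal(s$tag_mapped_genes_pct,
                 c(46.20, 40.53, 45.05, 48.47, 53.42, 47.20)[i])
    expect_equal(s$unambiguous_tag_mapped_genes_pct,
                 c(40.25, 33.68, 38.79, 42.38, 47.18, 40.43)[i])
  }
})

test_that("summarize_mapping rejects a mismatched library/result pair", {
  sim <- midscale_sim()
  other <- tag_library(c("CATGAAAAAAAAAAAAAAAAA" = 2), clean = TRUE)
  expect_error(summarize_mapping(sim$mapping, other), "correspond")
  s <- summarize_mapping(sim$mapping, sim$clean, n_ref_genes = 800)
  expect_equal(s$unambiguous_total + s$unknown_total +
                 (s$gene_total - s$unambiguous_total), s$clean_total)
})
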
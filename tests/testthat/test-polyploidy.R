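test_that("mid-parent values are parental means, symmetric, zero-filled", {
  p1 <- make_profile(c(g1 = 10, g2 = 0, g3 = 7), 1e6)
  p2 <- make_profile(c(g1 = 30, g2 = 0, g4 = 4), 1e6)
  m <- compute_mpv(p1, p2)
  expect_equal(m$mpv[m$gene_id == "g1"], 20)
  expect_equal(m$mpv[m$gene_id == "g2"], 0)
  expect_equal(m$mpv[m$gene_id == "g3"], 3.5)   # missing parent zero-filled
  expect_equal(m$mpv[m$gene_id == "g4"], 2)

  set.seed(5)
  cnt1 <- structure(rpois(100, 50), names = sprintf("g%03d", 1:100))
  cnt2 <- structure(rpois(100, 50), names = sprintf("g%03d", 1:100))
  pa <- make_profile(cnt1, 1e6); pb <- make_profile(cnt2, 1e6)
  expect_equal(compute_mpv(pa, pb)$mpv, compute_mpv(pb, pa)$mpv)
})

test_that("direction and dominance classification follow the MPV comparison", {
  amphi <- make_profile(c(g1 = 25, g2 = 10, g3 = 20), 1e6)
  p1 <- make_profile(c(g1 = 10, g2 = 20, g3 = 20), 1e6)
  p2 <- make_profile(c(g1 = 30, g2 = 20, g3 = 20), 1e6)
  res <- classify_nonadditive(amphi, p1, p2)
  r <- res$records
  expect_equal(r$direction[r$gene_id == "g1"], "above")     # 25 > mpv 20
  expect_equal(r$dominance[r$gene_id == "g1"], "p1_lt_p2")
  expect_equal(r$direction[r$gene_id == "g2"], "below")     # 10 < mpv 20
  expect_equal(r$direction[r$gene_id == "g3"], "additive")  # 20 == mpv 20
  expect_equal(r$dominance[r$gene_id == "g3"], "p1_eq_p2")
})

test_that("universe policy: all-zero genes dropped, min_detect excludes from a", {
  amphi <- make_profile(c(g1 = 0, g2 = 8, g3 = 50), 1e6)
  p1 <- make_profile(c(g1 = 10, g2 = 0, g3 = 10), 1e6)
  p2 <- make_profile(c(g1 = 10, g2 = 0, g3 = 10), 1e6)
  res <- classify_nonadditive(amphi, p1, p2, min_detect = 5)
  r <- res$records
  expect_equal(r$direction[r$gene_id == "g1"], "excluded")  # amphi below min_detect
  expect_equal(r$direction[r$gene_id == "g2"], "above")     # mpv 0, amphi > 0
  expect_equal(r$direction[r$gene_id == "g3"], "above")
  # partition: every universe gene is above/below/additive/excluded
  expect_true(all(r$direction %in% c("above", "below", "additive", "excluded")))
  expect_equal(res$report$a,
               sum(r$direction %in% c("above", "below")))
})

test_that("the non-additivity report reproduces the published percentages", {
  tab <- published_nonadditive_counts()
  bn <- tab[tab$amphidiploid == "Bn", ]
  rep_bn <- nonadditivity_report(
    above = structure(bn$above, names = bn$dominance),
    below = structure(bn$below, names = bn$dominance)
  )
  expect_equal(rep_bn$a, 19844)
  expect_equal(rep_bn$directions$count, c(9605, 10239))
  expect_equal(rep_bn$directions$pct_of_a, c(48.4, 51.6))
  dom <- rep_bn$dominance
  expect_equal(dom$a, c(9519, 10325))
  expect_equal(dom$a_pct, c(48.0, 52.0))
  expect_equal(dom$above_pct, c(54.3, 45.7))
  expect_equal(dom$above_pct_of_dom, c(54.8, 42.5))
  expect_equal(dom$below_pct, c(42.0, 58.0))
  expect_equal(dom$below_pct_of_dom, c(45.2, 57.5))

  # internal consistency across all three amphidiploids: every percentage
  # equals its count ratio within rounding
  for (am in unique(tab$amphidiploid)) {
    t <- tab[tab$amphidiploid == am, ]
    rp <- nonadditivity_report(
      above = structure(t$above, names = t$dominance),
      below = structure(t$below, names = t$dominance)
    )
    expect_equal(sum(rp$directions$count), rp$a)
    expect_equal(sum(rp$dominance$a), rp$a)
    expect_equal(rp$dominance$above + rp$dominance$below, rp$dominance$a)
    b_tot <- rp$directions$count[1]; c_tot <- rp$directions$count[2]
    expect_equal(rp$directions$pct_of_a,
                 polytag:::round_half_up(100 * c(b_tot, c_tot) / rp$a, 1))
    expect_equal(rp$dominance$above_pct_of_dom,
                 polytag:::round_half_up(100 * rp$dominance$above / rp$dominance$a, 1))
  }
})

test_that("an additive simulation is classified additive under tolerance", {
  # a flat abundance law so every gene is sampled deeply enough for the 5%
  # tolerance band to dominate sampling noise (counts ~ 1e4 per gene)
  cfg <- sim_config(n_genes = 200, depth = 2e6, abundance_sdlog = 0.5,
                    error_rate = 0, junk_frac = 0,
                    frac_nonadditive = 0, frac_silent = 0, seed = 29)
  ref <- generate_reference(cfg)
  tr <- simulate_truth(ref, cfg)
  tt <- polytag:::gene_tag_table(ref)
  catalog <- build_catalog(ref)
  prof <- lapply(c("P1", "P2", "P1xP2"), function(sp) {
    clean <- filter_raw_tags(sample_tags(ref, tr, sp, cfg, tag_table = tt))
    quantify(map_tags(clean, catalog), clean, genes = ref$gene_id)
  })
  res <- classify_nonadditive(prof[[3]], prof[[1]], prof[[2]],
                              tolerance = 0.05, min_detect = 5)
  r <- res$records[res$records$direction != "excluded", ]
  # with zero tolerance nearly everything deviates by sampling noise alone;
  # with a 5% band and deep error-free sampling the additive truth shows
  expect_gte(mean(r$direction == "additive"), 0.95)
})

test_that("truly non-additive genes are recovered directionally", {
  cfg <- sim_config(n_genes = 800, depth = 4e5, error_rate = 0, junk_frac = 0,
                    frac_nonadditive = 0.3, frac_silent = 0, seed = 37)
  ref <- generate_reference(cfg)
  tr <- simulate_truth(ref, cfg)
  tt <- polytag:::gene_tag_table(ref)
  catalog <- build_catalog(ref)
  prof <- lapply(c("P1", "P2", "P1xP2"), function(sp) {
    clean <- filter_raw_tags(sample_tags(ref, tr, sp, cfg, tag_table = tt))
    quantify(map_tags(clean, catalog), clean, genes = ref$gene_id)
  })
  res <- classify_nonadditive(prof[[3]], prof[[1]], prof[[2]])
  r <- res$records
  cl <- tr$classes[tr$classes$amphidiploid == "P1xP2", ]
  truth_dir <- structure(ifelse(cl$additivity_class == "above_mpv", "above",
                         ifelse(cl$additivity_class == "below_mpv", "below",
                                "additive")), names = cl$gene_id)
  r$truth <- truth_dir[r$gene_id]
  nonadd <- r[r$truth %in% c("above", "below") & r$direction != "excluded", ]
  expect_gte(mean(nonadd$direction == nonadd$truth), 0.9)
})

test_that("the optional significance tier flags only directional genes", {
  amphi <- make_profile(c(g1 = 400, g2 = 100, g3 = 100), 1e6)
  p1 <- make_profile(c(g1 = 100, g2 = 100, g3 = 90), 1e6)
  p2 <- make_profile(c(g1 = 100, g2 = 100, g3 = 110), 1e6)
  res <- classify_nonadditive(amphi, p1, p2, test = TRUE)
  r <- res$records
  expect_true(r$significant[r$gene_id == "g1"])
  expect_false(r$significant[r$gene_id == "g2"])
  expect_true(all(r$direction[r$significant] %in% c("above", "below")))
})

test_that("expressed-gene sets and Venn regions partition the union", {
  pr <- list(
    A = make_profile(c(g1 = 5, g2 = 5, g3 = 5, g4 = 0), 1e6),
    B = make_profile(c(g1 = 5, g2 = 5, g5 = 5), 1e6),
    C = make_profile(c(g1 = 5, g6 = 5), 1e6)
  )
  es <- expressed_sets(pr, min_count = 1)
  expect_equal(es$pairwise["A", "B"], 2)
  expect_equal(unname(es$venn["A&B&C"]), 1)
  expect_equal(unname(es$venn["A&B"]), 1)        # g2 (excluding g1)
  expect_equal(sum(es$venn), length(unique(unlist(es$sets))))

  # identical profiles: everything in the centre
  es_id <- expressed_sets(list(A = pr$A, B = pr$A, C = pr$A))
  expect_equal(unname(es_id$venn["A&B&C"]), 3)
  expect_equal(sum(es_id$venn) - es_id$venn[["A&B&C"]], 0)

  # disjoint profiles: empty intersections
  es_dj <- expressed_sets(list(A = make_profile(c(x = 2), 1e6),
                               B = make_profile(c(y = 2), 1e6)))
  expect_equal(es_dj$pairwise["A", "B"], 0)
  expect_error(expressed_sets(list(A = pr$A)), "at least 2")

  # random sets: 7 regions always sum to the union size
  set.seed(17)
  for (i in 1:5) {
    mk <- function(n) {
      ids <- sample(sprintf("g%03d", 1:200), n)
      make_profile(structure(rep(2, n), names = ids), 1e6)
    }
    es_r <- expressed_sets(list(A = mk(100), B = mk(120), C = mk(80)))
    expect_equal(sum(es_r$venn), length(unique(unlist(es_r$sets))))
  }
})
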
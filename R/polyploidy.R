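#' Mid-parent expression values
#'
#' The additive expectation for an amphidiploid: the arithmetic mean of the
#' two diploid parents' TPM values, per gene, over the union gene universe
#' (zero-filled). TPM scale is used because the parental libraries differ
#' in size.
#'
#' @param profile_p1,profile_p2 parental `expression_profile`s.
#' @return data.frame `gene_id`, `tpm_p1`, `tpm_p2`, `mpv`.
#' @export
compute_mpv <- function(profile_p1, profile_p2) {
  stopifnot(inherits(profile_p1, "expression_profile"),
            inherits(profile_p2, "expression_profile"))
  genes <- sort(union(profile_p1$gene_id, profile_p2$gene_id))
  pick <- function(p, what) {
    v <- p[[what]][match(genes, p$gene_id)]
    ifelse(is.na(v), 0, v)
  }
  data.frame(gene_id = genes,
             tpm_p1 = pick(profile_p1, "tpm"),
             tpm_p2 = pick(profile_p2, "tpm"),
             mpv = (pick(profile_p1, "tpm") + pick(profile_p2, "tpm")) / 2,
             stringsAsFactors = FALSE)
}

#' Classify amphidiploid genes against the mid-parent value
#'
#' Compares each gene's amphidiploid TPM with the mid-parent value of its
#' two diploid parents. Direction is `above` / `below` / `additive` with a
#' relative tolerance (default 0: any inequality counts, which makes nearly
#' every expressed gene non-additive, matching how such tables are usually
#' tallied without a significance filter). Dominance is determined solely
#' by the parents (`p1_gt_p2`, `p1_lt_p2`, `p1_eq_p2`). Genes with zero
#' counts in all three libraries are dropped; genes with an amphidiploid
#' count below `min_detect` are marked `excluded` and do not enter the
#' report. An optional significance tier tests the amphidiploid counts
#' against a pseudo-mid-parent library (rounded mean of parental counts,
#' mean of parental sizes) with [ac_pvalue()] and [bh_fdr()].
#'
#' @param profile_amphi,profile_p1,profile_p2 `expression_profile`s.
#' @param tolerance relative tolerance around the MPV inside which a gene is
#'   additive (default 0).
#' @param min_detect minimum amphidiploid count for a gene to be classified
#'   (default 1).
#' @param test run the optional Audic-Claverie significance tier.
#' @param fdr_max FDR threshold for the significance tier.
#' @return list with `records` (per-gene `mpv_record` data.frame) and
#'   `report` (a [nonadditivity_report()]).
#' @export
classify_nonadditive <- function(profile_amphi, profile_p1, profile_p2,
                                 tolerance = 0, min_detect = 1,
                                 test = FALSE, fdr_max = 0.001) {
  stopifnot(inherits(profile_amphi, "expression_profile"))
  mpv <- compute_mpv(profile_p1, profile_p2)
  genes <- sort(union(mpv$gene_id, profile_amphi$gene_id))
  pick <- function(p, what) {
    v <- p[[what]][match(genes, p$gene_id)]
    ifelse(is.na(v), 0, v)
  }
  d <- data.frame(
    gene_id = genes,
    count_amphi = pick(profile_amphi, "count"),
    tpm_amphi = pick(profile_amphi, "tpm"),
    tpm_p1 = mpv$tpm_p1[match(genes, mpv$gene_id)],
    tpm_p2 = mpv$tpm_p2[match(genes, mpv$gene_id)],
    stringsAsFactors = FALSE
  )
  d$tpm_p1[is.na(d$tpm_p1)] <- 0
  d$tpm_p2[is.na(d$tpm_p2)] <- 0
  d$mpv <- (d$tpm_p1 + d$tpm_p2) / 2
  # silent everywhere -> out of the universe entirely
  d <- d[d$count_amphi > 0 | d$tpm_p1 > 0 | d$tpm_p2 > 0, , drop = FALSE]
  if (nrow(d) == 0L) stopf("no gene expressed in any of the three libraries")
  d$direction <- ifelse(d$count_amphi < min_detect, "excluded",
                 ifelse(d$tpm_amphi > d$mpv * (1 + tolerance), "above",
                 ifelse(d$tpm_amphi < d$mpv * (1 - tolerance), "below",
                        "additive")))
  d$dominance <- ifelse(d$tpm_p1 > d$tpm_p2, "p1_gt_p2",
                 ifelse(d$tpm_p1 < d$tpm_p2, "p1_lt_p2", "p1_eq_p2"))
  if (test) {
    x_pseudo <- floor((pick(profile_p1, "count")[match(d$gene_id, genes)] +
                       pick(profile_p2, "count")[match(d$gene_id, genes)]) / 2
                      + 0.5)  # rounded (half-up) mean of parental counts
    N_pseudo <- (attr(profile_p1, "library_size") +
                 attr(profile_p2, "library_size")) / 2
    d$p_value <- ac_pvalue(x_pseudo, d$count_amphi,
                           N_pseudo, attr(profile_amphi, "library_size"))
    d$fdr <- bh_fdr(d$p_value)
    d$significant <- d$fdr <= fdr_max & d$direction %in% c("above", "below")
  }
  rownames(d) <- NULL
  records <- structure(d, class = c("mpv_record", "data.frame"))
  cell <- function(dir, dom) sum(d$direction == dir & d$dominance == dom)
  report <- nonadditivity_report(
    above = c(p1_gt_p2 = cell("above", "p1_gt_p2"),
              p1_lt_p2 = cell("above", "p1_lt_p2"),
              p1_eq_p2 = cell("above", "p1_eq_p2")),
    below = c(p1_gt_p2 = cell("below", "p1_gt_p2"),
              p1_lt_p2 = cell("below", "p1_lt_p2"),
              p1_eq_p2 = cell("below", "p1_eq_p2"))
  )
  list(records = records, report = report)
}

#' Non-additive expression summary table
#'
#' Builds the summary of non-additively expressed genes from the (direction
#' x parental-dominance) cell counts: `a` is the number of non-additive
#' genes (above + below the MPV), each direction is reported with its count
#' and percentage of `a`, and each dominance class with its share of `a`,
#' of the direction totals, and of its own subtotal. Percentages are
#' rounded half-up to 1 decimal.
#'
#' @param above,below named integer vectors of gene counts per dominance
#'   class (`p1_gt_p2`, `p1_lt_p2`, optionally `p1_eq_p2`).
#' @return a `nonadditivity_report`: list with `a`, `directions`
#'   (data.frame), and `dominance` (data.frame).
#' @export
nonadditivity_report <- function(above, below) {
  doms <- union(names(above), names(below))
  ab <- function(v, d) if (d %in% names(v)) as.numeric(v[[d]]) else 0
  b_tot <- sum(vapply(doms, ab, numeric(1), v = above))
  c_tot <- sum(vapply(doms, ab, numeric(1), v = below))
  a <- b_tot + c_tot
  directions <- data.frame(
    direction = c("above", "below"),
    count = c(b_tot, c_tot),
    pct_of_a = c(percent_of(b_tot, a, 1), percent_of(c_tot, a, 1)),
    stringsAsFactors = FALSE
  )
  dominance <- do.call(rbind, lapply(doms, function(d) {
    bi <- ab(above, d); ci <- ab(below, d); ai <- bi + ci
    data.frame(
      dominance = d, a = ai, a_pct = percent_of(ai, a, 1),
      above = bi, above_pct = percent_of(bi, b_tot, 1),
      above_pct_of_dom = percent_of(bi, ai, 1),
      below = ci, below_pct = percent_of(ci, c_tot, 1),
      below_pct_of_dom = percent_of(ci, ai, 1),
      stringsAsFactors = FALSE
    )
  }))
  drop0 <- dominance$dominance == "p1_eq_p2" & dominance$a == 0
  dominance <- dominance[!drop0, , drop = FALSE]
  rownames(dominance) <- NULL
  structure(list(a = a, directions = directions, dominance = dominance),
            class = "nonadditivity_report")
}

#' @export
print.nonadditivity_report <- function(x, ...) {
  cat(sprintf("<nonadditivity_report> a = %d non-additive genes\n", x$a))
  print(x$directions, ...)
  print(x$dominance, ...)
  invisible(x)
}

#' Expressed-gene sets and their intersections
#'
#' A gene is "expressed" in a library iff its unambiguous count is at least
#' `min_count`. Returns the per-species sets, all pairwise intersection
#' sizes, and for exactly three profiles the full 7-region Venn
#' decomposition.
#'
#' @param profiles named list of >= 2 `expression_profile`s.
#' @param min_count detection threshold (>= 1).
#' @return list with `sets`, `pairwise` (matrix of intersection sizes), and
#'   `venn` (named 7-region counts, 3 profiles only).
#' @export
expressed_sets <- function(profiles, min_count = 1L) {
  if (length(profiles) < 2L) stopf("need at least 2 profiles")
  if (min_count < 1L) stopf("min_count must be >= 1")
  if (is.null(names(profiles))) {
    names(profiles) <- vapply(profiles, function(p) {
      s <- attr(p, "species"); if (is.null(s) || is.na(s)) "?" else s
    }, character(1))
  }
  sets <- lapply(profiles, function(p) p$gene_id[p$count >= min_count])
  nm <- names(sets)
  pairwise <- outer(seq_along(sets), seq_along(sets),
                    Vectorize(function(i, j) length(intersect(sets[[i]], sets[[j]]))))
  dimnames(pairwise) <- list(nm, nm)
  venn <- NULL
  if (length(sets) == 3L) {
    s1 <- sets[[1]]; s2 <- sets[[2]]; s3 <- sets[[3]]
    inall <- intersect(intersect(s1, s2), s3)
    venn <- c(
      length(setdiff(setdiff(s1, s2), s3)),
      length(setdiff(setdiff(s2, s1), s3)),
      length(setdiff(setdiff(s3, s1), s2)),
      length(setdiff(intersect(s1, s2), s3)),
      length(setdiff(intersect(s1, s3), s2)),
      length(setdiff(intersect(s2, s3), s1)),
      length(inall)
    )
    names(venn) <- c(paste0(nm, "_only"),
                     paste(nm[1], nm[2], sep = "&"),
                     paste(nm[1], nm[3], sep = "&"),
                     paste(nm[2], nm[3], sep = "&"),
                     paste(nm, collapse = "&"))
  }
  list(sets = sets, pairwise = pairwise, venn = venn)
}
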
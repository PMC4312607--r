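#' Per-gene expression profile from unambiguous tags
#'
#' Sums the copy numbers of unambiguous tags per gene and normalizes to
#' tags per million (TPM) with the clean-tag total of the library as the
#' normalizer: `tpm = count * 1e6 / clean_total`. Genes without any
#' unambiguous tag are absent unless a gene universe is supplied, in which
#' case they are zero-filled.
#'
#' @param mapping a `mapping_result`.
#' @param clean the clean `tag_library` the mapping was derived from.
#' @param genes optional character vector of gene ids to zero-fill.
#' @param library_size normalizer; defaults to `clean$clean_total` (the
#'   tag-profiling convention); pass e.g. the gene-mapped total to use a
#'   mapped-tag normalizer instead.
#' @return an `expression_profile`: data.frame `gene_id`, `count`, `tpm`
#'   with attributes `species` and `library_size`.
#' @export
quantify <- function(mapping, clean, genes = NULL,
                     library_size = clean$clean_total) {
  stopifnot(inherits(mapping, "mapping_result"), inherits(clean, "tag_library"))
  if (!isTRUE(all.equal(mapping$clean_total, clean$clean_total))) {
    stopf("mapping result does not correspond to this library")
  }
  if (is.na(library_size) || library_size <= 0) {
    stopf("library size must be positive")
  }
  pt <- mapping$per_tag
  un <- pt[pt$category == "unambiguous_gene", , drop = FALSE]
  cnt <- tapply(un$count, un$gene_id, sum)
  prof <- data.frame(gene_id = names(cnt), count = as.numeric(cnt),
                     stringsAsFactors = FALSE)
  if (!is.null(genes)) {
    miss <- setdiff(genes, prof$gene_id)
    if (length(miss)) {
      prof <- rbind(prof, data.frame(gene_id = miss, count = 0,
                                     stringsAsFactors = FALSE))
    }
    prof <- prof[match(genes, prof$gene_id), , drop = FALSE]
  } else {
    prof <- prof[order(prof$gene_id), , drop = FALSE]
  }
  rownames(prof) <- NULL
  prof$tpm <- prof$count * 1e6 / library_size
  structure(prof, species = mapping$species, library_size = library_size,
            class = c("expression_profile", "data.frame"))
}

#' Sequencing saturation curve
#'
#' Shuffles the clean-tag stream with a fixed seed, consumes it in
#' increments of `step` tags, and records after each increment how many
#' genes have at least one unambiguous tag. Used to check that gene
#' discovery plateaus well before full depth.
#'
#' @param clean a clean `tag_library`, or a character vector of tag
#'   occurrences (the stream).
#' @param catalog a `tag_catalog`.
#' @param step increment in tags (>= 1).
#' @param seed shuffle seed.
#' @param fix_anchor passed to [map_tags()].
#' @return a `saturation_curve` data.frame: `reads_sampled`,
#'   `genes_detected`, starting at (0, 0).
#' @export
saturation_curve <- function(clean, catalog, step = 1e5L, seed = 1L,
                             fix_anchor = TRUE) {
  if (step < 1L) stopf("step must be >= 1")
  if (inherits(clean, "tag_library")) {
    if (!isTRUE(clean$clean)) stopf("saturation_curve requires a clean library")
    stream_lib <- clean
    stream <- rep.int(names(clean$counts), clean$counts)
  } else {
    stream <- as.character(clean)
    stream_lib <- tag_library(count_sequences(stream), clean = TRUE)
  }
  n <- length(stream)
  if (n == 0L) {
    return(structure(data.frame(reads_sampled = 0L, genes_detected = 0L),
                     class = c("saturation_curve", "data.frame")))
  }
  stream <- with_seed(seed, sample(stream, n))
  mp <- map_tags(stream_lib, catalog, fix_anchor = fix_anchor)
  gene_of <- mp$per_tag$gene_id[match(stream, mp$per_tag$tag)]
  first_idx <- tapply(seq_len(n)[!is.na(gene_of)], gene_of[!is.na(gene_of)], min)
  checkpoints <- unique(c(seq(step, n, by = step), n))
  detected <- vapply(checkpoints,
                     function(k) sum(first_idx <= k), numeric(1))
  structure(data.frame(reads_sampled = c(0L, checkpoints),
                       genes_detected = as.integer(c(0L, detected))),
            class = c("saturation_curve", "data.frame"))
}

ratio_classes <- function() c("<=2x", "2-5x", "5-10x", ">10x", "infinite")

#' Fold-ratio distribution between two libraries or profiles
#'
#' For every item (distinct tag or gene) observed in at least one of the two
#' inputs, computes the fold ratio of normalized abundance (larger over
#' smaller, so the distribution is symmetric in its arguments) and bins it
#' into the classes <=2x, 2-5x, 5-10x, >10x; items observed in only one
#' input fall in a dedicated "infinite" class. Used to show that the vast
#' majority of tags differ by at most five-fold between libraries.
#'
#' @param a,b two `expression_profile`s (compared on TPM) or two clean
#'   `tag_library`s (compared on per-million-normalized copy numbers).
#' @return data.frame `class`, `n`, `fraction`.
#' @export
ratio_distribution <- function(a, b) {
  val <- function(x) {
    if (inherits(x, "expression_profile")) {
      structure(x$tpm, names = x$gene_id)
    } else if (inherits(x, "tag_library")) {
      if (!isTRUE(x$clean)) stopf("ratio_distribution requires clean libraries")
      x$counts * 1e6 / x$clean_total
    } else stopf("inputs must be expression profiles or tag libraries")
  }
  va <- val(a); vb <- val(b)
  if (sum(va) == 0 && sum(vb) == 0) stopf("both inputs are empty")
  keys <- union(names(va), names(vb))
  xa <- ifelse(is.na(match(keys, names(va))), 0, va[match(keys, names(va))])
  xb <- ifelse(is.na(match(keys, names(vb))), 0, vb[match(keys, names(vb))])
  seen <- xa > 0 | xb > 0
  xa <- xa[seen]; xb <- xb[seen]
  hi <- pmax(xa, xb); lo <- pmin(xa, xb)
  cls <- ifelse(lo == 0, "infinite",
         ifelse(hi / lo <= 2, "<=2x",
         ifelse(hi / lo <= 5, "2-5x",
         ifelse(hi / lo <= 10, "5-10x", ">10x"))))
  n <- vapply(ratio_classes(), function(cl) sum(cls == cl), numeric(1))
  data.frame(class = ratio_classes(), n = as.integer(n),
             fraction = if (sum(n) > 0) n / sum(n) else rep(0, length(n)),
             row.names = NULL, stringsAsFactors = FALSE)
}
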
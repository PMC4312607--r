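#' Construct a tag library
#'
#' A tag library is the per-species multiset of 21-bp tags: a named integer
#' vector mapping tag sequence to copy number, plus raw/clean bookkeeping
#' totals. Raw libraries may still contain N-bearing, short, or singleton
#' tags; [filter_raw_tags()] turns a raw library into a clean one.
#'
#' @param counts named integer vector (tag sequence -> copy number).
#' @param species species identifier.
#' @param raw_total,raw_distinct raw bookkeeping totals; default to the
#'   totals of `counts`.
#' @param clean logical; is this a post-filter (clean) library?
#' @return object of class `tag_library`.
#' @export
tag_library <- function(counts, species = NA_character_,
                        raw_total = sum(counts),
                        raw_distinct = length(counts),
                        clean = FALSE) {
  counts <- structure(as.integer(counts), names = names(counts))
  if (length(counts) && is.null(names(counts))) {
    stopf("counts must be a named vector (tag sequence -> copy number)")
  }
  if (any(counts < 0L)) stopf("tag copy numbers must be non-negative")
  lib <- list(species = species, counts = counts,
              raw_total = as.numeric(raw_total),
              raw_distinct = as.integer(raw_distinct),
              clean_total = if (clean) sum(as.numeric(counts)) else NA_real_,
              clean_distinct = if (clean) length(counts) else NA_integer_,
              clean = clean)
  structure(lib, class = "tag_library")
}

#' @export
print.tag_library <- function(x, ...) {
  cat(sprintf("<tag_library> species=%s %s: %d distinct / %s total tags\n",
              x$species, if (x$clean) "clean" else "raw",
              length(x$counts), format(sum(as.numeric(x$counts)))), ...)
  invisible(x)
}

is_clean_tag <- function(tags) {
  nchar(tags) == 21L & startsWith(tags, "CATG") & !grepl("[^ACGT]", tags)
}

#' Filter a raw tag library into clean tags
#'
#' Applies the clean-tag definition of CATG-anchored DGE profiling: after
#' aggregating identical sequences (uppercased), removes empty tags, tags
#' containing any base outside A/C/G/T (unknown nucleotides "N"), tags not
#' exactly 21 bp, tags not beginning with the NlaIII site CATG, tags
#' matching a supplied adaptor sequence, and finally tags with a library
#' copy number of exactly 1. Anchor/length filters run before singleton
#' removal.
#'
#' @param raw a `tag_library` (raw).
#' @param adaptors character vector of adaptor sequences to drop (default
#'   none; adaptor trimming is upstream of simulated data).
#' @return a clean `tag_library` with `clean_total`/`clean_distinct` set and
#'   raw totals carried over. Pathological input yields an empty clean
#'   library, never an error.
#' @export
filter_raw_tags <- function(raw, adaptors = character()) {
  stopifnot(inherits(raw, "tag_library"))
  counts <- raw$counts
  names(counts) <- toupper(names(counts))
  if (anyDuplicated(names(counts))) {
    counts <- tapply(as.integer(counts), names(counts), sum)
    counts <- structure(as.integer(counts), names = names(counts))
  }
  keep <- !is.na(names(counts)) & nchar(names(counts)) > 0L &
    is_clean_tag(names(counts)) & counts > 0L
  if (length(adaptors)) keep <- keep & !(names(counts) %in% toupper(adaptors))
  counts <- counts[keep]
  counts <- counts[counts >= 2L]  # singleton removal, after aggregation
  counts <- counts[order(names(counts))]
  tag_library(counts, species = raw$species,
              raw_total = raw$raw_total, raw_distinct = raw$raw_distinct,
              clean = TRUE)
}

default_copy_bins <- function() c(2L, 6L, 11L, 21L, 51L, 101L)

#' Copy-number distribution of a clean tag library
#'
#' Bins distinct tags by copy number and reports the distinct and total tag
#' count (and fraction) per bin. Default bins are 2-5, 6-10, 11-20, 21-50,
#' 51-100, >100 copies, the classes used to show that few high-abundance
#' tags dominate a library.
#'
#' @param clean a clean `tag_library`.
#' @param bin_edges strictly increasing integer lower edges; the last bin is
#'   open-ended.
#' @return data.frame with columns `bin`, `distinct`, `total`,
#'   `frac_distinct`, `frac_total`.
#' @export
copy_number_histogram <- function(clean, bin_edges = default_copy_bins()) {
  stopifnot(inherits(clean, "tag_library"))
  if (!isTRUE(clean$clean)) stopf("copy_number_histogram requires a clean library")
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stopf("bin_edges must be strictly increasing")
  }
  nb <- length(bin_edges)
  labels <- c(paste0(bin_edges[-nb], "-", bin_edges[-1] - 1L),
              paste0(">", bin_edges[nb] - 1L))
  cnt <- as.numeric(clean$counts)
  bin <- findInterval(cnt, bin_edges)
  if (length(cnt) && any(bin == 0L)) stopf("counts below the first bin edge")
  distinct <- tabulate(bin, nbins = nb)
  total <- vapply(seq_len(nb), function(b) sum(cnt[bin == b]), numeric(1))
  nd <- sum(distinct); nt <- sum(total)
  data.frame(
    bin = labels, distinct = distinct, total = total,
    frac_distinct = if (nd > 0) distinct / nd else rep(0, nb),
    frac_total = if (nt > 0) total / nt else rep(0, nb),
    stringsAsFactors = FALSE
  )
}
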
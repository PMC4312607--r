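#' Build the reference tag catalog
#'
#' Enumerates every 21-bp tag (CATG + 17 following bases) at every CATG
#' occurrence on the sense sequence of each gene and on its reverse
#' complement (antisense transcription), so clean tags can be looked up
#' directly. A tag shared by several genes holds one entry per gene.
#'
#' @param reference a `reference_set`.
#' @return a `tag_catalog`: list with `entries` (data.frame `tag`,
#'   `gene_id`, `strand`, `offset`; offsets are 0-based positions of the
#'   CATG within the stored strand sequence), `keys` (per distinct tag:
#'   number of distinct genes and the gene when unique), `key_genes` (list
#'   of gene sets per key), and `gene_ids`.
#' @export
build_catalog <- function(reference) {
  stopifnot(inherits(reference, "reference_set"))
  ent <- list()
  for (strand in c("sense", "antisense")) {
    seqs <- if (strand == "sense") reference$sequence
            else reverse_complement(reference$sequence)
    sites <- lapply(seqs, taggable_sites)
    n_sites <- lengths(sites)
    if (sum(n_sites) == 0L) next
    gene <- rep.int(reference$gene_id, n_sites)
    pos <- unlist(sites, use.names = FALSE)
    seqv <- rep.int(seqs, n_sites)
    ent[[strand]] <- data.frame(
      tag = substring(seqv, pos, pos + 20L),
      gene_id = gene, strand = strand, offset = pos - 1L,
      stringsAsFactors = FALSE
    )
  }
  entries <- if (length(ent)) do.call(rbind, ent) else
    data.frame(tag = character(0), gene_id = character(0),
               strand = character(0), offset = integer(0))
  rownames(entries) <- NULL
  # per-key gene summary: unique (tag, gene) pairs, grouped by tag
  o <- order(entries$tag, entries$gene_id)
  tg <- entries[o, c("tag", "gene_id")]
  dup <- duplicated(tg)
  tg <- tg[!dup, , drop = FALSE]
  if (nrow(tg)) {
    r <- rle(tg$tag)
    keys <- data.frame(tag = r$values, n_genes = r$lengths,
                       stringsAsFactors = FALSE)
    keys$gene_id <- ifelse(keys$n_genes == 1L,
                           tg$gene_id[cumsum(r$lengths)], NA_character_)
    key_genes <- split(tg$gene_id, factor(tg$tag, levels = keys$tag))
  } else {
    keys <- data.frame(tag = character(0), n_genes = integer(0),
                       gene_id = character(0), stringsAsFactors = FALSE)
    key_genes <- list()
  }
  structure(list(entries = entries, keys = keys, key_genes = key_genes,
                 gene_ids = unique(reference$gene_id)),
            class = "tag_catalog")
}

# all Hamming-1 neighbours of each tag over the given positions, as a
# data.frame(query = index into tags, neighbour = sequence)
hamming1_neighbours <- function(tags, positions) {
  if (length(tags) == 0L) {
    return(data.frame(query = integer(0), neighbour = character(0)))
  }
  bases <- c("A", "C", "G", "T")
  out_q <- list(); out_n <- list(); k <- 0L
  for (pos in positions) {
    cur <- substr(tags, pos, pos)
    for (b in bases) {
      diff <- cur != b
      if (!any(diff)) next
      neigh <- tags[diff]
      substr(neigh, pos, pos) <- b
      k <- k + 1L
      out_q[[k]] <- which(diff)
      out_n[[k]] <- neigh
    }
  }
  data.frame(query = unlist(out_q, use.names = FALSE),
             neighbour = unlist(out_n, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Map clean tags to genes with at most one mismatch
#'
#' Each clean tag is first looked up exactly; tags without an exact hit are
#' looked up at every Hamming-distance-1 neighbour. By default mismatches
#' are restricted to the 17 variable bases (the CATG anchor is enzymatic and
#' held fixed); `fix_anchor = FALSE` searches all 21 positions. The union of
#' gene ids over all hits decides the category: exactly one gene (possibly
#' several positions within it) is `unambiguous_gene`, two or more genes is
#' `ambiguous_gene`, no hit is `unknown`. Exact hits take precedence: when a
#' 0-mismatch hit exists, 1-mismatch neighbours are never consulted.
#'
#' @param clean a clean `tag_library`.
#' @param catalog a `tag_catalog`.
#' @param fix_anchor keep the CATG anchor fixed during the mismatch search.
#' @return a `mapping_result`: list with `per_tag` (data.frame `tag`,
#'   `count`, `category`, `gene_id`, `mismatch_used`) and an `aggregates`
#'   data.frame of total/distinct counts per category.
#' @export
map_tags <- function(clean, catalog, fix_anchor = TRUE) {
  stopifnot(inherits(clean, "tag_library"), inherits(catalog, "tag_catalog"))
  if (!isTRUE(clean$clean)) stopf("map_tags requires a clean library")
  if (nrow(catalog$keys) == 0L) stopf("catalog is empty")
  tags <- names(clean$counts)
  if (length(tags) && !all(is_clean_tag(tags))) {
    stopf("library contains tags violating the clean-tag invariants")
  }
  category <- rep("unknown", length(tags))
  gene_id <- rep(NA_character_, length(tags))
  mismatch_used <- rep(NA_integer_, length(tags))
  tag_genes <- vector("list", length(tags))

  m0 <- match(tags, catalog$keys$tag)
  exact <- !is.na(m0)
  category[exact] <- ifelse(catalog$keys$n_genes[m0[exact]] == 1L,
                            "unambiguous_gene", "ambiguous_gene")
  gene_id[exact & category == "unambiguous_gene"] <-
    catalog$keys$gene_id[m0[exact & category == "unambiguous_gene"]]
  mismatch_used[exact] <- 0L
  tag_genes[exact] <- catalog$key_genes[m0[exact]]

  todo <- which(!exact)
  if (length(todo)) {
    positions <- if (fix_anchor) 5:21 else 1:21
    nb <- hamming1_neighbours(tags[todo], positions)
    hit <- match(nb$neighbour, catalog$keys$tag)
    ok <- !is.na(hit)
    if (any(ok)) {
      genes_per_query <- lapply(
        split(hit[ok], nb$query[ok]),
        function(keyidx) unique(unlist(catalog$key_genes[keyidx],
                                       use.names = FALSE))
      )
      qidx <- todo[as.integer(names(genes_per_query))]
      ng <- lengths(genes_per_query)
      category[qidx] <- ifelse(ng == 1L, "unambiguous_gene", "ambiguous_gene")
      gene_id[qidx[ng == 1L]] <-
        vapply(genes_per_query[ng == 1L], `[[`, character(1), 1L)
      mismatch_used[qidx] <- 1L
      tag_genes[qidx] <- genes_per_query
    }
  }
  per_tag <- data.frame(tag = tags, count = as.numeric(clean$counts),
                        category = category, gene_id = gene_id,
                        mismatch_used = mismatch_used,
                        stringsAsFactors = FALSE)
  rownames(per_tag) <- NULL
  agg <- do.call(rbind, lapply(
    c("unambiguous_gene", "ambiguous_gene", "unknown"),
    function(cat) data.frame(
      category = cat,
      total = sum(per_tag$count[per_tag$category == cat]),
      distinct = sum(per_tag$category == cat), stringsAsFactors = FALSE)
  ))
  structure(list(per_tag = per_tag, tag_genes = tag_genes, aggregates = agg,
                 species = clean$species,
                 clean_total = clean$clean_total,
                 clean_distinct = clean$clean_distinct),
            class = "mapping_result")
}

#' Library-level mapping summary
#'
#' Reproduces the row structure of a DGE tag-statistics table: raw and clean
#' totals, gene-mapped and unambiguous totals/distinct counts with their
#' percentages of clean tags (2 decimals), tag-mapped gene counts with
#' percentages of reference genes, and the unknown class. Ambiguous tags
#' hitting several genes are part of "gene-mapped" but not of
#' "unambiguous". With a transcript-only reference there is no intergenic
#' class: tags mapping nowhere are all `unknown`.
#'
#' @param result a `mapping_result`.
#' @param clean the clean `tag_library` the result was derived from.
#' @param n_ref_genes optional reference gene count; when supplied the
#'   percent-of-reference-genes columns are added.
#' @return one-row data.frame of summary statistics.
#' @export
summarize_mapping <- function(result, clean, n_ref_genes = NULL) {
  stopifnot(inherits(result, "mapping_result"), inherits(clean, "tag_library"))
  if (!isTRUE(clean$clean)) stopf("summarize_mapping requires the clean library")
  if (!isTRUE(all.equal(result$clean_total, clean$clean_total)) ||
      !identical(result$clean_distinct, clean$clean_distinct)) {
    stopf("mapping result does not correspond to this library")
  }
  pt <- result$per_tag
  unamb <- pt$category == "unambiguous_gene"
  amb <- pt$category == "ambiguous_gene"
  unk <- pt$category == "unknown"
  genes_all <- unique(unlist(result$tag_genes[unamb | amb], use.names = FALSE))
  genes_unamb <- unique(pt$gene_id[unamb])
  mapping_summary_from_counts(
    species = clean$species,
    raw_total = clean$raw_total, raw_distinct = clean$raw_distinct,
    clean_total = clean$clean_total, clean_distinct = clean$clean_distinct,
    gene_total = sum(pt$count[unamb | amb]),
    gene_distinct = sum(unamb | amb),
    unambiguous_total = sum(pt$count[unamb]),
    unambiguous_distinct = sum(unamb),
    tag_mapped_genes = length(genes_all),
    unambiguous_tag_mapped_genes = length(genes_unamb),
    unknown_total = sum(pt$count[unk]), unknown_distinct = sum(unk),
    n_ref_genes = n_ref_genes
  )
}

#' Mapping summary percentages from count inputs
#'
#' Computes every derived percentage of a DGE tag-statistics table from its
#' integer counts, so published library statistics can be re-derived and
#' checked. Percentages of clean tags and of reference genes are rounded
#' half-up to 2 decimals.
#'
#' @param species library label.
#' @param raw_total,raw_distinct,clean_total,clean_distinct library totals.
#' @param gene_total,gene_distinct tags mapped to any gene.
#' @param unambiguous_total,unambiguous_distinct tags mapped to exactly one
#'   gene.
#' @param tag_mapped_genes,unambiguous_tag_mapped_genes gene counts reached
#'   by any / by unambiguous tags.
#' @param genome_total,genome_distinct optional intergenic (genome-only)
#'   class, reported only when supplied.
#' @param unknown_total,unknown_distinct unmapped tags.
#' @param n_ref_genes reference gene count (for percent-of-reference rows).
#' @return one-row data.frame with counts and `*_pct` columns.
#' @export
mapping_summary_from_counts <- function(species = NA_character_,
                                        raw_total = NA_real_,
                                        raw_distinct = NA_integer_,
                                        clean_total, clean_distinct,
                                        gene_total = NA_real_,
                                        gene_distinct = NA_integer_,
                                        unambiguous_total = NA_real_,
                                        unambiguous_distinct = NA_integer_,
                                        tag_mapped_genes = NA_integer_,
                                        unambiguous_tag_mapped_genes = NA_integer_,
                                        genome_total = NULL,
                                        genome_distinct = NULL,
                                        unknown_total = NA_real_,
                                        unknown_distinct = NA_integer_,
                                        n_ref_genes = NULL) {
  pct <- function(x, den) if (is.null(x) || is.na(x)) NA_real_ else
    percent_of(x, den, digits = 2)
  out <- data.frame(
    species = species, raw_total = raw_total, raw_distinct = raw_distinct,
    clean_total = clean_total, clean_distinct = clean_distinct,
    gene_total = gene_total, gene_distinct = gene_distinct,
    unambiguous_total = unambiguous_total,
    unambiguous_total_pct = pct(unambiguous_total, clean_total),
    unambiguous_distinct = unambiguous_distinct,
    unambiguous_distinct_pct = pct(unambiguous_distinct, clean_distinct),
    tag_mapped_genes = tag_mapped_genes,
    unambiguous_tag_mapped_genes = unambiguous_tag_mapped_genes,
    unknown_total = unknown_total,
    unknown_total_pct = pct(unknown_total, clean_total),
    unknown_distinct = unknown_distinct,
    unknown_distinct_pct = pct(unknown_distinct, clean_distinct),
    stringsAsFactors = FALSE
  )
  if (!is.null(genome_total)) {
    out$genome_total <- genome_total
    out$genome_total_pct <- pct(genome_total, clean_total)
  }
  if (!is.null(genome_distinct)) {
    out$genome_distinct <- genome_distinct
    out$genome_distinct_pct <- pct(genome_distinct, clean_distinct)
  }
  if (!is.null(n_ref_genes)) {
    out$tag_mapped_genes_pct <- pct(tag_mapped_genes, n_ref_genes)
    out$unambiguous_tag_mapped_genes_pct <-
      pct(unambiguous_tag_mapped_genes, n_ref_genes)
  }
  out
}
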
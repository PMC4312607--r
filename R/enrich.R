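#' Read a gene-to-term annotation table
#'
#' Annotation is a user-supplied flat TSV: `gene_id`, `term_id`,
#' `namespace`, `label`. Terms are treated as flat sets (no ontology
#' propagation).
#'
#' @param path TSV file path.
#' @return `annotation_map` data.frame.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("gene_id", "term_id", "namespace", "label")
  if (!all(need %in% names(ann))) {
    stopf("annotation must have columns %s", paste(need, collapse = ", "))
  }
  structure(ann[need], class = c("annotation_map", "data.frame"))
}

#' Hypergeometric term enrichment of a DEG set
#'
#' For every term annotating at least one universe gene, computes the
#' hypergeometric upper-tail probability of seeing `k` or more DEGs in the
#' term: `p = sum_{i >= k} C(K,i) C(N-K, n-i) / C(N,n)` with `N` the
#' universe size, `K` the term's universe genes, and `n` the DEG count.
#' Q-values are Benjamini-Hochberg within each namespace (mirroring
#' separate GO / pathway analyses); a term is `enriched` when
#' `q <= q_max`.
#'
#' @param deg_set character vector of DEG gene ids (must be within
#'   `universe`).
#' @param universe character vector of background gene ids (typically all
#'   tag-mapped genes of the comparison).
#' @param annotation an `annotation_map` (or data.frame with its columns).
#' @param q_max enrichment flag threshold (default 0.05).
#' @param by_namespace correct within namespaces separately (default TRUE).
#' @return data.frame `term_id`, `namespace`, `label`, `k`, `K`, `n`, `N`,
#'   `p_value`, `q_value`, `enriched`, sorted by p-value.
#' @export
enrich_terms <- function(deg_set, universe, annotation, q_max = 0.05,
                         by_namespace = TRUE) {
  deg_set <- unique(deg_set)
  universe <- unique(universe)
  if (!all(deg_set %in% universe)) {
    stopf("deg_set must be a subset of the universe")
  }
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  ann <- ann[!duplicated(ann[c("gene_id", "term_id")]), , drop = FALSE]
  if (length(deg_set) == 0L || nrow(ann) == 0L) {
    return(data.frame(term_id = character(0), namespace = character(0),
                      label = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      q_value = numeric(0), enriched = logical(0),
                      stringsAsFactors = FALSE))
  }
  N <- length(universe); n <- length(deg_set)
  terms <- unique(ann[c("term_id", "namespace", "label")])
  K <- as.integer(table(ann$term_id)[terms$term_id])
  in_deg <- ann$gene_id %in% deg_set
  ktab <- table(ann$term_id[in_deg])
  k <- as.integer(ifelse(terms$term_id %in% names(ktab),
                         ktab[terms$term_id], 0L))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = terms$term_id, namespace = terms$namespace,
                    label = terms$label, k = k, K = K, n = n, N = N,
                    p_value = p, stringsAsFactors = FALSE)
  out$q_value <- if (by_namespace) {
    stats::ave(out$p_value, out$namespace, FUN = bh_fdr)
  } else bh_fdr(out$p_value)
  out$enriched <- out$q_value <= q_max
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keyword filtering of annotated DEG lists
#'
#' Case-insensitive substring match of keywords against annotation term
#' labels (e.g. "methyltransferase", "methylase"), applied to the DEGs of
#' each comparison; also returns the genes matched in every comparison.
#'
#' @param deg_tables named list of `deg_table`s (from [call_degs()]).
#' @param annotation an `annotation_map`.
#' @param keywords non-empty character vector of keywords.
#' @return list with `per_comparison` (named list of gene-id vectors) and
#'   `intersection` (genes matched in all comparisons).
#' @export
keyword_filter <- function(deg_tables, annotation, keywords) {
  if (length(keywords) == 0L) stopf("keywords must be non-empty")
  pat <- paste(sapply(tolower(keywords),
                      function(k) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", k)),
               collapse = "|")
  hit_terms <- grepl(pat, tolower(annotation$label))
  matched_genes <- unique(annotation$gene_id[hit_terms])
  per <- lapply(deg_tables, function(d) {
    degs <- d$gene_id[d$call %in% c("up", "down")]
    sort(intersect(degs, matched_genes))
  })
  inter <- if (length(per)) Reduce(intersect, per) else character(0)
  list(per_comparison = per, intersection = sort(inter))
}

## ---- hierarchical clustering -------------------------------------------

# pairwise dissimilarity matrix on rows; constant rows under the Pearson
# metric have undefined correlations and are assigned distance 1 to
# everything (with a message)
row_dissimilarity <- function(mat, distance) {
  if (distance == "euclidean") {
    return(as.matrix(stats::dist(mat, method = "euclidean")))
  }
  sds <- apply(mat, 1L, stats::sd)
  const <- sds == 0
  dmat <- matrix(1, nrow(mat), nrow(mat),
                 dimnames = list(rownames(mat), rownames(mat)))
  ok <- which(!const)
  if (length(ok) >= 2L) {
    dmat[ok, ok] <- 1 - stats::cor(t(mat[ok, , drop = FALSE]))
  }
  if (any(const)) {
    message(sum(const), " constant row(s) under Pearson distance; ",
            "treated as distance 1 to all rows")
  }
  diag(dmat) <- 0
  dmat
}

#' Average-linkage hierarchical clustering of a DEG expression matrix
#'
#' Agglomerative (UPGMA) clustering of genes over libraries on the
#' `log2(TPM + 1)` transformed matrix, with the dissimilarity
#' `1 - Pearson correlation` (default) or Euclidean distance. Ties in the
#' minimum inter-cluster distance are broken deterministically by
#' lexicographic pair order (cluster creation order); leaves are ordered by
#' recursive subtree size (smaller first), then label. Average-linkage
#' merge heights are non-decreasing.
#'
#' @param mat numeric matrix, genes (rows) by libraries (columns) of TPM
#'   values; needs >= 2 rows and no missing values.
#' @param distance `"one_minus_pearson"` (default) or `"euclidean"`.
#' @param linkage only `"average"` is supported.
#' @param transform function applied to the matrix before clustering
#'   (default `log2(x + 1)`; use `identity` to cluster as-is).
#' @return a `dendrogram_result`: list with hclust-style `merge` and
#'   `height`, leaf `order`, `labels`, and the transformed `matrix`.
#'   Convert with [as.hclust()] for plotting or heatmaps.
#' @export
cluster_degs <- function(mat, distance = c("one_minus_pearson", "euclidean"),
                         linkage = "average", transform = function(x) log2(x + 1)) {
  distance <- match.arg(distance)
  if (!identical(linkage, "average")) stopf("only average linkage is supported")
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L) stopf("need at least 2 rows to cluster")
  if (anyNA(mat)) stopf("matrix contains missing values")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("row", seq_len(nrow(mat)))
  tmat <- transform(mat)
  dmat <- row_dissimilarity(tmat, distance)
  n <- nrow(tmat)
  labels <- rownames(tmat)

  # active clusters keyed by hclust convention: -i for singletons, +m for
  # the cluster created at merge m
  active_id <- as.integer(-seq_len(n))
  size <- rep(1L, n)
  members <- as.list(seq_len(n))
  d <- dmat
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  children <- vector("list", n - 1L)
  for (m in seq_len(n - 1L)) {
    na <- length(active_id)
    dm <- d
    dm[upper.tri(dm, diag = TRUE)] <- Inf
    best <- Inf; bi <- 0L; bj <- 0L
    for (j in seq_len(na - 1L)) {       # lexicographic (j, i) pair order,
      for (i in (j + 1L):na) {          # j before i in creation order
        if (dm[i, j] < best) { best <- dm[i, j]; bi <- i; bj <- j }
      }
    }
    merge[m, ] <- sort(c(active_id[bj], active_id[bi]))
    height[m] <- best
    children[[m]] <- c(active_id[bj], active_id[bi])
    # Lance-Williams average-linkage update against remaining clusters
    wi <- size[bi]; wj <- size[bj]
    newrow <- (wi * d[bi, ] + wj * d[bj, ]) / (wi + wj)
    keep <- setdiff(seq_len(na), c(bi, bj))
    d <- d[keep, keep, drop = FALSE]
    nr <- newrow[keep]
    d <- rbind(cbind(d, nr), c(nr, 0))
    active_id <- c(active_id[keep], m)
    size <- c(size[keep], wi + wj)
    members <- c(members[keep], list(c(members[[bi]], members[[bj]])))
  }
  order <- subtree_order(children, n, labels)
  structure(list(merge = merge, height = height, order = order,
                 labels = labels, matrix = tmat,
                 distance = distance, linkage = "average"),
            class = "dendrogram_result")
}

# leaf ordering: at every internal node visit the smaller subtree first;
# ties by the lexicographically smallest leaf label in the subtree
subtree_order <- function(children, n, labels) {
  leaf_set <- function(id) {
    if (id < 0L) return(-id)
    sort(c(leaf_set(children[[id]][1]), leaf_set(children[[id]][2])))
  }
  walk <- function(id) {
    if (id < 0L) return(-id)
    ch <- children[[id]]
    sz <- vapply(ch, function(c) length(leaf_set(c)), numeric(1))
    key <- vapply(ch, function(c) min(labels[leaf_set(c)]), character(1))
    ord <- order(sz, key)
    c(walk(ch[ord[1]]), walk(ch[ord[2]]))
  }
  walk(length(children))
}

#' @importFrom stats as.hclust
#' @export
as.hclust.dendrogram_result <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = x$order,
                 labels = x$labels, method = paste0("average/", x$distance),
                 call = match.call(), dist.method = x$distance),
            class = "hclust")
}
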
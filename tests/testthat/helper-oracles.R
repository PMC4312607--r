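# Independent oracles used across tests. Each deliberately takes a
# different computational route from the package implementation.

# Audic-Claverie p-value by direct recurrence summation (no log-space):
# P(0|x) = (1+r)^-(x+1), P(k|x) = P(k-1|x) * r (x+k) / (k (1+r)).
oracle_ac_pvalue <- function(x, y, N1, N2) {
  r <- N2 / N1
  kmax <- max(2000L, ceiling(r * (x + 1) + 50 * sqrt(r * (x + 1)) + y + 100))
  terms <- numeric(kmax + 1L)
  terms[1L] <- (1 + r)^-(x + 1)
  for (k in seq_len(kmax)) {
    terms[k + 1L] <- terms[k] * r * (x + k) / (k * (1 + r))
  }
  lo <- sum(terms[seq_len(y + 1L)])
  hi <- sum(terms[(y + 1L):(kmax + 1L)])
  min(1, 2 * min(lo, hi))
}

# Benjamini-Hochberg step-up by its definition: fdr_(i) is the minimum over
# j >= i of m * p_(j) / j, mapped back to input order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# exhaustive scan of the whole catalog at Hamming distance 0 then 1
# (mismatches over the whole 21 bp or only the 17 variable bases)
oracle_map_tag <- function(tag, catalog, fix_anchor = TRUE) {
  keys <- catalog$keys$tag
  dists <- vapply(keys, function(k) hamming(tag, k), numeric(1))
  if (fix_anchor) {
    anchor_ok <- vapply(keys, function(k) {
      substr(k, 1, 4) == substr(tag, 1, 4)
    }, logical(1))
  } else {
    anchor_ok <- rep(TRUE, length(keys))
  }
  hit0 <- which(dists == 0)
  hits <- if (length(hit0)) hit0 else which(dists == 1 & anchor_ok)
  genes <- unique(unlist(catalog$key_genes[hits], use.names = FALSE))
  list(
    category = if (length(genes) == 0) "unknown"
               else if (length(genes) == 1) "unambiguous_gene"
               else "ambiguous_gene",
    gene_id = if (length(genes) == 1) genes else NA_character_,
    mismatch_used = if (length(genes) == 0) NA_integer_
                    else if (length(hit0)) 0L else 1L
  )
}

# enumerate every CATG-anchored 21-mer on a sequence and its reverse
# complement by brute-force window scan
oracle_scan_tags <- function(seq) {
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  out <- list()
  for (strand in c("sense", "antisense")) {
    s <- if (strand == "sense") seq else rc
    if (nchar(s) >= 21) {
      for (p in 1:(nchar(s) - 20)) {
        w <- substr(s, p, p + 20)
        if (substr(w, 1, 4) == "CATG") {
          out[[length(out) + 1]] <- data.frame(tag = w, strand = strand,
                                               offset = p - 1L,
                                               stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(tag = character(0), strand = character(0), offset = integer(0))
}

# hypergeometric upper tail by explicit enumeration with choose()
oracle_hyper_upper <- function(k, K, n, N) {
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# average-linkage agglomeration recomputing every inter-cluster distance
# from the raw dissimilarity matrix at each step (no Lance-Williams update);
# same tie-break convention: first minimal pair in creation order.
oracle_average_linkage <- function(dmat) {
  n <- nrow(dmat)
  clusters <- lapply(seq_len(n), identity)
  ids <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (m in seq_len(n - 1L)) {
    best <- Inf; bi <- 0L; bj <- 0L
    for (j in seq_len(length(clusters) - 1L)) {
      for (i in (j + 1L):length(clusters)) {
        dd <- mean(dmat[clusters[[i]], clusters[[j]]])
        if (dd < best) { best <- dd; bi <- i; bj <- j }
      }
    }
    merge[m, ] <- sort(c(ids[bj], ids[bi]))
    height[m] <- best
    clusters <- c(clusters[-c(bi, bj)],
                  list(c(clusters[[bj]], clusters[[bi]])))
    ids <- c(ids[-c(bi, bj)], m)
  }
  list(merge = merge, height = height)
}
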
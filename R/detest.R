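## Audic-Claverie test for tag-count data.
##
## Given a gene observed x times among N1 tags in library 1, the probability
## of observing y tags among N2 tags in library 2 under equal underlying
## expression is
##   P(y|x) = (N2/N1)^y * (x+y)! / ( x! y! (1 + N2/N1)^(x+y+1) ),
## the posterior predictive of a Poisson rate under a flat prior. The
## two-sided p-value doubles the smaller tail and caps at 1.

ac_log_pmf <- function(k, x, r) {
  k * log(r) + lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) -
    (x + k + 1) * log1p(r)
}

#' Audic-Claverie tag-count probability mass
#'
#' `P(y | x)` for observing `y` tags in a library of `N2` given `x` tags in
#' a library of `N1`, under equal expression. Computed in log-space via
#' log-gamma. Vectorized over `y`.
#'
#' @param y,x non-negative tag counts.
#' @param N1,N2 library sizes (>= 1).
#' @return probability mass, same length as `y`.
#' @export
ac_pmf <- function(y, x, N1, N2) {
  if (any(c(x, y) < 0)) stopf("counts must be non-negative")
  if (N1 < 1 || N2 < 1) stopf("library sizes must be >= 1")
  exp(ac_log_pmf(y, x, N2 / N1))
}

# one tail of the AC distribution, summed outward from y in log space
# (log-sum-exp accumulation, so deep tails far below double range still
# sum correctly) with relative truncation 1e-16
ac_tail_sum <- function(x, y, r, upper, chunk = 512L) {
  acc_log <- -Inf
  k0 <- y
  repeat {
    ks <- if (upper) k0 + 0:(chunk - 1L) else k0 - 0:(chunk - 1L)
    ks <- ks[ks >= 0]
    if (length(ks) == 0L) break
    lt <- ac_log_pmf(ks, x, r)
    m <- max(acc_log, lt)
    acc_log <- m + log(sum(exp(lt - m)) + exp(acc_log - m))
    if (!upper && ks[length(ks)] == 0L) break
    if (lt[length(lt)] < acc_log + log(1e-16)) break
    k0 <- if (upper) ks[length(ks)] + 1L else ks[length(ks)] - 1L
  }
  exp(acc_log)
}

ac_pvalue_scalar <- function(x, y, N1, N2) {
  r <- N2 / N1
  mean_y <- r * (x + 1)  # expected y under equal expression
  if (y >= mean_y) {
    tail_hi <- ac_tail_sum(x, y, r, upper = TRUE)
    tail_lo <- 1 - tail_hi + exp(ac_log_pmf(y, x, r))
  } else {
    tail_lo <- ac_tail_sum(x, y, r, upper = FALSE)
    tail_hi <- 1 - tail_lo + exp(ac_log_pmf(y, x, r))
  }
  min(1, 2 * min(tail_lo, tail_hi))
}

#' Audic-Claverie two-sided p-value
#'
#' Two-sided significance of a difference in tag counts between two
#' libraries: `p = min(1, 2 * min(P(Y <= y | x), P(Y >= y | x)))`. Tail sums
#' are computed in log-space with relative truncation at 1e-16; the smaller
#' tail is always summed directly so no catastrophic cancellation occurs.
#' Vectorized over `x` and `y`.
#'
#' @param x,y tag counts in library 1 and 2 (non-negative).
#' @param N1,N2 library sizes (>= 1).
#' @return p-value(s) in \[0, 1\].
#' @export
ac_pvalue <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) stopf("counts must be non-negative")
  if (any(N1 < 1) || any(N2 < 1)) stopf("library sizes must be >= 1")
  n <- max(length(x), length(y), length(N1), length(N2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
  vapply(seq_len(n),
         function(i) ac_pvalue_scalar(x[i], y[i], N1[i], N2[i]),
         numeric(1))
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted p-values (`stats::p.adjust(method = "BH")` behind a
#' validating interface); output order matches input order.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return FDR (adjusted p) values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Call differentially expressed genes between two libraries
#'
#' Tests every gene of the union universe (zero-filled) that has a nonzero
#' count in at least one library. P-values come from [ac_pvalue()] on raw
#' counts and library sizes, FDR from [bh_fdr()] over all tested genes; the
#' log2 ratio is `log2(tpm2 / tpm1)` with zero TPMs floored at `tpm_floor`.
#' Orientation is "profile1 vs profile2" with profile1 the control: `up`
#' means higher in profile2. Boundary values are significant (FDR <=
#' `fdr_max` and |log2 ratio| >= `min_abs_log2`).
#'
#' @param profile1,profile2 `expression_profile`s (control, experimental).
#' @param fdr_max FDR threshold (default 0.001).
#' @param min_abs_log2 minimum |log2 TPM ratio| (default 1).
#' @param tpm_floor floor applied to TPM values in the fold change only;
#'   p-values always use the raw counts (default 0.001 TPM).
#' @return a `deg_table` data.frame (`gene_id`, `x`, `y`, `tpm1`, `tpm2`,
#'   `log2_ratio`, `p_value`, `fdr`, `call`) with attributes `n_up`,
#'   `n_down`, `N1`, `N2`.
#' @export
call_degs <- function(profile1, profile2, fdr_max = 0.001, min_abs_log2 = 1,
                      tpm_floor = 0.001) {
  stopifnot(inherits(profile1, "expression_profile"),
            inherits(profile2, "expression_profile"))
  N1 <- attr(profile1, "library_size")
  N2 <- attr(profile2, "library_size")
  genes <- union(profile1$gene_id, profile2$gene_id)
  if (length(genes) == 0L) stopf("empty gene universe")
  pick <- function(p, what) {
    v <- p[[what]][match(genes, p$gene_id)]
    ifelse(is.na(v), 0, v)
  }
  x <- pick(profile1, "count"); y <- pick(profile2, "count")
  tpm1 <- pick(profile1, "tpm"); tpm2 <- pick(profile2, "tpm")
  keep <- x > 0 | y > 0   # both-zero genes carry no information
  d <- data.frame(gene_id = genes[keep], x = x[keep], y = y[keep],
                  tpm1 = tpm1[keep], tpm2 = tpm2[keep],
                  stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stopf("no gene has a nonzero count in either library")
  d$log2_ratio <- log2(pmax(d$tpm2, tpm_floor) / pmax(d$tpm1, tpm_floor))
  d$p_value <- ac_pvalue(d$x, d$y, N1, N2)
  d$fdr <- bh_fdr(d$p_value)
  d$call <- "not_significant"
  d$call[d$fdr <= fdr_max & d$log2_ratio >= min_abs_log2] <- "up"
  d$call[d$fdr <= fdr_max & d$log2_ratio <= -min_abs_log2] <- "down"
  d <- d[order(d$gene_id), , drop = FALSE]
  rownames(d) <- NULL
  structure(d, n_up = sum(d$call == "up"), n_down = sum(d$call == "down"),
            N1 = N1, N2 = N2, fdr_method = "BH",
            class = c("deg_table", "data.frame"))
}
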
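#' Simulation configuration for synthetic DGE tag libraries
#'
#' Bundles every knob of the synthetic diploid/amphidiploid generator.
#' Defaults emulate a six-library NlaIII DGE experiment: three diploid
#' parents and the three pairwise amphidiploids, each sequenced to about six
#' million 21-bp CATG-anchored raw tags over a reference of tens of
#' thousands of genes, with a heavy-tailed (log-normal) abundance law so
#' that a small minority of genes carries most of the tags.
#'
#' @param n_genes number of reference genes.
#' @param length_range integer pair, min/max transcript length (min >= 25 so
#'   every gene can host a CATG site with 17 trailing bases).
#' @param abundance_sdlog sd of the log-normal relative-abundance law; larger
#'   values give a heavier tail.
#' @param depth raw tags sampled per library.
#' @param error_rate per-base miscall probability; 90% of miscalls substitute
#'   one of the other three bases, 10% emit an ambiguous "N".
#' @param junk_frac fraction of raw tags drawn from a persistent pool of
#'   random unmappable tag sequences (emulating tags from transcripts absent
#'   from the reference); pool tags recur, so they survive the copy-number
#'   filter and end up in the "unknown" mapping class.
#' @param frac_nonadditive probability that an expressed amphidiploid gene
#'   deviates from the mid-parent value.
#' @param frac_silent probability that a gene is silent in a given diploid.
#' @param primary_site_prob probability that a tag comes from the 3'-most
#'   CATG site of its transcript (the canonical NlaIII/MmeI tag); otherwise a
#'   uniformly chosen internal CATG site is used (partial digestion).
#' @param nonadditive_fold_range fold-deviation range from the mid-parent
#'   value for non-additive genes; the multiplier is log-uniform on this
#'   interval, applied upward or downward with equal probability.
#' @param seed master integer seed; all draws in all generator operations
#'   are derived from it, no global RNG state is consumed.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 20000L,
                       length_range = c(300L, 3000L),
                       abundance_sdlog = 2.2,
                       depth = 6e6,
                       error_rate = 0.005,
                       junk_frac = 0.25,
                       frac_nonadditive = 0.5,
                       frac_silent = 0.1,
                       primary_site_prob = 0.9,
                       nonadditive_fold_range = c(2, 5),
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes), length_range = as.integer(length_range),
    abundance_sdlog = abundance_sdlog, depth = as.numeric(depth),
    error_rate = error_rate, junk_frac = junk_frac,
    frac_nonadditive = frac_nonadditive, frac_silent = frac_silent,
    primary_site_prob = primary_site_prob,
    nonadditive_fold_range = as.numeric(nonadditive_fold_range),
    seed = as.integer(seed)
  )
  if (cfg$n_genes < 0L) stopf("n_genes must be >= 0")
  if (length(cfg$length_range) != 2L || any(is.na(cfg$length_range)) ||
      cfg$length_range[1] > cfg$length_range[2]) {
    stopf("length_range must be an ordered integer pair")
  }
  if (cfg$length_range[1] < 25L) {
    stopf("length_range minimum must be >= 25 (room for CATG + 17 bases)")
  }
  for (p in c("error_rate", "junk_frac", "frac_nonadditive", "frac_silent",
              "primary_site_prob")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stopf("%s must be in [0,1]", p)
  }
  if (cfg$depth < 0) stopf("depth must be >= 0")
  if (cfg$abundance_sdlog <= 0) stopf("abundance_sdlog must be positive")
  if (any(cfg$nonadditive_fold_range < 1) ||
      cfg$nonadditive_fold_range[1] > cfg$nonadditive_fold_range[2]) {
    stopf("nonadditive_fold_range must be an ordered pair of folds >= 1")
  }
  structure(cfg, class = "sim_config")
}

#' Species layout of the simulated cross
#'
#' Three diploid parents (`P1`, `P2`, `P3`) and the three pairwise
#' amphidiploids (`P1xP2`, `P1xP3`, `P2xP3`), mirroring a three-diploid /
#' three-allopolyploid Brassica-style design.
#'
#' @return named list mapping each amphidiploid to its two parents.
#' @export
amphidiploid_parents <- function() {
  list("P1xP2" = c("P1", "P2"), "P1xP3" = c("P1", "P3"),
       "P2xP3" = c("P2", "P3"))
}

sim_species <- function() c("P1", "P2", "P3", names(amphidiploid_parents()))

#' Generate a synthetic reference transcriptome
#'
#' Random transcript sequences; any gene that does not already contain a
#' CATG with at least 17 following bases gets one injected at a random
#' eligible position, so every gene can yield a 21-bp tag.
#'
#' @param config a [sim_config()].
#' @return a `reference_set`: data.frame with columns `gene_id`, `sequence`.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  if (n == 0L) {
    return(structure(data.frame(gene_id = character(0),
                                sequence = character(0),
                                stringsAsFactors = FALSE),
                     class = c("reference_set", "data.frame")))
  }
  with_seed(derive_seed(config$seed, 1L), {
    lens <- sample(config$length_range[1]:config$length_range[2], n,
                   replace = TRUE)
    seqs <- random_dna(n, lens)
    # ensure a taggable CATG site (CATG + >= 17 trailing bases)
    for (i in seq_len(n)) {
      if (!has_taggable_site(seqs[i])) {
        pos <- sample.int(lens[i] - 20L, 1L)
        substr(seqs[i], pos, pos + 3L) <- "CATG"
      }
    }
    structure(data.frame(
      gene_id = sprintf("G%05d", seq_len(n)),
      sequence = seqs, stringsAsFactors = FALSE
    ), class = c("reference_set", "data.frame"))
  })
}

# positions of CATG occurrences with >= 17 bases following, on the given string
taggable_sites <- function(seq) {
  m <- gregexpr("CATG", seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  m <- as.integer(m)
  m[m + 20L <= nchar(seq)]
}

has_taggable_site <- function(seq) length(taggable_sites(seq)) > 0L

#' Simulate ground-truth abundances and non-additivity labels
#'
#' Diploid relative abundances are log-normal (heavy-tailed), with a
#' configurable fraction of silent genes per species, normalized to sum to 1.
#' Each amphidiploid gene is additive (abundance exactly the mean of its two
#' parents) or non-additive (above/below the mid-parent value by a
#' log-uniform fold), with the configured frequency. Stored amphidiploid
#' abundances keep the exact additive-mean relation; sampling renormalizes
#' internally.
#'
#' @param reference a `reference_set` (non-empty).
#' @param config a [sim_config()].
#' @return `simulation_truth`: list with `abundance` (genes x 6 species
#'   matrix), `classes` (per amphidiploid gene: additivity class, dominance
#'   parent, fold), and `gene_id`.
#' @export
simulate_truth <- function(reference, config) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(reference)
  if (n == 0L) stopf("reference must be non-empty")
  with_seed(derive_seed(config$seed, 2L), {
    species <- sim_species()
    ab <- matrix(0, nrow = n, ncol = length(species),
                 dimnames = list(reference$gene_id, species))
    for (d in c("P1", "P2", "P3")) {
      x <- stats::rlnorm(n, meanlog = 0, sdlog = config$abundance_sdlog)
      silent <- stats::runif(n) < config$frac_silent
      x[silent] <- 0
      if (sum(x) > 0) x <- x / sum(x)
      ab[, d] <- x
    }
    classes <- list()
    for (am in names(amphidiploid_parents())) {
      par <- amphidiploid_parents()[[am]]
      mpv <- (ab[, par[1]] + ab[, par[2]]) / 2
      cls <- rep("additive", n)
      fold <- rep(1, n)
      nonadd <- stats::runif(n) < config$frac_nonadditive & mpv > 0
      dir_up <- stats::runif(n) < 0.5
      fr <- config$nonadditive_fold_range
      m <- exp(stats::runif(n, log(fr[1]), log(fr[2])))
      cls[nonadd & dir_up] <- "above_mpv"
      cls[nonadd & !dir_up] <- "below_mpv"
      fold[nonadd] <- ifelse(dir_up[nonadd], m[nonadd], 1 / m[nonadd])
      ab[, am] <- mpv * fold
      dom <- rep(NA_character_, n)
      dom[nonadd & ab[, par[1]] > ab[, par[2]]] <- par[1]
      dom[nonadd & ab[, par[1]] < ab[, par[2]]] <- par[2]
      classes[[am]] <- data.frame(
        gene_id = reference$gene_id, amphidiploid = am,
        additivity_class = cls, dominance_parent = dom,
        fold = fold, stringsAsFactors = FALSE
      )
    }
    structure(list(
      gene_id = reference$gene_id,
      abundance = ab,
      classes = do.call(rbind, classes)
    ), class = "simulation_truth")
  })
}

# sense-strand tag site table for sampling: per gene, primary (3'-most) tag
# and any alternative internal-site tags
gene_tag_table <- function(reference) {
  sites <- lapply(reference$sequence, taggable_sites)
  tags <- mapply(function(seq, pos) substring(seq, pos, pos + 20L),
                 reference$sequence, sites, SIMPLIFY = FALSE)
  primary <- vapply(tags, function(t) if (length(t)) t[length(t)] else NA_character_,
                    character(1))
  alts <- lapply(tags, function(t) if (length(t) > 1L) t[-length(t)] else character(0))
  list(primary = primary, alts = alts, n_alt = lengths(alts))
}

# persistent junk-tag pool shared by all libraries of one configuration
junk_pool <- function(config) {
  n_pool <- max(1L, as.integer(round(config$n_genes * 0.5)))
  with_seed(derive_seed(config$seed, 104729L), {
    list(tags = paste0("CATG", random_dna(n_pool, rep(17L, n_pool))),
         prob = {
           w <- stats::rlnorm(n_pool, 0, config$abundance_sdlog)
           w / sum(w)
         })
  })
}

#' Sample a raw tag library for one species
#'
#' Draws `depth` raw 21-bp tags gene-proportionally to the species' true
#' abundance. Each tag is the CATG-anchored 21-mer of the sampled gene
#' (3'-most site with probability `primary_site_prob`, otherwise a random
#' internal site), then each base is miscalled independently at
#' `error_rate`; a `junk_frac` fraction of draws is replaced by tags from a
#' random unmappable pool. Deterministic given the configuration seed.
#'
#' @param reference a `reference_set`.
#' @param truth a `simulation_truth` for the same reference.
#' @param species one of `P1`,`P2`,`P3`,`P1xP2`,`P1xP3`,`P2xP3`.
#' @param config a [sim_config()].
#' @param tag_table optional precomputed per-gene tag-site table to reuse
#'   across libraries (speed-up when sampling many species).
#' @return a raw `tag_library`.
#' @export
sample_tags <- function(reference, truth, species, config, tag_table = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "simulation_truth"))
  if (!species %in% colnames(truth$abundance)) {
    stopf("unknown species '%s'", species)
  }
  depth <- as.integer(config$depth)
  if (depth == 0L) {
    return(tag_library(structure(integer(0), names = character(0)),
                       species = species, raw_total = 0L))
  }
  ab <- truth$abundance[, species]
  if (sum(ab) == 0 && config$junk_frac < 1) {
    stopf("species '%s' has zero total abundance; nothing to sample", species)
  }
  if (is.null(tag_table)) tag_table <- gene_tag_table(reference)
  pool <- if (config$junk_frac > 0) junk_pool(config) else NULL
  sidx <- match(species, colnames(truth$abundance))
  with_seed(derive_seed(config$seed, 100L + sidx), {
    is_junk <- stats::runif(depth) < config$junk_frac
    n_gene_draws <- sum(!is_junk)
    tags <- character(depth)
    if (n_gene_draws > 0L) {
      g <- sample.int(nrow(reference), n_gene_draws, replace = TRUE,
                      prob = ab / sum(ab))
      t_out <- tag_table$primary[g]
      use_alt <- stats::runif(n_gene_draws) > config$primary_site_prob &
        tag_table$n_alt[g] > 0L
      if (any(use_alt)) {
        t_out[use_alt] <- vapply(g[use_alt], function(gi) {
          a <- tag_table$alts[[gi]]
          a[sample.int(length(a), 1L)]
        }, character(1))
      }
      if (config$error_rate > 0) t_out <- miscall_bases(t_out, config$error_rate)
      tags[!is_junk] <- t_out
    }
    if (any(is_junk)) {
      tags[is_junk] <- pool$tags[sample.int(length(pool$tags), sum(is_junk),
                                            replace = TRUE, prob = pool$prob)]
    }
    tag_library(count_sequences(tags), species = species, raw_total = depth)
  })
}

# apply the sequencing error model to a vector of 21-bp tags:
# k ~ Binomial(21, rate) miscalls per tag, positions with replacement,
# miscall = one of the other three bases (90%) or "N" (10%)
miscall_bases <- function(tags, rate) {
  k <- stats::rbinom(length(tags), 21L, rate)
  hit <- which(k > 0L)
  if (length(hit) == 0L) return(tags)
  mat <- matrix(unlist(strsplit(tags[hit], "", fixed = TRUE), use.names = FALSE),
                ncol = 21L, byrow = TRUE)
  rows <- rep.int(seq_along(hit), k[hit])
  pos <- sample.int(21L, length(rows), replace = TRUE)
  idx <- cbind(rows, pos)
  cur <- mat[idx]
  bases <- c("A", "C", "G", "T")
  to_n <- stats::runif(length(rows)) < 0.1
  shift <- sample.int(3L, length(rows), replace = TRUE)
  curi <- match(cur, bases)
  newb <- bases[((ifelse(is.na(curi), 0L, curi) - 1L + shift) %% 4L) + 1L]
  newb[to_n] <- "N"
  mat[idx] <- newb
  tags[hit] <- do.call(paste0, asplit(mat, 2L))
  tags
}
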
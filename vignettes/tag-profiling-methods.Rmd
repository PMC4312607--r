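---
title: "Digital gene expression tag profiling: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital gene expression tag profiling: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polytag)
```

## The measurement model

NlaIII/MmeI digital gene expression (DGE) profiling counts transcripts by
sequencing one short tag per cDNA molecule: NlaIII cuts at its CATG
recognition site, MmeI releases a 21-bp fragment — the CATG anchor plus 17
transcript-derived bases — and the tag count of a gene is a direct digital
readout of its mRNA abundance. `polytag` implements the complete analysis
chain for such libraries:

1. **Clean-tag filtering** (`filter_raw_tags`): after aggregating identical
   sequences, tags that are empty, contain a base outside A/C/G/T, are not
   exactly 21 bp, lack the CATG prefix, match a supplied adaptor, or occur
   exactly once in the library are discarded. Copy number is only defined
   after aggregation, so aggregation precedes the singleton filter; the
   anchor/length filters are applied before singleton removal (the order is
   a configuration of the implementation, not observable in the totals).
2. **Tag-to-gene mapping** (`build_catalog`, `map_tags`): every CATG
   occurrence with 17 following bases, on the sense strand and on the
   reverse complement of each transcript, enters a catalog. A clean tag is
   looked up exactly first; only if that fails are all Hamming-distance-1
   neighbours consulted. The union of genes over the hits decides the
   category: one gene = unambiguous (several sites within one gene still
   count as one locus, because all downstream counting is per gene), two or
   more = ambiguous, none = unknown.
3. **Quantification** (`quantify`): per-gene counts are sums of unambiguous
   tag copy numbers, normalized to tags per million (TPM) with the
   clean-tag total as the denominator.
4. **Differential expression** (`ac_pvalue`, `call_degs`): the
   Audic–Claverie test for a pair of single (unreplicated) libraries, with
   Benjamini–Hochberg FDR across the tested genes and the thresholds
   FDR ≤ 0.001 and |log2 TPM ratio| ≥ 1 (both boundaries inclusive).
5. **Non-additivity** (`compute_mpv`, `classify_nonadditive`): an
   amphidiploid gene is compared with the mid-parent value (MPV), the
   arithmetic mean of the two parental TPMs; direction (above/below) and a
   parental-dominance breakdown are tabulated.
6. **Enrichment and structure** (`enrich_terms`, `keyword_filter`,
   `cluster_degs`): hypergeometric term enrichment with BH q-values,
   keyword filtering of annotated DEG lists, and average-linkage
   hierarchical clustering of DEG expression matrices.

## The Audic–Claverie statistic

For a gene with `x` tags among `N1` clean tags in library 1, the
probability of `y` tags among `N2` in library 2 under equal expression is

$$P(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!\,(1 + N_2/N_1)^{x+y+1}},$$

the posterior predictive of a Poisson rate under a flat prior — equivalently
a negative binomial with size $x+1$ and success probability
$N_1/(N_1+N_2)$ (the package uses this identity as an independent
cross-check in its tests, never as the implementation). The two-sided
p-value doubles the smaller of the two tails and caps at 1.

Numerics: every term is evaluated in log space via `lgamma`; tails are
summed outward from `y` with log-sum-exp accumulation and relative
truncation at $10^{-16}$, and the smaller tail is always summed directly
(the larger one is obtained by complement), so there is neither
catastrophic cancellation nor underflow — p-values remain exact down to the
bottom of the double range.

One property worth stating explicitly: the law conditions on the count in
the *first* library, so swapping the roles of the two libraries does not
leave the p-value exactly invariant. At `x = 0, y = 10` and equal sizes the
two orientations differ by exactly a factor 2 deep in the tail; across
random count pairs they agree within an order of magnitude, and at the
calling thresholds the orientation never changes which genes are
significant in practice. The package follows the published convention "A
vs. B" with A the control: `call_degs(profileA, profileB)` reports `up` for
genes higher in B.

`bh_fdr` is a validating wrapper around `stats::p.adjust(method = "BH")`;
its step-up behaviour is verified against a from-scratch implementation of
the definition in the tests.

## The synthetic study generator

`sim_config()` defines the generator defaults as a six-library experiment —
three diploid parents `P1`–`P3` and the three pairwise amphidiploids — with:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 20000 | reference transcript count |
| `length_range` | 300–3000 bp | transcript lengths (uniform) |
| `abundance_sdlog` | 2.2 | sd(log) of the log-normal abundance law |
| `depth` | 6e6 | raw tags per library |
| `error_rate` | 0.005 | per-base miscall probability |
| `junk_frac` | 0.25 | tags drawn from an unmappable pool |
| `frac_nonadditive` | 0.5 | amphidiploid genes off the MPV |
| `frac_silent` | 0.1 | silent genes per diploid |
| `primary_site_prob` | 0.9 | draws from the 3'-most CATG site |
| `nonadditive_fold_range` | 2–5 | fold deviation from the MPV |

Rationale for the key choices:

* **Abundance law.** Real CATG tag libraries are extremely heavy-tailed:
  tags with more than 100 copies are under 8% of distinct tags but over
  two thirds of the total tag mass, and over 43% of distinct tags have only
  2–5 copies. A log-normal with `sdlog = 2.2` reproduces all three
  statistics at the default scale (measured at 20000 genes and 6e6 tags:
  6.7% of distinct and 86% of total above 100 copies, 59% of distinct at
  2–5 copies). This is a deliberately tuned emulation target, not an
  invariant; the tests assert only the qualitative signature.
* **Tag model.** A transcript's canonical tag is its 3'-most CATG + 17
  bases (the fragment the enzymes release); with probability 0.1 a draw
  uses a random internal CATG site instead, emulating partial digestion and
  creating multi-site genes. Raw 21-bp tags are emitted directly — the
  upstream base-calling and adaptor trimming of a real run are outside the
  generator's scope.
* **Errors.** Each base is miscalled independently; 90% of miscalls
  substitute one of the other three bases (producing the 1-mismatch class
  the mapper must resolve), 10% emit an `N` (removed by the clean filter).
  Error positions within a tag are drawn with replacement — collisions are
  negligible at 21 positions.
* **Unknown tags.** Real libraries contain 25–45% of clean tags that map
  nowhere. Singleton random sequences would be removed by the copy-number
  filter, so the generator draws junk tags from a persistent pool (half the
  gene count, with its own heavy-tailed weights) shared by all libraries of
  a configuration; pool tags recur and survive filtering, landing in the
  `unknown` mapping class at a rate set by `junk_frac = 0.25`.
* **Non-additivity.** Amphidiploid truth starts from the exact parental
  mean; a `frac_nonadditive` subset is multiplied (or divided) by a
  log-uniform fold in 2–5×, matching the fold range at which the pipeline
  calls differential expression. The two stored invariants — additive genes
  exactly at the parental mean, per-species abundances summing to 1 —
  cannot both hold once non-additive genes shift the amphidiploid total, so
  the stored truth keeps the exact mean relation and `sample_tags`
  renormalizes internally. Consequence: with many non-additive genes the
  *relative* abundance of an additive gene is slightly below its relative
  MPV; this mirrors the real transcriptome-size bias of unreplicated DGE
  designs and is one reason the directional-recovery checks score only the
  truly non-additive genes.
* **Determinism.** A single integer seed drives everything; per-species and
  per-task streams are derived from it arithmetically (all below $2^{31}$),
  and every stochastic operation restores the caller's RNG state.

What the generator does *not* emulate: homeologous sequence similarity
between parental genomes (reference transcripts are independent random
sequences, so cross-gene tag collisions are much rarer than between real
Brassica A/B/C homeologs), intergenic transcription, positional biases, and
base-quality structure. Passing recovery tests therefore demonstrate the
correctness of the statistics and bookkeeping, not the hardness of mapping
in a triplicated genome.

## Parameters of the analysis stages

* `map_tags(fix_anchor = TRUE)`: mismatches are restricted to the 17
  variable bases by default, because a miscalled base inside the CATG
  anchor would have prevented the enzyme from cutting — such a tag is more
  plausibly junk than a real tag with a damaged anchor. `fix_anchor =
  FALSE` restores the full 21-position neighbourhood.
* `quantify(library_size = clean_total)`: the TPM denominator is the
  clean-tag total (the tag-profiling convention); pass the gene-mapped
  total instead to normalize per mapped tag.
* `call_degs(fdr_max = 0.001, min_abs_log2 = 1, tpm_floor = 0.001)`:
  p-values always use raw counts (which handle zeros natively); the floor
  applies only to the fold change of zero-count genes. Genes with zero
  counts in both libraries are excluded before testing so they do not
  inflate the FDR correction. FDR is per comparison, not joint across
  comparisons.
* `classify_nonadditive(tolerance = 0, min_detect = 1)`: with tolerance 0
  any inequality counts as non-additive, which reproduces the
  near-universal non-additivity of published MPV tables (they apply no
  significance filter); sampling noise alone pushes nearly every expressed
  gene off the exact MPV. The optional `test = TRUE` tier runs the AC test
  against a pseudo-mid-parent library (counts = half-up-rounded mean of the
  parents, size = mean of the parental sizes) — an approximation, flagged
  as such, for users who want a significance-filtered table.
* `enrich_terms(q_max = 0.05, by_namespace = TRUE)`: the universe should be
  the tag-mapped genes of the comparison; q-values are BH within each
  namespace, mirroring separate GO and pathway analyses. Terms are flat
  sets: no ontology propagation.
* `cluster_degs(distance = "one_minus_pearson")`: clustering operates on
  `log2(TPM + 1)`. Ties in the minimal inter-cluster distance are broken by
  the first pair in cluster-creation order; leaves are ordered by subtree
  size then lexicographically smallest label, so results are bit-for-bit
  reproducible. Constant rows (undefined Pearson correlation) are set to
  distance 1 from everything, with a message. Average linkage guarantees
  non-decreasing merge heights.

## Degenerate inputs and numerical edges

Empty libraries filter to empty libraries (never an error); an empty tag
stream yields the saturation curve `[(0, 0)]`; a library whose clean total
is zero cannot be quantified (error); `ratio_distribution` puts items seen
in only one library in a dedicated "infinite" class rather than dividing by
zero; percentages of an empty denominator are reported as 0. Percentage
rounding is half-up (as summary tables are printed), not banker's rounding.

## Problem sizes used by the tests and the acceptance script

Unit and property tests run on 150–2000-gene references with 3e4–4e5-tag
libraries; the acceptance-grade checks use 5000 genes and 1e6-tag
libraries, the scale at which per-gene counts (median of a few tens)
reproduce the statistical regime of the published six-million-tag libraries
at desk-top cost. The additive-recovery check uses a flat abundance law
(`abundance_sdlog = 0.5`, 200 genes at 2e6 tags) because a 5% additivity
band is only meaningful when every gene's sampling noise is well inside it.

## Known limitations

* Single-library designs have no dispersion estimate; the AC test captures
  sampling noise only, so biological variability inflates its significance,
  which is why the published thresholds are as strict as FDR ≤ 0.001.
* With a transcript-only reference there is no intergenic ("genome only")
  mapping class; those tags fall into `unknown`. The summary operation
  accepts externally supplied genome-mapping counts when reproducing
  published tables.
* MPV classification at tolerance 0 is deliberately noise-dominated (see
  above); interpret the direction tabulation, not its raw size, unless the
  significance tier is enabled.
* The clustering implementation is quadratic-to-cubic in the number of
  rows; it is meant for DEG-sized matrices (up to a few thousand rows), not
  whole-transcriptome matrices.
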
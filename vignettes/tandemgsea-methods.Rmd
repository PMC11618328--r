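---
title: "Statistics behind tandemgsea: pairwise enrichment, single-sample scores, and the dual assessment"
author: "tandemgsea authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistics behind tandemgsea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A pairwise gene-set enrichment analysis (GSEA) answers an *average* question:
does the expression of a gene set differ, on aggregate, between two groups of
samples? With enough samples, small average shifts become arbitrarily
significant, yet the per-sample score distributions of the two groups can
still lie almost entirely on top of each other. A gene set in that situation
is a sound statistical finding and a useless biomarker: no individual sample
can be classified by it. `tandemgsea` runs the pairwise analysis and a
single-sample analysis on the same contrast and collection, then grades each
gene set on both axes.

The package works on a log-scale expression matrix (genes x samples), a
sample-to-group phenotype table, and a GMT gene-set collection. Two groups
are contrasted at a time; the first label (`a`) is the reference direction
for every signed statistic.

# Ranking and the pairwise stage

Genes are ranked by one of three per-gene metrics between groups `a` and `b`:

* `tstat` (default): two-sample t, pooled variance ("Student") by default,
  Welch behind a flag. The plain two-sample t is used rather than a
  moderated variant: downstream set-level conclusions are driven by the rank
  order, which is stable across these choices, and the package avoids
  importing an empirical-Bayes machinery whose internals it does not need.
* `logfc`: difference of group means (the input is log2 scale, so this is
  the log fold change).
* `combined`: `logfc * -log10(p)`, fold change weighted by significance.
  P-values are floored at 1e-300 before the logarithm so the metric stays
  finite; a p of exactly 1 gives 0 regardless of fold change.

Ties in the ranking metric are broken by gene identifier (radix order, so
the result is locale-independent); the ranked list is a reproducible total
order, which matters because the enrichment walk below depends on position.

The enrichment score (ES) of a set is the classic weighted
Kolmogorov–Smirnov running sum: walking down the ranked list, set members
add `|metric|^p / sum(|metric|^p over members)` and non-members subtract
`1/(N - N_hit)`; the ES is the extremum of maximal absolute deviation
(positive wins exact ties). The weight exponent defaults to p = 1. If every
member's metric is exactly zero the hit weights fall back to equal, rather
than dividing by zero. The leading edge is the members at or before the
extremum (at or after, for negative ES).

The null distribution is built by gene-tag permutation: random same-size
subsets of the ranked universe, 1000 draws by default, seeded (default 127)
and shared across sets of equal size since the null depends only on size
given the ranking. Phenotype permutation is deliberately not offered: in a
preranked workflow the labels are already consumed by the ranking step.
The normalized enrichment score divides the ES by the mean magnitude of
same-sign null scores, and the p-value is the +1-corrected one-sided tail
among same-sign nulls, so p is never exactly zero. Benjamini–Hochberg is
applied across all scored sets; `padj < 0.05` is the default significance
rule.

**A granularity consequence worth knowing.** With 1000 permutations, about
half the null draws share the observed sign, so the smallest achievable
p-value is roughly 1/500. After BH over `m` sets, the smallest achievable
adjusted p is about `m/500`: when only one set in a 50-set collection truly
shifts, it cannot reach `padj < 0.05` no matter how strong the shift.
Real cohorts rarely hit this wall because many sets shift together (each
small p lowers the BH bar for the others), but single-planted synthetic
collections do — which is why the shipped presets carry 20 sets, and why
users scoring large collections with a single expected signal should raise
`n_perm`.

# Single-sample stage

`ssgsea_score()` implements the rank-weighted single-sample statistic: per
sample, genes are ranked by expression (descending, average ranks on ties)
and given weights N..1 from the top raised to `alpha` (default 0.25); the
score is the *sum* over positions of the normalized cumulative weighted hit
ECDF minus the cumulative miss ECDF — an integral, not an extremum, which
makes it smooth in the effect size. Because it sees only within-sample
ranks, the score is invariant under any strictly increasing transform of a
sample's expression vector (a property the test suite checks with random
transforms). A fully constant sample carries no rank information and is
scored 0 with a warning. Scores for a collection are range-normalized by
default (divided by the global max minus min), matching the customary
convention; this rescaling changes t-statistic magnitudes but not overlap,
AUC, or any rank-based quantity, and can be disabled.

`gsva_score()` is a simplified faithful variant of the gene-set variation
statistic: per gene, each sample's level is converted to a cumulative
density across samples (gaussian kernel, bandwidth sd/4; an empirical-CDF
kernel is available), per sample the genes are ordered by that density with
symmetric rank weights `|N/2 - position|^tau` (tau = 1), and the score is
the maximum positive plus the minimum negative deviation of the walk. It is
documented as "gsva-style": distributionally faithful, not a bit-compatible
port of any package. It needs at least 3 samples (the density is estimated
across samples); samples with no between-sample variation score 0. On
planted fixtures the two scorers correlate above 0.99, so either can back
the assessment; ssGSEA is the default because it is per-sample independent.

`zscore_by_set()` standardizes each set's score row to mean 0, sd 1 (n-1
denominator) for heatmap display; constant rows are an error rather than a
silent NaN.

# The dual assessment

For every scored set (or only the pairwise-significant ones, on request):

* Student's t (or Welch) on the per-sample scores between the groups, BH
  corrected across the assessed sets.
* **Overlap percentage**: the two groups' score ranges are intersected
  (closed interval) and the statistic is the percentage of all samples,
  both groups pooled, whose score falls inside that intersection. 0 for
  disjoint ranges, 100 for identical ones. This definition is the
  package's own: it is assumption-free, reproduces the qualitative
  extremes, and uses only order statistics. Being range-based it is
  sensitive to single extreme samples; it is a descriptive companion to
  the AUC, not a test.
* **ROC/AUC** with the tie-corrected Mann–Whitney formulation. The
  positive class is the group the set's NES favours (the group with the
  higher scores), so a discriminating set always has AUC near 1 rather
  than near 0, and AUC values are comparable across sets.
* **Optimal cutpoint**: among observed score values, the one maximizing
  sensitivity + specificity, classifying positive at `score >= c`
  (direction auto-flips if the AUC of that rule would be below 0.5); ties
  break toward the smallest cutpoint. All-equal scores return a flagged
  degenerate cutpoint. Scores are then centred on the cutpoint; `high` is
  `centred >= 0` (the boundary sample is high), and the descending centred
  scores form the waterfall ordering, summarized as a 2x2
  stratum-by-group table with row percentages.
* **Verdict**: `distinct` if pairwise `padj < 0.05` *and* AUC at or above
  `auc_threshold`; `significant_but_overlapping` if significant but below
  it; otherwise `not_significant`. The default `auc_threshold = 0.8` is a
  deliberate, configurable midpoint between the AUC ~0.6 regime (clearly a
  poor classifier) and the AUC ~0.99 regime (clearly a discriminating
  one); it is a package default, not an empirical estimate.

# Synthetic cohorts and what they do (and do not) show

`generate_cohort()` draws a per-gene baseline from
`Normal(baseline_mean, baseline_sd)` (defaults 7 and 1.5, typical of log2
microarray intensity), adds i.i.d. `Normal(0, noise_sd)` per cell (default
1), and shifts a `planted_fraction` (default 0.7, so the leading edge is a
proper subset of the set) of one planted set's genes by `effect_delta` in
group `a`. The other sets are uniform draws and carry no signal. Everything
is a pure function of the spec, including its seed.

Two pinned presets reproduce the workflow's two regimes:

* `overlapping_regime`: 200 + 200 samples, `effect_delta = 0.25` (a quarter
  of the per-cell noise), 20 sets of 8–17 genes. The per-gene effect is
  individually negligible but the cohort is large, so the planted set is
  pairwise significant while its score distributions overlap almost
  completely (AUC ~0.6, overlap >90%). The small set size is deliberate:
  the group separation of a set-level score grows roughly with the square
  root of the set size at fixed per-gene effect, so compact sets keep the
  AUC low, while the per-gene t statistic grows with the square root of
  the cohort size, which restores pairwise detectability independently.
* `distinct_regime`: 56 + 63 samples (arm sizes typical of
  transcriptional-subtype comparisons), `effect_delta = 2` on every
  planted gene. Significant, AUC ~1, overlap ~0.

The Gaussian location-shift model is the minimal structure the downstream
statistics consume (ranks and means). It does not emulate probe-level
noise, batch effects, heavy tails, or gene–gene correlation; in real data,
correlated sets inflate the permutation-null tails and overlap estimates
are noisier. Passing the regime tests therefore demonstrates that the
machinery separates the two regimes when they are truly present — not that
any particular real cohort will land in either.

`null_pvalue_study()` is the calibration harness: replicate null cohorts
(`effect_delta = 0`), aggregating raw pairwise and score-test p-values; on
the shipped settings both families keep their nominal 5% level inside the
99% binomial envelope.

# Numerical and degenerate-input choices

* Missing or non-finite expression values are rejected at load; no
  imputation exists, because silent imputation corrupts rank statistics.
* Duplicate gene rows are collapsed (opt-in) by highest mean across all
  samples, label-agnostically, ties to first occurrence.
* Zero within-group variance with equal means gives t = 0, p = 1;
  with different means it is an error naming the genes (a noise-free
  fixture, not a real cohort).
* Empirical p-values carry the +1 correction; BH caps at 1; p-value
  validation rejects values outside (0, 1].
* All tie-breaks (ranking, cutpoint, waterfall order) resolve to a
  documented deterministic choice, so equal configurations give
  byte-identical output files.
* Problem sizes in the shipped tests (2000-gene cohorts, 1000
  permutations, 50-replicate null studies) were chosen so the full suite
  exercises every statistic at realistic scale while remaining quick on a
  laptop.

# Known limitations

* The permutation p-value is the simple empirical tail; no adaptive
  refinement, so resolution is bounded by `n_perm` (see the granularity
  note above).
* The gsva-style scorer is distribution-faithful, not package-exact.
* Only two-group contrasts; no paired designs, covariates, or
  count-model differential expression.
* The overlap percentage is range-based and so driven by extremes; read
  it alongside the AUC and the density plots.
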
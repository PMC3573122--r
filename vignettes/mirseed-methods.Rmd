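---
title: "Methods: seed-match miRNA target discovery with mirseed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-match miRNA target discovery with mirseed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirseed)
```

## The problem

When a microRNA is over-expressed in a cell population, its direct targets
are repressed through sites in their 3'UTRs, most of which pair by perfect
Watson-Crick complementarity with the miRNA *seed* — nucleotides 2–7 (a
6mer) or 1–8 (an 8mer) at the 5' end of the mature sequence. A
transcriptome profile of miRNA-transfected versus control cells therefore
carries a recoverable footprint: predicted targets should be
over-represented among the down-regulated transcripts. `mirseed`
implements that discovery loop as composable, testable pieces:
differential expression with categorization, exact seed-match scanning,
hypergeometric over-representation, ranked-list (GSEA-style) signature
enrichment, multi-evidence candidate filtering with cross-species support,
and cross-model miRNA overlap.

## Differential expression model

Matrices are log2 intensities, features × samples, with a sample sheet
assigning each sample to one of two conditions. `quantile_normalize()`
forces all columns onto the common distribution given by the row means of
the column-sorted matrix (idempotent by construction). For a contrast
treatment vs control, `differential()` computes per feature:

* `AveExpr` — mean log2 intensity over all samples;
* `logFC` — mean(treatment) − mean(control);
* a **moderated t**: the pooled sample variance \(s^2\) (df
  \(d = n_1+n_2-2\)) is shrunk towards a prior,
  \(\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)\), and
  \(t = \mathrm{logFC} / \sqrt{\tilde s^2 (1/n_1 + 1/n_2)}\) is referred
  to a t distribution with \(d + d_0\) degrees of freedom (two-sided);
* `adjP` — Benjamini–Hochberg step-up adjustment, implemented from the
  definition and checked against a brute-force oracle.

Defaults are \(d_0 = 4\) and \(s_0^2\) = the median per-feature pooled
variance. This is a deliberate single-channel stand-in for a two-colour
dye-swap limma pipeline (print-tip loess within arrays, empirical-Bayes B
statistic): everything downstream consumes only `logFC`/`adjP`, and the
synthetic generator emits single-channel data, so the simpler moderated t
with a fixed prior is sufficient and fully specified. With `prior_df = 0`
it collapses to the ordinary pooled two-sample t (tested against
`t.test`). Under the null the default settings give a rejection rate at
p < 0.05 of ≈ 0.042 with n = 3 per group — slightly conservative because
the median-variance prior sits below the mean of a \(\chi^2\)-distributed
sample variance — which stays inside the binomial 99% calibration band
asserted in the acceptance suite.

Degenerate zero-variance features: the prior keeps t finite; if the prior
variance is also zero, t is 0 when logFC is 0 and otherwise ±Inf with
p = 0 and a warning.

`categorize()` splits features at three cutoffs: an inclusive expression
floor (`AveExpr >= min_aveexpr`) defining the background universe, and
strict fold-change and significance cuts (`|logFC| > min_abs_logfc`,
`adjP < max_adjp`) defining the up and down sets. Two presets are
exposed: `"standard"` (7.0, 0.7, 0.05), the permissive screen, and
`"stringent"` (7.0, 1.5, 0.01), the high-confidence screen used for short
candidate lists. The strict-vs-inclusive choices follow the screens'
verbal definitions ("above", "below") rather than rounding conventions.

`relative_expression_ddct()` is the comparative CT transform
\(2^{-\Delta C_T}\) for qPCR validation work.

## Seed scanning

`seed_sequence()` extracts the 6mer (2–7) or 8mer (1–8) seed and returns
its reverse complement as a DNA motif; RNA/DNA and case are
interchangeable everywhere (U↔T normalization at the boundaries).
`scan_sites()` reports *every* exact occurrence on the given strand,
overlapping occurrences included (a lookahead regex; verified against a
naive sliding-window oracle), with 0-based half-open coordinates. Only
perfect Watson-Crick complementarity is implemented — no G:U wobble,
context scores or conservation — because external tools (TargetScan-,
PicTar-, miRanda-style lists) enter as flat tables and are intersected
with the in-house scan by `intersect_sources()`, which also returns the
exclusive Venn region counts for up to three (or more) sources.

## Over-representation statistic

For each miRNA, source and category, `enrich()` forms the quadruple
N (background), K (predicted targets in background), n (category size),
k (predicted targets in the category) and computes the hypergeometric
upper tail \(P(X \ge k)\) — inclusive of the observed k, the standard
convention. The background is the *expressed* universe (AveExpr floor),
not the whole array, matching how the categories themselves are built and
avoiding inflated K; this default is the package's resolution of an
ambiguity in the original web tool. BH adjustment is applied across
miRNAs within each (source, category) family. Zero-target miRNAs yield
p = 1 with fold enrichment flagged undefined rather than being dropped.

## Ranked-list enrichment

`ranked_list()` orders features by moderated t (descending, lexicographic
tie-break so results are platform-independent). `enrichment_score()` is
the weighted running sum: increments \(|m_i|^p / \sum_{hits} |m|^p\) at
members, decrements \(1/(M - M_{hit})\) at non-members; the ES is the
signed maximal deviation. Exponent 0 recovers the unweighted
Kolmogorov-Smirnov statistic; the default exponent 1 is standard weighted
GSEA. The leading edge is the set of members at or before the peak for
positive scores and at or after it for negative scores (the standard
convention; a literal "at or before" reading is only meaningful for
positive scores).

`significance()` uses **gene-tag permutation** (size-matched random sets),
not phenotype permutation: the designs this emulates have two or three
arrays per condition, far too few to permute labels. NES divides the ES
by the mean |null ES| of the same sign; the nominal p is the same-sign
exceedance fraction with an add-one correction (never exactly zero).
With a single gene set the sign-stratified FDR q degenerates to the
nominal p and is reported as such.

## Candidates and cross-model overlap

`candidate_filter()` intersects the consensus predicted targets (≥
`min_sources` tools) with the down category under the stringent screen
and sorts by logFC ascending ("largest inhibition" is read as logFC; the
alternative — an empirical-Bayes log-odds — is out of scope).
`cross_species_support()` flags candidates whose mapped ortholog is
significantly down in an independent in-vivo table; mapping is strictly
via the supplied ortholog map (no case folding), and unmapped candidates
are flagged false with a warning rather than dropped.

`model_overlap()` screens each disease-model miRNA table with a Welch
two-sample t (pooled-variance switchable) at a strict raw-p threshold —
raw, not adjusted, because the screen is a per-model filter whose
robustness comes from requiring the *triple* intersection. The common
list additionally requires sign consistency across models; miRNAs
significant everywhere with disagreeing signs are surfaced as discordant.

## Synthetic data: what it emulates, what it does not

The generators are pure functions of their arguments including the seed.

* `gen_utrs()` plants exact seed-complementary sites in a chosen fraction
  of random UTRs (uniform positions, non-overlapping) and *destroys*
  accidental occurrences in non-planted UTRs by single-base substitution,
  re-checked to a fixpoint. The truth is therefore exact — the seed scan
  recovers it with zero errors by construction — which makes it a sharp
  oracle for the scanning/prediction code but says nothing about
  biological site functionality.
* `gen_expression()` draws per-feature baselines N(10, 1) on the log2
  scale (so the AveExpr ≥ 7 floor excludes ≈ 1% of features and remains a
  live filter), adds planted shifts to the treatment group and i.i.d.
  Gaussian noise (default sd 0.3, n = 3 per group — typical transfection
  designs). No intensity-dependent variance, spatial or print-tip
  artifacts, or dye-swap structure: a green recovery test establishes the
  statistical pipeline, not robustness to array artifacts.
* `gen_model_tables()` plants a common dysregulated subset with
  consistent signs across three models plus model-specific extras with
  random signs. Defaults — effect 2 (4-fold), noise sd 0.4, n = 5 per
  group — were fixed once by a priori power analysis (per-test power
  0.9997 at alpha 0.01, exact five-miRNA recovery ≈ 0.996 per simulation)
  to represent strong dysregulation with realistic inter-animal
  variability.

One interaction worth knowing: applying `quantile_normalize()` to a
matrix in which ~10% of features carry one-sided planted shifts
*attenuates* those shifts (it forces identical column distributions),
e.g. a planted −1.5 estimates around −1.3. That is a property of quantile
normalization with asymmetric truth, not an implementation artifact; the
synthetic pipelines therefore feed generator output (already on a common
scale) directly to `differential()`, while normalization remains the
ingestion step for real matrices.

## Numerical choices

* BH and the hypergeometric tail are checked against brute-force oracles
  (1e-12); the running-sum ES likewise, on hundreds of random instances.
* Empirical p-values carry an add-one correction.
* `adjP = 0` is floored at 1e-300 before −log10 in plot tables.
* Ties: ranking ties break lexicographically; quantile-normalization ties
  resolve by stable column order.
* Seeds: every stochastic operation takes an explicit seed and restores
  the caller's RNG state (`withr::with_seed`).

## Known limitations

Single-channel model only (no dye-swap, loess, background correction);
no G:U wobble or context scoring in the scanner; gene-tag (not
phenotype) permutation; single-set FDR degenerates to the nominal p;
ortholog mapping is symbol-level, not sequence-level. The acceptance
suite's simulations demonstrate recovery under the generators' stated
world — they are stand-ins for, not reproductions of, cohort-scale
results, which require the original deposited datasets.
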
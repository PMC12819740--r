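---
title: "Models and methods behind tescape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tescape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tescape)
```

`tescape` analyses locus-level transposable element (TE) expression in
case/control single-nucleus RNA-seq, one cell type at a time, and
integrates the result with chromatin accessibility. This vignette
explains the statistical model behind each stage, the tunable parameters
and why their defaults are what they are, what the synthetic-data
generator does and does not emulate, and the numerical and design
decisions a maintainer should know about.

## The pseudobulk negative-binomial model

Within a cell type, counts of all cells belonging to the same biological
sample are summed ("pseudobulk"), so the unit of replication is the
sample, not the cell. For feature $f$ and sample $s$ the model is

$$ y_{fs} \sim \mathrm{NB}(\mu_{fs}, \phi_f), \qquad
   \log \mu_{fs} = \beta_{0f} + \beta_{1f}\,x_s + \log N_s, $$

with $x_s$ the case indicator and $N_s$ the sample's total pseudobulk
library (computed over **all** features, genes included, before any
subsetting). The test statistic is the deviance difference between this
model and the intercept-only model, referred to $\chi^2_1$;
$\log_2\mathrm{FC} = \beta_{1f}/\ln 2$ (case over control).
Benjamini–Hochberg FDR is applied across tested features within the cell
type.

**Assumptions.** Library-size offsets (no compositional normalisation
such as TMM) assume dysregulated features are a small fraction of the
library; this holds in the generator's defaults because the gene budget
dominates per-cell counts. The $\chi^2_1$ reference assumes enough
samples for the LRT asymptotics — with 11 + 7 samples the null
simulations in the test suite put the empirical type-I rate at
$p < 0.05$ inside $0.05 \pm 0.02$.

**Fitting.** Because the design is a two-group comparison with offsets,
each group's log-rate is a one-parameter concave problem; it is solved
by Newton scoring, vectorised across features (score
$\sum_j (y-\mu)/(1+\phi\mu)$, step cap 5, at most 100 iterations,
tolerance $10^{-8}$). Features without nonzero counts in at least 2
samples per condition are excluded before testing (recorded in an
attribute); non-converged fits get `NA` p-values and are excluded from
the FDR correction. The Poisson limit ($\phi = 0$) is exact and is
checked in the tests against a closed-form two-group Poisson LRT, and
the NB path against `glm` + `MASS::negative.binomial` and against
`edgeR::glmLRT` at matched dispersion and offsets.

**Dispersion.** Per feature, $\phi_f$ is profiled on a 31-point
log-spaced grid ($10^{-4}$ to 20) with one parabolic refinement, holding
the means at the Poisson group fit; the per-feature estimate is then
shrunk on the log scale toward the geometric-mean common dispersion with
fixed weight 0.3. This is deliberately the simplest empirical-Bayes
average that passes the calibration and recovery properties; those
properties, not the recipe, are the contract.

## Balanced downsampling and the "highly robust" rule

With 11 cases vs 7 controls, `make_plans()` draws K = 10 *distinct*
uniform subsets of 7 cases (rejection resampling; the 11-choose-7 = 330
subset space makes collisions rare), keeps all controls, and the DE test
is re-run per subset. A feature is **highly robust** iff it is
significant (FDR < 0.05) in the full data and in all K iterations. The
effect filter $|\log_2\mathrm{FC}| \ge 2$ is applied *after* robustness
classification, on full-data estimates; the order is recorded in the
output metadata since both orders produce a set satisfying both
thresholds.

## Annotation and enrichment

* **Direction and class summaries** are straight ratios, reported to one
  decimal.
* **Age classes** use first-match prefix rules (L1HS and L1PA2–8 young;
  L1PA9–17 and L1PB old; L1M very old; L2/L3 ancient; AluY young; AluS
  old; AluJ and MIR ancient); unmatched subfamilies are "unclassified"
  rather than forced into a tier.
* **Family enrichment** compares observed family counts to the genomic
  baseline mix (45% Alu, 17% L1, 8% L2, 5% MIR, 8% ERV, 3% DNA, 14%
  other): a chi-square goodness-of-fit test for overall deviation plus
  per-family exact two-sided binomial tests with BH correction. The
  two-sided binomial p is the minimum-likelihood convention (the sum of
  probabilities of all outcomes no more likely than the observed one),
  which is what `binom.test` implements; sidedness is a package decision
  because conventions differ.
* **Chromosome enrichment** compares observed counts to a
  length-proportional expectation and flags folds above 1.5.
* **Cluster-size diagnostics** report DE TEs per 1,000 cells, the
  Spearman correlation of cell count with DE count (exact p for up to 10
  cell types), and the Pearson correlation of cell count with mean
  |log2FC|, so abundance-driven artefacts are visible rather than
  implicit.

## Proximity windows and the selection matrix

Pairs are formed by interval gap between the TE and the **gene body**
(0 on overlap), strand ignored, at windows of 50 kb, 250 kb, 500 kb and
1 Mb. Gene-body (rather than TSS) distance matches the nearest-distance
semantics of the interval toolkits this analysis style uses; a TSS mode
is available behind the `anchor` flag, and the choice is recorded in the
configuration because published median distances cannot disambiguate the
two.

Three metrics summarise each window: isolation % (TEs with no gene in
the window), median genes per TE (zeros included), and the number of
gene sets over-represented (one-sided hypergeometric, BH q < 0.05) among
the proximal-gene union. The **normalized selection matrix** min-max
scales each metric across windows and orients them so that lower
isolation, more significant gene sets and *lower* median coverage score
higher; the composite is their weighted mean (equal weights by default)
and ties break to the smaller window. Penalising coverage is the
package's rendering of the observation that megabase windows sweep in
excessive genes and spurious associations; the formula is isolated in
`select_window()` so alternatives can be swapped. A metric constant
across windows is neutralised at 0.5.

The gene-set step is a generic hypergeometric over-representation test
on a supplied collection — no ontology structure, propagation or
redundancy handling; it stands in for GO machinery by design.

TE-derived-gene depletion uses a 2×2 Fisher test against a configurable
genome-wide expectation of 3% TE-derived genes in a 20,000-gene
background. Genomic feature assignment classifies the TE midpoint with
precedence promoter > enhancer > exon > intron > intergenic, promoters
spanning −2,000/+500 bp around the TSS (strand-aware; both spans
configurable, the values being a common convention rather than a
biological constant).

## ATAC integration and the regulatory score

Per TE: direct peak overlap, peaks within 250 kb, and — over those
peaks' rows of the accessibility matrix — mean accessibility, variance,
and the specificity index
$\tau = \sum_i (1 - x_i/\max x)/(n-1)$ on per-cell-type means (0 =
uniform, 1 = single type). Mean matrix signal is the default
accessibility summary; peak height vs cell fractions vs binarised signal
is not identifiable from published summaries, so the summary function is
a seam.

Each TE–gene pair receives
$\mathrm{score} = 0.3\,s_\mathrm{dist} + 0.3\,s_\mathrm{acc} +
0.2\,s_\mathrm{eff} + 0.2\,s_\mathrm{corr}$ with
$s_\mathrm{dist} = 1 - \min(d, W)/W$, $s_\mathrm{acc}$ and
$s_\mathrm{eff}$ min-max scaled over the scored set (degenerate scales
neutralised at 0.5 with a warning), and
$s_\mathrm{corr} = \max(r, 0)$ — negative expression correlations carry
no regulatory support. $r$ defaults to the product-moment correlation of
log1p library-normalised TE and gene pseudobulk across sample-by-cell-type
units; externally supplied (e.g. simulated) correlations can be injected.
Normalisation contexts are stored on the result for reproducibility.

Confidence tiers: *high confidence* = peak overlap **and** composite
above the set-wise median; *Very High* additionally needs
$s_\mathrm{corr} \ge 0.3$; *Medium* = exactly one of overlap /
above-median; *Low* = neither. The 0.3 correlation-support threshold and
the XOR rule are package decisions rendering "overlap and correlation
support" concrete; both are arguments.

## What the generator emulates — and what it does not

`simulate_te_dataset()` produces negative-binomial counts for genes and
TE loci over a toy genome of four 10-Mb chromosomes (large enough for
all four windows, small enough for brute-force oracles in tests). Key
defaults and their rationale:

* **Design**: 11 case vs 7 control samples; seven brain cell types with
  per-sample cell ranges scaled to a few thousand cells total, since
  published per-sample counts are only bounded, not printed.
* **TE transcript share**: TE means are rescaled (by root-finding, with
  planted-effect inflation and the planted-baseline floor included in
  the expectation) so the realized dataset-wide mean per-cell TE
  fraction hits `target_te_fraction` (default 0.12, the 10–15% regime).
* **Planted effects**: `plant_ad_scenario()` concentrates ~63% of
  effects in an excitatory-like population (95% upregulated), ~32% in an
  oligodendrocyte-like population (65% upregulated), remainder
  scattered; magnitudes uniform on [2.2, 6.5] log2 units so the robust
  set's mean |log2FC| sits near 4. Planted TEs get a baseline floor
  (default 0.1 counts/cell) so effects act on a measurable baseline.
* **Heterogeneity**: per-feature log-normal means (gene budget
  dominating the library), mild cell-type factors (log-sd 0.25), sample
  factors (log-sd 0.1), cell-size factors (log-sd 0.3), shared NB
  dispersion 0.15 per cell.
* **Positive controls**: a configurable fraction (default 0.6) of
  planted TEs receives an overlapping ATAC peak with elevated,
  cell-type-skewed signal; three gene sets are seeded from genes near
  planted TEs; half the synthetic AD-risk list is biased toward genes
  near planted TEs.

Not emulated: reads, BAMs, UMI collapsing, ambient RNA, doublets, batch
effects, mapping ambiguity of young TE subfamilies, linked-locus
correlation structure, or realistic gene-length effects. Passing tests
therefore demonstrate statistical correctness and calibration of the
pipeline under its own model — not robustness to alignment artefacts or
to multimapping bias, which in real data notoriously depresses young-L1
detection.

## Numerical choices and problem sizes

Determinism: every stage draws from a seed derived from one root seed
per stage label; double runs are byte-identical, and the run manifest
records the config hash, thresholds and row counts (it deliberately
contains no wall-clock timestamps, to keep rerun outputs identical).
Degenerate inputs are handled explicitly: empty robust sets short-circuit
the proximity and scoring stages; constant metrics neutralise to 0.5;
zero-total cells get `NA` TE fractions; correlation of constant profiles
is `NA`.

The shipped test and acceptance problem sizes are chosen for desk-scale
runs: bundles of 120–400 genes and 100–400 TE loci over ~1,300–3,600
cells, K = 10 downsampling iterations on the full-size scenario, a
~2,500-test null calibration, and a 50-replicate recovery experiment at
sample-level dispersion 0.05 — the level a pseudobulk of ~50 cells with
per-cell dispersion 0.15 plus sample heterogeneity actually exhibits.
The recovery experiment supplies library sizes externally (as the
pipeline does, from all features) so that planted effects do not feed
back into the offsets; at desk scale this composition effect is the main
bias risk and is documented rather than hidden: with 60 strong planted
effects in a ~930-count cell, naive within-subset libraries would bias
estimates by ~0.2 log2 units.

## Known limitations

* No TMM/compositional normalisation — by design, but it means extreme
  planted scenarios (or real datasets where DE features dominate the
  library) acquire a small negative bias in log2FC estimates.
* The dispersion shrinkage weight is fixed, not estimated; `edgeR`-style
  trended/tagwise shrinkage would be strictly better at scale and can be
  swapped in behind `nb_lrt()`.
* The gene-set test ignores ontology structure; counts of "significant
  sets" across windows are comparable only within a run.
* Locus-level uniqueness vs name-level uniqueness of TE calls can differ
  when the same locus is called in several cell types; both accountings
  are exposed (`robust_de` rows vs distinct `feature_id`s) rather than
  merged.
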
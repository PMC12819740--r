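# tescape

Cell-type-resolved analysis of transposable element (TE) dysregulation in
case/control single-nucleus RNA-seq, with chromatin-accessibility-weighted
scoring of candidate TE–gene regulatory pairs.

## The problem

Transposable elements make up roughly half of the human genome and
contribute 10–15% of the transcripts detected in brain nuclei when counts
are assigned at the individual locus rather than pooled by subfamily.
In neurodegenerative disease, loss of epigenetic silencing can reactivate
individual TE loci in specific cell populations, and reactivated elements
that sit in promoters or enhancers can disturb the regulation of nearby
genes. Detecting this signal from droplet single-nucleus data raises four
statistical problems that `tescape` addresses as one pipeline:

1. **Pseudobulk differential expression.** Per cell type, cells are summed
   to sample-level pseudobulk so replication is at the biological-sample
   level. Each feature is tested with a negative-binomial log-linear model

   `log mu_fs = beta_0f + beta_1f * condition_s + log N_s`

   where `N_s` is the sample's pseudobulk library size. The test is the
   likelihood-ratio chi-square (1 df) of the condition coefficient;
   `log2FC = beta_1f / ln 2`. Per-feature dispersions are estimated by
   profile maximum likelihood and shrunk on the log scale toward the
   common dispersion. Benjamini–Hochberg FDR is applied within cell type.
2. **Robustness under imbalance.** With 11 cases against 7 controls, a
   single influential case sample can drive spurious calls. The screen
   repeats the test on K = 10 distinct random case subsets of size 7
   (all controls retained) and keeps only features significant in the
   full data *and* in all K iterations, then applies the
   `|log2FC| >= 2` effect filter — the "highly robust" set.
3. **Composition and position.** The robust set is annotated by TE
   class/family/subfamily and evolutionary age (L1HS/L1PA2–8 young, AluY
   young, AluS old, AluJ/MIR ancient, …), tested against the genomic
   baseline mix (45% Alu, 17% L1, 8% L2, 5% MIR, 8% ERV, 3% DNA, 14%
   other) with a chi-square goodness-of-fit plus per-family exact
   binomial tests, and checked for chromosome-level enrichment
   (fold > 1.5 over a length-proportional expectation) and cluster-size
   artefacts (Spearman/Pearson diagnostics, rates per 1,000 cells).
4. **From loci to genes.** TE–gene pairs are formed at 50 kb / 250 kb /
   500 kb / 1 Mb windows (interval gap to the gene body, 0 on overlap);
   a normalized selection matrix over isolation %, median genes per TE
   and gene-set enrichment picks the working window. AD-risk-gene
   proximity, TE-derived-gene depletion (Fisher), and genomic-feature
   assignment (promoter > enhancer > exon > intron > intergenic) follow.
   Finally each pair is scored against snATAC peaks:

   `score = 0.3 s_dist + 0.3 s_acc + 0.2 s_eff + 0.2 s_corr` in [0, 1],

   with confidence tiers (Very High / High / Medium / Low) anchored on
   peak overlap, the set-wise median score, and correlation support.

A fully seeded synthetic-data module generates complete inputs (sparse
counts with locus-encoded TE names, cell metadata, BED tracks, peak
matrices, gene lists and gene sets) with planted cell-type-specific
effects, so the whole pipeline runs and is calibrated at desk scale with
no external data.

## Worked example

```r
library(tescape)

cfg    <- plant_ad_scenario(simulation_config(seed = 1), n_effects = 60)
bundle <- simulate_te_dataset(cfg)
bundle
#> <te_bundle> 800 features (400 genes, 400 TE loci) x 3606 cells; 18 samples; 300 peaks

result <- run_te_pipeline(bundle, seed = 1)
result
#> <te_pipeline>
#>   features tested: 2514 | robust DE TEs: 57
#>   selected window: 250 kb | scored pairs: 262

glance(result)
#> # A tibble: 1 x 6
#>   n_de_tests n_robust_tes pct_up mean_te_pct selected_window n_scored_pairs
#>        <int>        <int>  <dbl>       <dbl>           <int>          <int>
#> 1       2514           57   89.5        12.0          250000            262

result$annotation$direction_by_cell_type
#> # A tibble: 5 x 7
#>   cell_type     n  n_up n_down n_zero pct_up pct_down
#> 1 ASC           1     1      0      0  100        0
#> 2 EX           37    36      1      0   97.3      2.7
#> 3 ODC          17    12      5      0   70.6     29.4
#> 4 OPC           1     1      0      0  100        0
#> 5 PER.END       1     1      0      0  100        0
```

The run recovers the planted structure: TE transcripts average 12.0% of
per-cell counts, 57 TE loci pass the robustness screen, ~90% are
upregulated, and the dysregulation concentrates in the excitatory-neuron-
and oligodendrocyte-like populations (37 and 17 loci), the former almost
entirely upregulated. The window-selection matrix picks 250 kb
(composite 0.944 against 0.33–0.52 for the alternatives), and 262 TE–gene
pairs are scored, 3 reaching the Very High tier:

```r
glance(result$scores)
#> # A tibble: 1 x 5
#>   n_pairs median_composite n_peak_overlap n_very_high n_high_confidence
#> 1     262            0.393            158           3                90
```

`plot_te_fraction()`, `autoplot()` on DE results and scores,
`plot_direction_summary()` and `plot_window_selection()` give the
standard views; `tidy()`/`glance()` return plain tibbles. The file-based
front end `run_pipeline(config, outdir)` drives the same stages from a
YAML config and writes every table as TSV plus a JSON run manifest;
re-running with the same config and seed reproduces the outputs byte for
byte.

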
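# regulonscope

Mapping a bacterial sigma-factor regulon — and what it does to the
proteome.

In *Caulobacter crescentus* the alternative sigma subunit sigma-32
(RpoH) drives the heat-shock response; the DnaK/DnaJ chaperone system
normally keeps it in check, and depleting DnaKJ unleashes it.
`regulonscope` is an R package for the computational pipeline that
characterizes such a response:

* **ChIP-seq peak calling** with a fixed density threshold (peaks =
  maximal runs of bins with density > 10), reported by maximum position
  and area, and **strand-aware promoter assignment**: a peak maps to a
  gene whose translation start lies within 200 bp upstream to 60 bp
  downstream of the peak maximum, with upstream-to-downstream **operon
  propagation** of direct-target flags.
* **Regulon classification** from multi-condition fold changes
  FC = (x_cond + 1)/(x_ref + 1): a gene is sigma-32-regulated when it
  crosses 2-fold in the same direction after 6 h *and* 9 h of chaperone
  depletion *and* upon sigma-factor overproduction, while the
  sigma-factor deletion background responds mildly (≥2-fold less) or
  not at all (<2-fold).  Direct targets = upregulated genes with
  promoter binding evidence.
* **TMT proteomics**: sum-to-100% normalization, mean-ratio fold
  changes, pooled-variance Student's t-test on log2 abundances,
  1.5-fold / p ≤ 0.05 calls, and transcript-protein concordance
  (Venn) accounting.
* **Proteomap-style allocation**: molecular investment = relative
  molecular count × sequence length, aggregated over a functional
  hierarchy into mass fractions that sum to 100% per level, with
  percent changes between conditions.
* **Protein half-lives** from translation-shutoff chases: log-linear
  OLS with shared slope across replicates, t1/2 = ln2/k, censored
  reporting ("t1/2 > 360 min") when decay is slower than the
  observation window.
* A **synthetic-data generator** that plants a known regulon (direct
  targets, effect sizes, half-lives) on a simulated 4 Mb genome with
  operons, so every stage is validated against ground truth.

It is aimed at microbial genomics researchers who want a transparent,
fully testable reimplementation of this class of threshold-based
regulon analysis rather than a black-box caller.

## Worked example

```r
library(regulonscope)

cfg <- sim_config(seed = 42)           # 3000 genes, 400 operons, planted
res <- run_regulon_pipeline(cfg)       # |log2 fold| = 3, noise CV 0.2
round(res$summary, 3)
#>            regulon_up          regulon_down        direct_targets
#>               300.000                78.000               180.000
#>      chip_sensitivity      chip_specificity        r2_dep_vs_v56a
#>                 1.000                 1.000                 0.877
#>     slope_dep_vs_v56a     r2_dep_vs_rpohdel           proteins_up
#>                 0.934                 0.030               214.000
#>         proteins_down            up_overlap down_overlap_fraction
#>               766.000               214.000                 0.084
```

Read: of 300 planted upregulated and 80 downregulated genes, the
classifier recovers 300 up and 78 down at 20% noise; all 180 planted
direct targets are found by peak calling + operon propagation with no
false positives (sensitivity = specificity = 1).  Depletion and
overproduction fold changes correlate strongly (R² = 0.88, slope 0.93)
while the deletion background shows no correlation (R² = 0.03) — the
planted signature of a response driven by the sigma factor.  The large
protein down-set is the compositional shadow of strong upregulation
under sum-to-100% quantification; only 8.4% of it has transcriptional
support.

Half-life estimation, uncensored and censored:

```r
course <- simulate_decay(23.5, c(0, 8, 16, 24, 32, 48),
                         noise_cv = 0.05, seed = 42)
censor_estimate(fit_decay(course), 48)
#> t1/2 = 24.1 min (k = 0.02879/min, R^2 = 0.989, n = 18)

stable <- simulate_decay(Inf, c(0, 60, 120, 240, 360),
                         noise_cv = 0.05, seed = 42)
censor_estimate(fit_decay(stable), 360)
#> t1/2 > 360 min (censored; R^2 = 0.671, n = 15)
```

Proteome mass reallocation between conditions:

```r
ch <- res$allocation$change
ch[grep("Folding|Ribosome", ch$category),
   c("category", "fraction_a", "fraction_b", "change_pct")]
#>                                                           category fraction_a fraction_b change_pct
#>  Genetic information processing / Folding, sorting and degradation       7.82      23.20      196.7
#>                                             Translation / Ribosome      14.61      11.21      -23.3
```

The folding/degradation machinery triples its share of the proteome
while ribosomal mass shrinks — resources move from proliferation to
maintenance.

To run the same classifiers on real processed data instead of
simulations, see `read_supplementary_tables()` and the methods
vignette (`vignettes/regulon-mapping-methods.Rmd`).

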
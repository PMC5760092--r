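---
title: "Methods: mapping a sigma-factor regulon and its proteome response"
author: "regulonscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping a sigma-factor regulon and its proteome response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonscope)
```

## The problem

In alpha-proteobacteria such as *Caulobacter crescentus*, the
alternative sigma subunit sigma-32 (RpoH) redirects RNA polymerase to
heat-shock promoters.  Under normal growth the Hsp70 chaperone DnaK and
its co-chaperone DnaJ keep sigma-32 activity low; depleting DnaKJ
liberates sigma-32 and remodels both the transcriptome and the
proteome.  `regulonscope` implements the computational side of mapping
that response: which genes belong to the sigma-32 regulon, which of
them are direct promoter targets, how the proteome reallocates mass
between functional categories, and how fast the factor itself is
degraded.

Every stage can run on real processed data (normalized expression
tables, binned ChIP-seq density, TMT protein abundances) or on
synthetic data with planted ground truth, so the whole pipeline is
testable end to end.

## Regulon definition from multi-condition fold changes

Per-gene linear fold changes are ratios of (replicate-averaged)
normalized expression with a pseudocount:

FC_g = (x_g,cond + c) / (x_g,ref + c),  c = 1 by default.

The pseudocount guards against division by zero and keeps
zero-expression genes from crossing thresholds spuriously; on
normalized expression of magnitude ~10^2-10^3 it is negligible for
expressed genes.

A gene joins the regulon with direction d (up or down) when three
conditions hold:

1. **Depletion response**: FC crosses the 2-fold threshold in direction
   d at *both* 6 h and 9 h of chaperone depletion (thresholds are
   inclusive, "at least twofold").
2. **Overproduction concordance**: FC crosses 2-fold in the same
   direction upon constitutive sigma-factor overproduction (the V56A
   variant, which escapes chaperone control).
3. **Deletion-background test**: in the sigma-factor deletion
   background the response is *absent* (|log2 FC| below the absent
   cutoff, 2-fold by default) *or* *milder* (at least 2-fold smaller
   than the depletion response on the log2 scale, with concordant
   signs).

The "milder or no response" wording is genuinely ambiguous, so both
arms are individually switchable (`absent_arm`, `milder_arm`) and the
milder comparison is anchored on the 6 h depletion contrast (the axis
conventionally plotted), all configurable in `classifier_config()`.

One subtlety: with the absent cutoff tied to the main fold threshold,
raising the threshold widens what counts as "no response", so the
regulon is not monotone in the threshold.  `absent_threshold` decouples
the two; holding it fixed restores the intuitive property that a
stricter threshold can only shrink the regulon, and the property suite
tests exactly that.

The attenuated-DNA-binding point mutant (D252G) contrasts are computed
and reported but never enter the regulon definition; its response is
modeled in the generator as half the log2 fold, a modeling choice (the
observation being emulated is only "similar but less pronounced").

No dispersion-based differential-expression test (DESeq2-style) is
applied: the definition is a pure fold-change filter by design, and the
package implements it as such.

## Peak calling and promoter assignment

The ChIP signal is a strandless, binned read-density track (default 10
bp bins; the bin width of typical processed tracks, configurable).  A
peak is a maximal contiguous run of bins with density strictly above
the threshold (default 10); "remained above" is read literally, so bins
equal to the threshold terminate a run, with a `strict = FALSE` escape
hatch.  Each peak reports the position of its maximum — the center of
the leftmost maximal bin, so all position comparisons carry a
±bin-width tolerance — and its area (sum of density over the run).

A peak is assigned to a gene when the gene's translation start lies
within 200 bp upstream through 60 bp downstream of the peak maximum.
"Upstream" is only meaningful relative to transcription, so the window
is applied strand-relatively by default; `strand_relative = FALSE`
offers an absolute-coordinate compatibility mode since processed
datasets do not always state their convention.

Operon propagation is upstream-to-downstream only: a window-assigned
peak marks the assigned gene and every gene transcribed after it in the
same operon as direct targets; genes upstream of an internal peak are
never flagged.  A gene listed in two operons is an input error.  Tracks
are treated as linear; the chromosome is circular, but no annotated
gene or planted site spans the origin in generated data, and real
tracks are produced on linearized coordinates.

## TMT proteomics

Protein abundances are normalized to portions of 100% per sample, the
standard relative-abundance convention for isobaric labeling.  Fold
changes are ratios of group means on the normalized scale; significance
is a two-sample Student's t-test on per-replicate log2 abundances,
pooled-variance by default (the classic reading of "Student's t-test";
Welch via `var_equal = FALSE`).  Calls use 1.5-fold and raw p <= 0.05
with **no multiple-testing correction** — deliberately, because the
threshold+p convention for TMT screens is reproduced as-is; treat the
resulting counts as screen-level, not FDR-controlled.

Zero-variance groups (possible only in noiseless synthetic data) yield
an undefined p-value and are excluded from significance-gated calls.
Proteins absent from every replicate of a group are reported as
not-detected rather than erroring.

Because columns are forced to sum to 100, a strong planted response
drags every other protein's relative abundance down (compositional
drift).  This is a real property of relative quantification, not an
artifact: recovery tests correct for the drift analytically when
comparing estimated ratios to planted folds.

## Mass-fraction allocation (proteomaps)

A protein's molecular investment is its relative molecular count (mean
normalized abundance over a condition's replicates) multiplied by its
sequence length — the share of amino acids committed to it.
Investments are renormalized to 100% and summed over the levels of a
functional-category hierarchy; fractions sum to 100% at every level and
a parent equals the sum of its children.  Changes between conditions
are reported both relative (Δ/baseline × 100, the "increased by 49%"
form) and in absolute percentage points.  Statistically insignificant
proteins stay in the sums — significance affects only downstream
coloring metadata, produced by `export_treemap_data()`; the Voronoi
geometry of treemap figures is out of scope.

## Decay kinetics

Chase time courses are fitted with first-order decay, the standard
model for translation-shutoff experiments: each replicate is normalized
to its t = 0 intensity, ln(intensity) is regressed on time with a
shared slope and per-replicate intercepts (log-linear OLS is chosen
over nonlinear least squares for determinism; the estimates coincide
exactly on noiseless data), and t1/2 = ln 2 / k.  When k <= 0 or the
half-life exceeds the last observed timepoint, the estimate is censored
and reported as a lower bound ("t1/2 > 360 min" for a 6 h chase) —
slower decay is simply not observable within the window.

## The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions every recovery test runs under:

| parameter | default | rationale |
|---|---|---|
| genome_length | 4.0 Mb | alpha-proteobacterial chromosome scale |
| n_genes | 3000 | plus 400 operons of 2-4 genes, >= 300 bp intergenic spacing |
| n_up / n_down / n_direct | 300 / 80 / 180 | the scale of the mapped regulon |
| effect_up / effect_down | 8 / 0.125 | planted \|log2 fold\| = 3 |
| noise_cv | 0.2 | multiplicative lognormal, typical RNA-seq ratio noise |
| chip background / peak height | 2 / 50 | background far below, peaks far above the calling threshold of 10 |
| bin_width | 10 bp | typical processed-track binning |
| n_replicates | 3 | independent biological triplicates |

Noise is multiplicative lognormal throughout (unit mean, specified CV):
it preserves positivity and matches ratio-based analysis.  Binding
sites are Gaussian bumps (sigma = 40 bp) centered 20-80 bp upstream of
the leader translation start.  That offset range is deliberate: with
>= 300 bp intergenic spacing it makes every planted site fall in
exactly one gene's assignment window, so the noiseless end-to-end run
recovers the planted truth with sensitivity = specificity = 1 — an
identity property the acceptance suite asserts at full scale.

Direct targets are planted as whole transcription units (a selected
operon is up + direct for all members, with the site at its leader),
the only configuration self-consistent with upstream-only propagation.
Expression is one sample per condition (the typical design of the
emulated RNA-seq contrasts); the proteome is triplicate with a
configurable transcript-protein concordant fraction (default 0.7).

What the generator does *not* emulate: read-level artifacts (no FASTQ,
no alignment, no duplicates), overdispersed counts, batch effects,
operon-internal promoters, or peak-shape irregularities.  Passing
recovery tests therefore validate the logic and the estimators, not
robustness to those real-data pathologies.

## Test-design notes

* Recovery rates are checked as means over 20 fixed seeds at the
  default (3000-gene) scale for the regulon classifier, and at a
  200-gene scale for per-protein ratio recovery, where each seed
  contributes 10 planted proteins.
* The protein-ratio recovery test uses 12 replicates rather than the
  triplicate default: the ratio-of-means estimator has relative
  standard error ≈ cv·sqrt(2/n), and a 10%-of-truth recovery band is
  only ~1.2 SE wide at n = 3 (≈78% coverage by construction) versus
  ~2.5 SE at n = 12.  The band is a property of the estimator's
  precision, so the test supplies the replication that precision
  requires; triplicates remain the simulated study condition
  everywhere else.
* Half-life recovery uses a 48 min chase with 6 timepoints at 5% noise
  (within 10% over 20 seeds); censoring is exercised with a 360 min
  chase of a stable protein.
* Oracle tests never share code with the implementation: the peak
  caller is checked against a naive single-pass scan, the regulon rule
  against an exhaustive per-gene boolean filter, and t-test p-values
  against the closed-form pooled-variance formula (to 1e-10).

## Reproducing published counts

`read_supplementary_tables()` ingests TSV exports of an article's
processed data (normalized expression per condition, promoter
ChIP-enrichment flags, TMT abundances, sequence lengths and the
functional hierarchy) and the same classifiers run on them unchanged;
the acceptance suite contains the corresponding checks.  The processed
dataset itself is not redistributable with the package and must be
supplied by the user.

## Known limitations

* The regulon definition inherits every ambiguity of threshold-based
  set logic; the configurable arms exist to make those choices explicit
  rather than to remove them.
* Peak calling has no statistical background model — by design it
  reproduces a fixed-threshold definition, and is not a general-purpose
  ChIP-seq caller.
* Protein-to-gene mapping defaults to shared identifiers; real data
  need an explicit mapping table.
* Censored half-lives carry no confidence interval; the bound is the
  observation window, nothing more.
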
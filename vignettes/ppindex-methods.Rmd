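---
title: "Methods: the pyroptosis potential index and its analysis battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the pyroptosis potential index and its analysis battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppindex)
```

## The model

Pyroptosis activity is not directly observable in bulk RNA-seq; what can
be measured is the coordinated transcription of the genes that regulate
it. The pyroptosis potential index (PPI) summarizes this per sample as a
directional single-sample enrichment score: the ssGSEA enrichment score of
the positive-regulator set minus that of the negative-regulator set.

The score depends on a sample's expression vector only through its
within-sample ranks (ties averaged, walking order made deterministic by
breaking rank ties on gene symbol). Consequences worth knowing:

* the index is invariant under any strictly monotone transform of a
  sample's expression (FPKM vs log2(FPKM+1) does not matter);
* it is *relative*: it measures where the regulator genes sit in a
  sample's own expression distribution, not absolute abundance;
* raising the expression of a positive regulator (holding other genes'
  order fixed) can never decrease the positive-set score.

### The catalog

`prgCatalog()` ships the curated pyroptosis-regulator catalog: 46 positive
and 12 negative regulators, 58 symbols in total. The source reviews
summarize the catalog as "57 PRGs" while enumerating 58 distinct symbols;
we transcribe the enumerated lists verbatim — the lists, not the count,
are the operative input — and record the discrepancy in the
documentation rather than guessing which symbol to drop (CD274/PD-L1 is
the most likely double-count candidate, appearing both as a positive
regulator and among the immune checkpoints). Symbols are matched
case-sensitively after whitespace trimming; no alias resolution is
attempted, so expression matrices must use the same symbol dialect
(e.g. GSDME, not DFNA5).

### Parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.25 | ssGSEA rank-weight exponent (dimensionless). 0 weights all set genes equally; larger values emphasize highly expressed members. 0.25 is the documented default of the widely used single-sample implementation. |
| `normalize` | `TRUE` | divide each direction's scores by their range (max − min) across the samples of the run before subtracting. The published index formula subtracts "two enrichment scores" without stating normalization, so both behaviors are exposed; normalized is the cited implementation's default. Note normalized scores are run-relative: adding samples changes everyone's index. |

The ssGSEA aggregation is the *sum* of the running-sum deviations over all
positions (single-sample convention), not the maximum deviation (two-group
GSEA convention). The two-group GSEA stage (`gseaScore`) uses the maximum
deviation, signed, with ties between the positive and negative extremum
resolved toward the positive deviation (documented because exact ties do
occur with the unweighted statistic on short lists).

## Group splitting and survival

`splitGroups()` implements three rules: `median` (default; strictly above
the within-stratum median is "high", at-or-below — including samples
exactly at the median — is "low"), `mean`, and `top_bottom_30`
(`ceiling(0.3 n)` samples at each extreme, middle discarded). The source
analyses describe both a median and a mean split in different places;
median is the default and every output records the rule used.

Survival analysis delegates the standard machinery to the `survival`
package: two-group log-rank via `survdiff` (deaths pooled at tied times)
and univariate Cox regression via `coxph` with Breslow tie handling
(chosen as the simplest well-defined convention; the tie method is not
otherwise pinned down). Survival times of exactly zero are shifted to 0.5
days to keep subjects in the risk set at entry; negative times are
rejected. Cohorts with no events return a sentinel rather than a test.
Perfect separation / non-convergence is flagged (`converged = FALSE`)
with no estimate. `survivalScan()` reports both the continuous-score and
the group-indicator hazard ratio, since either dichotomized or continuous
modeling is defensible; rows are labeled favorable (HR < 1) or adverse
(HR > 1). Raw p-values drive the significance stars (the p < 0.05
convention of the field); Benjamini–Hochberg-adjusted values are reported
alongside, adjusted across strata within each endpoint.

## Permutation GSEA

Ranking between high and low groups uses the signal-to-noise ratio
`(mean_high − mean_low) / (sd_high + sd_low)` with each sd floored at
`max(0.2 |group mean|, 0.2)` — the classic desktop behavior, preventing
near-constant genes from dominating. Weight `p = 1`, 1000 permutations,
and **gene-label** permutations are the defaults: once only the ranked
list is retained, sample-label permutation is no longer possible, and the
gene-label null has the convenient property of depending on a set only
through its size, so nulls are computed once per distinct size.

NES is ES divided by the mean |null ES| of matching sign; the permutation
p-value is the same-sign tail proportion with +1 smoothing; FDR is the
GSEA-style ratio of sign-matched tail proportions of the pooled null NES
and the observed NES, clipped to [0, 1] and then made monotone (each
set's FDR becomes the minimum over all sets at most as extreme) so a
larger |NES| can never carry a larger FDR. A sign with no null mass
yields a flagged `NA` NES.

## Associations, TMB, mutation frequencies

Spearman correlation (Pearson on average ranks) is the default for
score associations; the exact permutation null is used for n ≤ 9 without
ties, the t approximation otherwise. Pearson is used for checkpoint-gene
and cell-line/drug correlations, matching the conventions of the analyses
being reproduced. Missing values are pairwise-deleted per test, never
imputed; constant inputs yield flagged undefined coefficients rather than
errors mid-scan.

TMB is nonsynonymous mutations per megabase. The per-Mb definition leaves
the denominator open; we default to 38 Mb (a common exome-size
convention), configurable. The nonsynonymous vocabulary defaults to the
nine standard MAF classes (`tmbVocabulary()`); rows with classifications
outside the documented MAF vocabulary are excluded with a warning and
counted in a QC attribute. Mutation frequency counts a sample once per
gene regardless of row multiplicity and defaults to nonsilent rows only
(flag available), since the silent/nonsilent choice is not pinned down by
the source figures.

ESTIMATE and CIBERSORT outputs (purity, stromal/immune scores, 22 cell
fractions) are consumed as precomputed tables; those algorithms are cited
tools, not this package's contribution, and reimplementing them would
invite silent divergence.

## Drug-sensitivity model

The IC50 predictor is deliberately simple and fully stated in its
metadata: genes shared between the cell-line panel and the tumors are
z-scored per gene within each matrix independently (constant genes
dropped, ≥ 200 usable shared genes required by default), and per drug a
ridge linear model (intercept unpenalized via centering, SVD solution) is
fit with the penalty chosen by seeded 10-fold cross-validation over
`10^seq(-3, 3, 0.5)`, ties broken toward the stronger penalty. The λ = 0
limit is exactly least squares; λ → ∞ collapses predictions to the
training mean. This is *not* a re-implementation of published
transfer-learning predictors (no IC50 power transform, no empirical-Bayes
batch homogenization), and outputs say so. Orientation is stated
everywhere: lower IC50 = more sensitive.

A caveat the tests make explicit: dense ridge cannot recover a sparse
5-gene signal when noise genes vastly outnumber training lines (held-out
correlation degrades well below 0.8 at p ≈ 250 genes for 45 training
lines, for our implementation and an independent one alike), so the
recovery checks run on a compact 40-gene panel where the model class is
adequate. On real panels the model leans on co-expression structure that
the i.i.d. recovery fixture deliberately lacks.

## The synthetic cohort generator

`simulateCohort()` emulates the *shapes* and the *statistical couplings*
of the real pan-cancer inputs so that every stage runs and is testable
offline:

* baseline expression is Gaussian on the log2(FPKM+1) scale (per-gene
  means N(3, 1.5²), per-value noise sd 1, clipped at 0);
* each tumor draws a latent activation a ~ Uniform(0, 1) (normals: 0) —
  uniform rather than binary so the index behaves as a continuous score
  while thresholded recovery metrics (AUC against a > 0.5) remain
  available;
* positive-catalog genes shift by +δ·a (δ = 1.5 log2 units by default),
  negative-catalog genes by −κ·δ·a (κ = 1);
* four survival endpoints are exponential with log-hazard β·a per stratum
  (β = 0.8 default, sign configurable per stratum; baseline rate 1/1000
  per day) under independent exponential censoring tuned to ≈ 30%;
* immune and stromal scores rise linearly in a; purity falls as
  1 − 0.5·ic·a (ic = 0.6); three planted cell fractions (M1 macrophages,
  CD8 T cells, Tregs) couple to a through their gamma shape so the signal
  survives compositional normalization at the rank-correlation sizes
  reported for such couplings in real cohorts (ρ ≈ 0.3–0.5); the
  remaining 19 fractions are uncoupled;
* stemness (RNAss/DNAss), MSI and HRD carry mild negative couplings;
  mutation counts are Poisson (≈ 2/Mb over 38 Mb) with optional
  activation coupling (off by default);
* cell lines get their own activation and IC50 = base − drug-coupling·a
  + noise for seven named chemotherapy/targeted agents;
* immune subtypes C1–C6 are assigned by binning a (ordered so the
  IFN-γ-dominant subtype C2 sits highest, matching the pan-cancer
  observation) with 10% label noise.

All randomness flows from one mandatory master seed through fixed
per-stage sub-seeds, so identical configs are bitwise-reproducible and
stages can be regenerated independently. What the generator does *not*
emulate — and what passing tests therefore do not certify about real
data — includes gene–gene co-expression and batch structure, realistic
survival-time distributions, cancer-type-specific expression programs,
subclonality, and copy-number/methylation modalities.

## Problem sizes

The shipped test-suite and acceptance computations use cohorts of 40–200
samples with 300–1000 genes, 200 replicate strata for null calibration,
100 replicates for Cox recovery at n = 300, 1000 permutations for GSEA,
and a 60-line/40-gene drug panel — sizes at which every planted effect is
comfortably detectable and the whole suite runs in well under a minute of
compute per module, which we consider the right regime for a reusable
verification battery.

## Known limitations

* Normalized scores (the default) are run-relative; cross-cohort
  comparisons need either raw mode or a fixed reference cohort.
* The catalog is a snapshot of a moving literature; regulators absent
  from it simply do not inform the index.
* The index reads transcription only — no translation, modification, or
  protein-level regulation.
* Gene-label permutation GSEA tests a different null than sample
  permutation and is anti-conservative under strong gene–gene
  correlation.
* The drug model's simplifications (above) make its absolute IC50 scale
  meaningless; only comparisons and correlations are interpretable.
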
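---
title: "Methods: rank-based infiltrate scoring and the LUSC subtype pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank-based infiltrate scoring and the LUSC subtype pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infiltrank)
```

This vignette documents the models and procedures the package implements,
the parameters that matter, the numerical conventions chosen where the
procedures leave room, and what the synthetic-data tests do and do not
demonstrate about real cohorts.

## Data model

Expression data travel as wide tibbles: `symbol` and `entrez` identifier
columns plus one nonnegative numeric column per sample (normalized RSEM-scale
values for RNA-seq cohorts, RMA-scale for arrays). Zero is a valid expression
value; missingness (`NA`) is distinct and arises either from explicit NA
tokens at read time or from the log transform of zeros downstream. Duplicate
gene rows are retained at read time — collapsing is an explicit operation
(`collapse_probes()`) used only for the array and cross-species stages.
Clinical data are per-sample tibbles of survival years, an event indicator
and an optional stage label.

## Survival preprocessing

`preprocess_survival()` implements the curation rules for TCGA-style raw
records: records with negative days-to-last-follow-up are discarded (a
negative time is unusable and the conflict has no computational resolution);
dead patients contribute days-to-death; alive patients contribute the
maximum of last-follow-up and last-known-alive; years = days/365. An alive
record with a positive days-to-death is contradictory; since resolving it
requires consulting the clinical source, the record is kept (vital label
wins) but flagged, with a `conflict_override` argument for manual
resolution. This keeps the irreproducible curation step out of the
automated path while making it explicit.

## Subtype assignment and aggregation

Tumors are assigned by Pearson correlation against published four-subtype
centroids after log2 transform (zeros → missing) and per-gene median
centering, over the genes shared with the centroid table. Correlations use
pairwise-complete entries, consistent with the missing-value convention.
Exact ties in the maximal correlation — measure-zero on real data — fall
back to the fixed order Classical, Basal, Primitive, Secretory.

Aggregation averages each gene inside each subtype, correlates the four
mean vectors pairwise, and takes the two highest mutually exclusive
coefficients greedily: the globally best pair first, which forces the
remaining pair. A brute-force check over the three perfect matchings of
four subtypes is part of the test suite rather than the algorithm, because
the greedy step matches the procedure's stepwise description. Display order
puts the largest subtype of each aggregate at the flanks, yielding the
canonical C–B–P–S layout on cohorts with the reference structure.

## The gene-selection cascade

`hybrid_select()` keeps a gene only when all five criteria hold:

| criterion | statistic | threshold |
|---|---|---|
| a | (max−min)/(min+ε) of the two group medians | strictly top 50% of genes |
| b | two-sided Wilcoxon rank-sum p, presence filter | p calculable and < 0.01; presence > 60% of samples |
| c | Storey q among calculable, presence-passing genes | q < 0.01 (and b holds) |
| d | overall median | strictly above the first octile of gene medians |
| e | standard deviation | strictly top 50% (GO variant e′: top 1/3) |

Conventions: "strictly in the top f" is rank (average ties) > n·(1−f), so a
tie straddling the cut fails; the first octile is the nearest-rank (lower)
order statistic, an order statistic rather than an interpolated quantile;
ε is the machine double epsilon, which keeps the ratio finite for zero
medians without distorting nonzero ones. The Wilcoxon test is exact when
both groups have ≤ 20 samples and no ties, otherwise the normal
approximation with continuity correction. A p-value is "not calculable"
only in the fully degenerate case where every value in both groups is
identical. The presence count (values ≥ 0.5) is evaluated on the raw
normalized scale, before any transform.

Storey q-values use the smoother π₀ estimate (natural spline of
π₀(λ) = mean(p > λ)/(1−λ) over λ = 0.05…0.95, evaluated at λ = 0.95). With
fewer than 100 p-values the smoother is unstable, so π₀ falls back to 1 and
the q-values coincide with Benjamini–Hochberg — the conservative direction.

Because e′ (top 1/3) implies e (top 1/2), the GO-variant selection is a
subset of the hybrid selection on any input; the suite asserts this as an
invariant.

## Heat-map structure

Clustering uses uncentered correlation (cosine about zero) as similarity
and average linkage, the convention of the legacy Cluster 3.0 tool, with
pairwise-complete handling of missing entries; an item with no overlap
against any other cannot be placed and goes last with a warning. Genomic
dissimilarity between subtypes is the city-block (L1) distance between
per-gene subtype means; the tests verify the metric axioms and a naive
summation oracle.

Two detectors cut a row-ordered matrix:

* `heatmap_split()` scans a window with Δ(CB, PS) — the difference between
  the average hyper-expression fraction (samples ≥ gene mean; ties count as
  above, matching the ≥ definition of hyper-expression) of the CB and PS
  subtypes — and ends the upper portion one gene after the maximal prefix
  with Δ < 0, tolerating violation runs up to `tolerance` genes (default 3).
  Runs reset when the sign returns below zero; the alternative
  (accumulating violations across the window) would make the split depend
  on distant, unrelated fluctuations. The window and tolerance are
  parameters because their published values are dataset-specific.
* `splitting_point()` finds the first sign flip away from the sequence's
  leading sign that persists for at least five following consecutive-value
  pairs. Flips back toward the leading sign are reversions, not splits —
  this is what makes a short +,−,+,… excursion a non-split.

## Survival statistics

The median split sends values ≥ the median (standard sample median; mean of
the central order statistics for even n) to the high group, making the
split — and hence the hazard ratio — invariant under strictly increasing
transforms. The proportional-hazards fit uses the Efron tie approximation
by default (the stricter standard; Breslow is available behind a switch
since the original fitting routine's convention is unknowable), with a Wald
95% CI on the log-HR scale and a log-rank p on the same split. The batch
screen applies this per gene and adds BH FDR over the testable genes'
log-rank p-values; constant genes are flagged untestable and carry no FDR.

## Immune density scores

For each marker gene, samples are ranked ascending 1..n with average ranks
for ties; per cell type, ranks are averaged across markers per sample.
Dual-membership genes (at most two cell types per gene; a third is a
validation error) contribute with full weight to both types. Rank averaging
conserves the rank sum, so each cell type's scores average to exactly
(n+1)/2 — the suite asserts this exactly, not approximately. The CD14 score
ranks the nine CD14+ cell types by their high/low-CD14 density-score ratio
(9 = highest); exact ties are broken by the declared cell-type order so the
result is always a permutation of 1..9. Cell-type correlation structure
uses Spearman coefficients clustered in both dimensions without any
transformation or centering, with colour bounds at the matrix min/max.

## Mouse gradient patterns

Differential expression between two replicate groups requires (a) complete
separation in one direction — whose probability under exchangeability is
1/C(n₁+n₂, n₂), verified by enumeration — (b) a relative mean difference
≥ 50%, and (c) a range in the top 75% of genes. The 50% baseline is the
smaller of the two means, consistent with the relative-variation convention
of the RNA-seq criterion (a); the choice is configurable because the
procedure's own baseline is unstated. Sub-patterns A-1/A-2 (and mirrored
B-1/B-2) are evaluated literally from their requirement lists; A-2's
grand-mean requirements are strict, so a configuration like means 1 < 2 < 3
with the grand mean at 1.9 satisfies A-1 but not A-2 (the middle group is
not strictly below the grand mean). Negating all values swaps the A and B
families exactly — a property test.

Cross-species selection maps mouse-selected genes through an ortholog table
and filters by presence (> 60% of Classical+Secretory samples) and
Classical-vs-Secretory Wilcoxon BH FDR < 5×10⁻⁵, then splits by the
median(Classical)/median(Secretory) ratio. A ratio of exactly 1 goes to the
"below" list; an infinite ratio (zero Secretory median) goes to "above"
with a warning.

## Synthetic cohorts: what they emulate

`generate_cohort()` draws four log2-scale centroids as baseline +
pair-shared shift + subtype-specific shift (defaults 1.2/0.8/0.4 sd), so
Classical–Basal and Primitive–Secretory are the correlated pairs by
construction; samples are centroid + Gaussian noise on the log scale
(log-normal on the raw scale — the pipeline consumes normalized values, not
counts, so a negative-binomial count model would be the wrong scale), with
a configurable fraction of zeros exercising the null→missing path. Default
cohort size is 348 with subtype proportions approximating the reference
cohort's 208/140 CB/PS balance. `generate_survival()` plants an exponential
hazard multiplied by the target ratio for marker-high samples, with
independent exponential censoring. `generate_signature_cohort()` adds
marker modules sharing latent activities, one coupled (default r = 0.9) to
a CD14-like gene. `generate_mouse_arrays()` plants monotone condition means
with a minimum gap of `effect` noise standard deviations and a 1.6× ratio
per step (clearing the 50% mean-difference criterion); `effect = 0`
collapses planted genes onto a flat profile, making them proper nulls.

Problem sizes in the tests and the acceptance script (cohorts of 80–500
samples, 40–2000 genes, 50-seed recovery loops) were chosen as the smallest
scales at which the planted effects are statistically identifiable.

What passing these tests shows: the implementation recovers planted
structure (labels, hazard ratios, coupled modules, gradient genes) at
realistic noise, and its null behaviour is calibrated. What it does not
show: robustness to batch effects, to library-size artefacts, to deviations
from proportional hazards, or to marker lists that are wrong for the tissue
— none of which the generators simulate. The packaged signature file is a
synthetic stand-in reproducing only the *composition* of the curated
signature (598 genes, 572 single- and 26 dual-membership, 29 cell types);
its gene lists are not biological marker sets, except the six canonical
inflammatory monocyte markers kept under the IM label.

## Degenerate inputs and numerical tolerances

Zeros become missing only at the log-transform boundary; all-zero genes
survive as flagged all-missing rows. Constant genes: untestable in the
median split, degenerate (NA) in the Wilcoxon, zero relative variation.
Centering is exact to 1e-9 per row (asserted). Correlation-test p-values
match numeric t-tail integration to 1e-10. A perfect correlation (1−r² at
machine epsilon) reports an infinite t statistic and p = 0 rather than a
spurious finite value.

## Interface notes

The pipeline is driven from R: `pipeline_config()` + `run_pipeline()`
execute the full synthetic end-to-end analysis deterministically (the run
report carries per-stage status and timings), and each stage is an exported
function usable on real data frames. Intermediate results are written as
TSV when an output directory is configured; gene-set inputs export as GCT
v1.2 + CLS for external enrichment tools, whose own computations are out of
scope — only their input preparation and output filtering
(`filter_enrichment_terms()`) are implemented.
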
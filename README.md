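# infiltrank

Rank-based immune infiltrate scoring and expression subtype analysis for
lung squamous cell carcinoma (LUSC) cohorts.

## The problem

Bulk RNA-seq of a tumor mixes malignant cells with the immune infiltrate.
Deconvolution methods (CIBERSORT, TIMER, ssGSEA) estimate cell-type
proportions from reference profiles; this package implements a simpler,
deconvolution-free alternative built entirely on within-cohort ranks, and
the surrounding cohort analysis that identifies an immune-rich, poor-prognosis
subset of LUSC:

* **Subtyping** — nearest-centroid assignment of each tumor to the four LUSC
  expression subtypes (Classical, Basal, Primitive, Secretory) by Pearson
  correlation on log2, median-centered expression, and correlation-based
  aggregation of the four subtypes into the CB (Classical+Basal) and PS
  (Primitive+Secretory) groups.
* **Gene selection** — a five-criterion cascade combining the relative
  variation of group medians, Wilcoxon rank-sum tests with a presence filter,
  Storey q-values, an expression floor (first octile of gene medians) and a
  heterogeneity requirement (top half / top third of standard deviations).
* **Heat-map structure** — uncentered-correlation, average-linkage ordering;
  city-block "genomic dissimilarity" between subtype mean vectors; and two
  gradient-based detectors that split a clustered matrix into upper/lower
  portions (the Δ(CB, PS) hyper-expression scan and the sustained sign-change
  "splitting point").
* **Survival** — clinical record curation, Kaplan–Meier/log-rank comparisons,
  and a batch per-gene screen fitting a proportional-hazards model on the
  median split of each gene (high = value ≥ gene median), with
  Benjamini–Hochberg FDR.
* **Immune density scores** — the core statistic. For each marker gene of an
  immune cell type, samples are ranked 1..n (ties averaged); a sample's
  density score for that cell type is the mean of its ranks over the type's
  markers:

  `score(sample j, type T) = mean over genes g in T of rank_j(g)`

  Scores live on the 1..n scale, average exactly (n+1)/2 per cell type, and
  depend only on within-gene ranks. The **CD14 score** then ranks the nine
  CD14+ cell types (1..9) by the ratio of their mean density score in
  CD14-high (≥ median) versus CD14-low samples.
* **Mouse gradient patterns** — for a normal → primary → metastatic replicate
  design (4+3+3 arrays), complete-separation differential criteria with a
  combinatorial implied p-value (1/C(7,3) = 0.0286 for 4 vs 3) and the
  monotone sub-pattern definitions A-1/A-2/B-1/B-2, plus ortholog-matched
  cross-species selection.
* **Synthetic cohorts** — seeded generators for every input (expression with
  subtype structure, survival with a planted hazard ratio, marker modules
  coupled to a CD14-like gene, replicate arrays with planted gradients), so
  the whole pipeline is testable without downloads.

Everything is tidyverse-shaped: functions take a data frame first and return
tibbles, results have `tidy()`/`glance()` methods and `autoplot()` figures.

## Worked example

A synthetic 120-sample cohort with one immune module coupled (r = 0.9) to a
CD14-like gene, survival driven by CD14 (planted hazard ratio 2):

```r
library(infiltrank)

co <- generate_cohort(n_samples = 120, n_genes = 300, seed = 7)
sc <- generate_signature_cohort(co, coupling = 0.9, seed = 8)
ds <- density_scores(sc$expr, sc$signature)
cd14 <- as.numeric(expr_mat(sc$expr)[sc$expr$symbol == "CD14", ])
cl <- generate_survival(setNames(cd14, ds$sample), hr = 2, seed = 9)

cd14_scores(ds, cd14, sc$truth$types, cl) |>
  dplyr::arrange(dplyr::desc(cd14_score))
#> # A tibble: 9 x 5
#>   cell_type   density_ratio cd14_score hazard_ratio logrank_p
#> 1 IM                  2.29           9        1.93    0.00356
#> 2 aDC                 1.33           8        1.38    0.130
#> 3 Neutrophils         1.04           7        1.30    0.229
#> ...
```

The planted IM (inflammatory monocyte) module gets the top CD14 score (9 of
9): its density ratio between CD14-high and CD14-low samples (2.29) is the
largest of the nine CD14+ cell types, and its high-density samples carry the
clearest survival disadvantage (HR 1.93, log-rank p = 0.0036) — the
behaviour the score system is designed to surface. Subtype aggregation on
the same cohort recovers the planted pair structure:

```r
aggregate_subtypes(co$expr, co$labels)
#> Subtype aggregates: Primitive+Secretory | Classical+Basal
#> Display order: Classical, Basal, Primitive, Secretory
```

`autoplot()` works on the screen, density, CD14 and correlation objects;
`plot_km()` draws Kaplan–Meier curves for any labelled grouping.

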
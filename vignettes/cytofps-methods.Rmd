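---
title: "Methods: FPS clustering and penalized classification for CyTOF cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FPS clustering and penalized classification for CyTOF cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

`cytofps` implements an end-to-end analysis for paired-condition mass
cytometry (CyTOF) cohort studies comparing two groups of individuals
(labelled `HD` and `RA`). Each individual contributes one basal and one
stimulated sample measured on a fixed 28-channel panel: 7 quality-control
channels (Gaussian discriminator parameters and DNA intercalators), 12
phenotyping markers used for clustering and annotation, and 9 functional
(signaling / activation) markers used for features and group tests.

The pipeline is deterministic given a seed and a feature table, and every
stage is exposed both as R functions and through `run_pipeline()`.

```{r}
library(cytofps)
```

## Synthetic cohorts with ground truth

Real cohort-scale data cannot ship with a package, so `cytofps` includes a
fully seeded generator. `simulation_config()` describes a cohort: subsets
with mixture proportions and phenotyping profiles, planted group effects
(arcsinh-scale shifts of functional markers in chosen subsets, either in
the basal state or in the stimulation response), a debris component
separated from intact cells by at least 3 population standard deviations
on the QC channels, and log-normal between-individual variation.
`default_paper_scenario()` plants basal shifts (p-p38, IkBa and p-cJun in
CD4 T cells; p-NFkB up and CD86 down in classical monocytes and myeloid
dendritic cells) plus a weaker stimulation-response component, scaled by
`effect_scale`. The returned truth object records per-event subset labels,
debris flags, realized mixture proportions and the planted effect table,
so that recovery can be scored exactly.

```{r}
cfg <- default_paper_scenario(n_hd = 4, n_ra = 4, events_per_sample = 500,
                              seed = 1)
sim <- simulate_cohort(cfg)
length(sim$tables)          # 8 individuals x 2 conditions
head(sim$truth$labels[[1]])
```

The generator is a benchmarking device, not a physical model of a mass
cytometer: it plants Gaussian (arcsinh-scale) subsets and leaves out
spillover, acquisition drift, doublet kinetics and batch structure.

## Event cleanup

Debris and doublets are removed per sample with a 2-component Gaussian
mixture with full covariance, fitted by EM on the 7 QC channels after
per-channel scaling to zero mean and unit population standard deviation
(denominator `n`, not `n - 1`). EM is initialized from a seeded k-means
partition, covariance estimates carry a `1e-6` ridge, and convergence is a
`1e-8` relative log-likelihood change. The smaller-weight component is
discarded. The per-sample report records counts, component weights and
convergence, and cleanup refuses zero-variance channels rather than
silently dividing by zero.

```{r}
cl <- clean_cohort(sim$tables, seed = 1)
cl$report[1:3, c("individual_id", "condition", "n_total", "n_kept")]
```

## Transform, pooling and FPS clustering

Marker channels (phenotyping + functional) are transformed with
`asinh(x / 5)`; QC channels stay untransformed, and double transformation
is an error. Cleaned basal and stimulated events from all individuals are
pooled, and clustering runs on the 12 phenotyping channels only.

Cluster representatives are chosen by greedy farthest point sampling
(FPS): starting from a seeded random event, each step adds the event
farthest (Euclidean) from the current set, with distance ties broken to
the lowest index. This is the classical greedy k-center heuristic, whose
covering radius is within a factor 2 of the optimal k-center radius; the
test suite verifies both the exact greedy trace against a brute-force
oracle and the 2-approximation bound against exhaustive optima. Events
are assigned to their nearest representative (no Lloyd refinement), giving
`k = 49` clusters by default. Clusters holding strictly less than
1/100,000 of the pooled events are discarded.

Kept representatives are merged by complete-linkage hierarchical
clustering (`stats::hclust`) cut at 15 meta-clusters; meta-clusters
holding strictly less than 0.5% of the pooled total are discarded.
Both filter denominators are the *original* pooled event count.

Meta-clusters are annotated from their median phenotyping profiles with a
fixed rule list (B cells, naive/memory CD4 T cells, CD8 T cells, NK
cells, classical monocytes, myeloid and plasmacytoid dendritic cells,
first match wins). A marker counts as "high" when the meta-cluster median
exceeds the midrange (midpoint of min and max) of the meta-cluster
medians for that marker. The midrange is used instead of the median of
medians because with few meta-clusters the median is itself one of the
compared values, which makes "above the median" degenerate; this choice
is a documented implementation decision.

```{r}
tr <- lapply(cl$tables, arcsinh_transform)
clustering <- cluster_cohort(tr, k = 30, seed = 1)
clustering$meta_model$annotations
```

## Feature extraction

For each individual and kept meta-cluster, three statistics of each of
the 9 functional markers are computed on arcsinh scale:

* `median_basal` — median in the basal sample;
* `q90_basal` — 90% quantile in the basal sample (type-7 quantile);
* `arcsinh_ratio` — median in the stimulated sample minus median in the
  basal sample (a fold-change on arcsinh scale).

Columns are ordered statistic-block first, then meta-cluster, then panel
marker order, so with 12 kept meta-clusters the `basal`, `ratio` and
`combined` models have exactly 216, 108 and 324 columns. Cells backed by
fewer than `min_cells = 10` events are masked, imputed with the cohort
median of the remaining individuals, and logged; the missingness mask is
part of the feature table.

## Classification

Individuals are classified RA-vs-HD with lasso-penalized logistic
regression under *double* leave-one-out cross-validation: the outer loop
holds out one individual; inside each outer training set an inner
leave-one-out loop selects the penalty `lambda` by held-out binomial
deviance over a 50-value log grid from `lambda_max` down to
`1e-3 * lambda_max`, recomputed per outer fold. Standardization and
imputation references are likewise recomputed inside each outer training
set, so the model scored on an individual never sees that individual
(the test suite checks this leakage contract bit-for-bit). Ties in inner
deviance go to the larger (sparser) `lambda`; the classification
threshold is 0.5; AUC is the rank statistic with ties counted one half.

The solver is a deterministic coordinate-descent IRLS path algorithm
(C++), with warm starts along the penalty path, a sequential strong rule
with full KKT verification, a `1e-5` floor on IRLS weights, and a
curvature-scaled convergence test (`x_j^2`-weighted squared step), which
keeps iteration counts bounded when weights saturate. The inner
cross-validation uses tolerance `1e-6` and final fits `1e-8`; solutions
match `glmnet` objectives to ~7 significant digits on test problems.
`final_nonzero_coefficients()` refits on the full cohort at a
full-cohort LOO-selected `lambda` and reports the surviving features.

```{r}
ft <- build_feature_table(tr, clustering, model = "combined")
cv <- double_loocv(ft)
cv$confusion
cv$auc
```

## Group comparisons

`compare_groups()` applies two-sided Mann-Whitney U tests to per-individual
meta-cluster summaries (median and 75% quantile of each functional marker,
per condition), reporting U, p and direction, sorted by p. P-values are
exact by network enumeration when `n1 * n2 <= 400` and the data are
tie-free, otherwise a normal approximation with tie and continuity
corrections is used. No multiplicity adjustment is applied by default
(the result records this; Benjamini-Hochberg values are available with
`adjust = TRUE`). `abundance_table()` reports per-sample and pooled
meta-cluster fractions.

## Problem sizes and limitations

Default parameters (`k = 49` clusters, 15 meta-clusters, the size-filter
thresholds, cofactor 5, `min_cells = 10`) target cohorts of tens of
individuals with 10^3–10^5 events per sample; all bundled experiments run
on one CPU. Known limitations:

* the annotation rules assume the default 12-marker phenotyping panel;
* the cleanup GMM assumes debris is separable on QC channels and always
  removes exactly one component;
* with small balanced cohorts, leave-one-out leaves the held-out
  individual's class under-represented in training, which biases
  chance-level accuracy estimates away from 50% for null data —
  a property of the LOO design itself, not of the solver;
* the FCS reader/writer supports the float-type FCS 3.1 subset the
  package writes, not the full standard.
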
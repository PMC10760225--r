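---
title: "Histomorphological phenotype learning: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Histomorphological phenotype learning: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hplkit)
library(dplyr)
```

`hplkit` implements a self-supervised workflow for prognosis from biopsy
whole-slide images (WSIs): tiles are embedded without labels, grouped into
*histomorphological phenotype clusters* (HPCs) by community detection, and
each patient is represented by the fraction of their tiles falling in each
cluster. Penalized linear models on those compositions predict binary outcome
and disease-free survival (DFS), and because every model is linear in
per-cluster abundances, predictions decompose exactly into per-phenotype
contributions. This vignette documents the models, the tunable parameters and
the design decisions; the README shows a worked end-to-end example.

## The pipeline stage by stage

### Tile preprocessing

Slides are rescaled to a target resolution (default 0.5 µm/px, the standard
20× working magnification) and cut into a non-overlapping, row-major grid of
square tiles (224 px at production scale). Rescaling uses exact area
averaging when shrinking and bilinear interpolation when enlarging, both
realized as interpolation weight matrices. A tile is rejected when background
covers more than 75% of it. "Background" is not specified more precisely in
most of the field's pipelines, so we fix a concrete rule: a pixel is
background when the minimum of its 3×3-mean-smoothed R, G, B values is at
least 220/255 — ordinary white-glass detection. The threshold and rule are
configurable (`preprocess_config()`).

Color variation across scanners and stains is compensated with Reinhard
color transfer: per-channel mean and standard deviation in the Ruderman
lαβ space (log-LMS decorrelated axes) are matched to target statistics. The
target defaults to the pooled statistics of the run's own kept tiles, so a
single-cohort run is centred on itself; for cross-cohort parity the target
can be frozen and passed in. Channels with zero spread receive only the mean
shift. The transform is idempotent up to clipping.

### Self-supervised embedding

Tile vectors are learned with the Barlow-Twins objective. Two stochastic
augmentations (crop-resize, horizontal flip, color jitter, gaussian blur) of
the same tile are embedded by the same network, embeddings are
batch-normalized per dimension, and the empirical cross-correlation matrix
$C_{ij} = \frac{1}{n}\sum_b \hat z^A_{bi}\,\hat z^B_{bj}$ is pushed toward
the identity:

$$\mathcal{L} = \sum_i (1 - C_{ii})^2 + \lambda \sum_{i \ne j} C_{ij}^2 .$$

The loss is zero exactly when $C = I$ and equals $4d$ on the diagonal term
for anti-correlated whitened views. The off-diagonal weight defaults to
$\lambda = 5 \times 10^{-3}$, the original Barlow-Twins setting. Training
uses 40% of tiles drawn per institution.

The backbone is deliberately modest — an area-averaged downsample of the tile
followed by a small fully-connected network with a linear projector, trained
by Adam in pure R — because the package's contract is only
*tile → z-dimensional vector* (z = 128 by default) and desk-scale tests must
run on a laptop CPU. Gradients of the loss (through the batch normalization)
are analytic and verified against finite differences in the test suite. For
experiments that should not depend on training stochasticity at all,
`cohort_embeddings()` bypasses the encoder and draws
ground-truth-structured Gaussian embeddings directly; clustering and all
downstream statistics are tested on both paths.

### Phenotype clustering

A k-nearest-neighbour graph (k = 50 by default, cosine metric — embeddings
are direction-coded) is clustered with the Leiden algorithm under the
resolution-parameterized modularity objective. Two passes mirror the
intended artifact workflow:

1. an **over-clustering pass** at high resolution (r = 7) yields many small,
   homogeneous clusters; clusters dominated by artifacts (air bubbles,
   out-of-focus regions — near-white tiles) are flagged and their tiles
   removed. At production scale the flagging is a visual call;
   `propose_artifact_clusters()` ranks clusters by mean tile luminance (and,
   on synthetic data, by ground-truth purity) to support it.
2. a **final pass** re-runs the kNN graph on the retained tiles (cleaner
   neighbourhoods than subsetting the old graph) over a grid of resolutions.

The working resolution is chosen from presence metrics: for each cluster, the
percentage of patients (institutions) with at least one tile — or at least 1%
of their own tiles — in it, averaged over clusters. When resolution grows past
the data's natural granularity, clusters become patient- or
institution-specific and these averages decline; `select_resolution()` takes
the largest resolution whose 1%-threshold patient presence is within 5
percentage points of the sweep maximum. On synthetic cohorts this lands
within ±2 of the planted phenotype count.

### Compositional representation

Each slide is represented by the proportions of its kept tiles per HPC; a
patient's slides are pooled at the tile level (a slide with three times the
tiles weighs three times as much), since the representation is defined as the
percentage of the patient's *tiles* per cluster. Slide-averaging is available
as an option. Because proportions live on the simplex, linear models consume
the centred log-ratio (CLR) transform
$\mathrm{clr}_k(x) = \log x_k - \tfrac1K \sum_j \log x_j$, which maps to a
zero-sum vector and is invariant to rescaling. Structural zeros are handled
by an additive pseudocount of one tile-count (1/`n_tiles`) before
renormalization; a fixed pseudocount (including 0, which errors on zeros) can
be passed instead.

### Outcome models

Three-fold cross-validation assigns each patient to a test set exactly once;
the remaining patients split 80/20 into training and validation. Splits are
rejection-sampled until each fold's train and test Kaplan-Meier curves differ
by at most 0.15 (maximum vertical gap at pooled event times), so folds carry
comparable survival profiles; after 200 attempts the best split found is
used, with a warning.

Both model families are elastic nets on the CLR features. We use
`alpha` = overall penalty strength and `l1_ratio` = L1 share (glmnet's
`lambda` and `alpha` respectively) — the binary good/poor model defaults to
penalty 0.25 with `l1_ratio` 0.5 (the source analysis reports only the tuned
penalty for this model; the L1 share is our documented default), and the Cox
DFS model to penalty 0.35 with `l1_ratio` 0.01. Penalties are scaled per
observation, so duplicating every row leaves coefficients unchanged. CLR
features are not re-standardized before fitting (CLR already centres each
sample); a standardization flag exists.

Discrimination is summarized by AUROC (logistic) and by Harrell's and Uno's
concordance (Cox). Uno's IPCW form is truncated by default at the largest
training-split event time. Risk stratification thresholds test patients at
the **median of the training hazard predictions** (lower-median convention
for even n) — fixed before any test outcome is seen, so the subsequent
log-rank test keeps its nominal level; this is verified empirically in the
acceptance suite (rejection rate 5% ± 2.5% under a null generator).
Per-coefficient significance uses Wald tests; since Wald tests on penalized
fits are ill-defined, the model is refit unpenalized on the active set
(|coef| > 1e-8) and p-values come from the observed information of the
refit. P-values are combined across folds with Fisher's method, and
coefficients are averaged across folds for reporting.

### Interpretation

For a linear predictor the Shapley value of feature *k* relative to a
background point is exactly $w_k (x_k - \bar x_k)$; `linear_shap()` uses the
per-fold training means as background, and additivity
(base + contributions = prediction) holds to machine precision.
`forest_summary()` reports per-cluster mean log hazard ratios,
Fisher-combined p-values and patient presence. Cluster enrichment against
external labels (diagnosis; local recurrence vs overall metastasis, where
nodal and distant metastases are grouped) uses Spearman rank correlation on
raw proportions (a CLR flag exists) with Benjamini-Hochberg correction at a
0.01 significance threshold.

Spatial structure is summarized by the tile-adjacency interaction matrix:
for every kept tile, the cluster labels of its existing grid neighbours are
tallied and aggregated per focal cluster, then column-normalized. The default
neighbourhood is 8-connected and same-cluster neighbours are counted (the
diagonal is retained, matching the visible diagonal structure of such plots);
4-connectivity and self-exclusion are flags. Heatmap exports colour one block
per tile, with blanks for rejected tiles, and are exactly decodable back to
the assignment.

## The synthetic cohort generator

No public WSI cohort accompanies this problem, so the generator is a
first-class, tested module that defines the study conditions:

* **Three institutions** with unequal sizes. The default sizes are the
  published post-exclusion counts (38 + 85 + 40 = 163 patients). The two
  (mutually inconsistent) published good/poor splits are exposed as
  `cohort_presets()` without resolving which is correct.
* **Multiple slides per patient for one institution only** (1–5, emulating
  the site that contributed several slides per lesion); the others contribute
  exactly one.
* **Planted phenotypes.** Each patient draws a composition over K = 8
  phenotypes from a Dirichlet(1, …, 1); each slide's tiles are multinomial in
  that composition, with a configurable fraction (default 0.1) replaced by an
  artifact phenotype.
* **Outcomes from a proportional-hazards model.** The event time is
  exponential with rate $\lambda_0 \exp(\beta^\top \mathrm{clr}(x))$ — the
  CLR covariate matches the downstream model family (raw proportions are a
  flag). Defaults: $\beta$ = (1.5, −1.5, 1, −1, 0.5, −0.5, 0, 0),
  $\lambda_0$ = 0.01/month, random censoring at 0.008/month, administrative
  censoring at 120 months — a strong, realistic DFS regime chosen once as the
  test bed. A patient is `poor` iff an event occurred; poor-outcome subtypes
  (LR vs NM/DM/DSD) are assigned by which planted driver phenotype dominates
  the composition, so subtype enrichment is recoverable by design.
* **Procedural tiles.** Rendered tiles are blob textures whose density,
  radius and palette are stable functions of the phenotype id — crude as
  histology, but sufficient that intensity statistics separate phenotypes,
  which is the property the encoder tests need. Artifact tiles render
  near-white with pale grey bubble blotches: bright enough to rank first by
  luminance, yet with enough sub-threshold pixels to survive the 75%
  background filter — if artifacts were plain white they would be discarded
  at preprocessing and the artifact-cluster pass would have nothing to do.
  Tiles default to 64 px in tests (224 px for production parity); all
  geometry is side-length agnostic.
* **Determinism.** One global seed; every entity (patient, tile, fold sweep)
  derives its own sub-stream by hashing the seed with stable labels, so
  identical configs reproduce byte-identical cohorts and changing one entity
  never reshuffles another.

What the generator does **not** emulate: realistic histology texture,
scanner noise, stain variability beyond what Reinhard normalization removes,
spatially correlated phenotype layouts within a slide (tiles are exchangeable
given the composition), or informative censoring. Passing tests therefore
demonstrate that the machinery recovers planted structure under the stated
model — not that the pipeline reaches any particular performance on real
slides.

## Numerical choices and degenerate inputs

* Batch normalization inside the loss uses population variance and **errors
  on zero-variance columns** (naming the column) rather than folding an
  epsilon into the scale, keeping the loss-zero identity exact.
* Leiden cluster ids are relabelled 0-based by decreasing size; isolated
  graph vertices become singleton clusters.
* Tiny validation splits can lack events or comparable pairs; cross-validation
  records `NA` for the affected metric with a warning instead of failing.
* A degenerate risk split (all test scores on one side of the threshold)
  yields groups with a warning and no log-rank test.
* Concordance requires at least one comparable pair; Uno weights error when
  the censoring survival is zero at a needed event time.
* `fisher_combine()` rejects p ≤ 0; BH passes `NA` through.

## Problem sizes used by the tests

The suite and the acceptance script are sized for a single CPU: clustering
recovery uses 4,000 embeddings (8 phenotypes + artifacts, 128-d), model
recovery a 300-patient cohort with 3-fold cross-validation, the null
calibration 200 replicates of 150-patient cohorts, and encoder sanity 2,000
rendered 64×64 tiles for 5 epochs. These sizes were chosen as the smallest at
which the Monte-Carlo tolerances quoted in the tests are statistically
meaningful.

## Known limitations

* The encoder is a toy by construction; no claim is made about parity with
  large-scale GPU training, and UMAP/PAGA visualizations are delegated to
  established implementations rather than reimplemented.
* Artifact identification at production scale remains a human decision; the
  luminance ranking is a proposal mechanism only.
* The elastic-net interpretation of the published single "alpha" for the
  logistic model (penalty strength, with L1 share 0.5) is an interpretation,
  flagged as such above.
* Survival modelling is single-event; competing risks and time-varying
  covariates are out of scope.
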
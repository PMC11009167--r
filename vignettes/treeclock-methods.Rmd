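---
title: "Cell lineage tree-shape clocks: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell lineage tree-shape clocks: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treeclock)
```

## The idea

Somatic single-nucleotide variants accumulate in dividing cells and are
inherited along the cell lineage, so they act as natural barcodes: the
pattern of shared variants among single cells from one blood sample encodes
a cell lineage tree. The central premise of this package is that the *shape*
of that tree — its depth, balance, spectral structure and tip-distance
distribution — carries information about the age of the person the cells
came from: mutation counts grow with lifetime divisions, and clonal
expansions (clonal hematopoiesis) make old trees more imbalanced than young
ones. `treeclock` turns that premise into a reproducible prediction
pipeline:

1. **Variant filtering.** Per-cell sparse alt/ref UMI count matrices are
   cleaned by removing common germline variants (minor allele frequency
   above 1% in a population VCF) and by two consecutive false-positive
   filters: a variant is *detected* in a cell only if at least 8 distinct
   UMIs support the alternative allele in that cell, and a variant is kept
   only if detected in at least 4 cells.
2. **Pseudo-alignments and pseudo-replicates.** Cells become rows of a
   three-state alignment (`A` detected, `R` reference seen, `?` missing);
   five partially overlapping random subsets of 700 of the ~1400 cells give
   five "partial trees" per sample, which quantify within-sample tree
   variability.
3. **Tree inference.** Pairwise p-distances (proportion of differing sites
   among pairwise-comparable ones) feed UPGMA, giving rooted ultrametric
   trees.
4. **Tree metrics.** Each tree is summarised by 31 named shape statistics in
   five groups (below).
5. **Age regression.** Chronological age is regressed on the 31 statistics,
   sex, and sex-by-statistic interactions (63 predictors) with an elastic
   net, evaluated by grouped nested leave-one-out cross-validation.

## The regression model

With samples $i = 1..N_s$, pseudo-replicates $j = 1..n_i$, predictors
$x_{ij}$ and ages $y_{ij}$ (identical for all replicates of a sample), the
fit solves

$$
\hat\mu,\hat\beta \;=\; \arg\min_{\mu,\beta}\;
\frac{1}{2N_{\mathrm{tot}}}\sum_{i}\sum_{j}
\bigl(y_{ij}-\mu-x_{ij}^{\top}\beta\bigr)^2
+\lambda\Bigl[\tfrac12(1-\alpha)\lVert\beta\rVert_2^2
+\alpha\lVert\beta\rVert_1\Bigr],
$$

a convex program for fixed regularization constant $\lambda$ and lasso
fraction $\alpha$. It is solved by cyclic coordinate descent in covariance
form ($X^\top X/N$ is precomputed per fold, so each coordinate update is
$O(p)$), with a compiled inner loop and convergence when the largest
coefficient change in a full pass drops below `tol = 1e-6`. Warm starts
across the hyperparameter grid make the nested scan cheap.

Hyperparameters are chosen from the exhaustive grid
$\lambda \in \{0.1, 0.3, 1, 3, 10\}$, $\alpha \in \{0.6, 0.7, 0.8, 0.9, 1\}$
by leave-one-*sample*-out cross-validation in the inner loop (lowest mean
absolute error over held-out replicates); the outer loop is also
leave-one-sample-out, so with 18 samples there are 18 outer and 17 inner
folds, every pseudo-replicate gets exactly one prediction, and each
coefficient is estimated once per outer fold. Pseudo-replicates of one
sample are never split across training and test.

Performance is reported as mean absolute error, median absolute error,
root-mean-squared error and Pearson correlation over all
(predicted, chronological) pairs. The *age difference* is
$\hat y - y$; the *age acceleration* is the residual of $\hat y$ from the
ordinary least-squares trend of $\hat y$ on $y$ — the customary correction
for the shrinkage bias of penalized clocks, whose fitted slope is below 1
(young ages overestimated, old ages underestimated).

### Design choices in the model layer

* **Standardization.** Penalized regression is scale-sensitive and the 31
  metrics have wildly different units, so by default every predictor column
  is z-scored (population SD) *on the training partition of each fold*; test
  rows are transformed with the training parameters. `standardize = FALSE`
  is exposed for sensitivity analyses.
* **Interactions.** Sex is coded F = 0, M = 1 and interaction columns are
  the raw products sex × statistic; since every column is subsequently
  standardized within each training fold, forming products before rather
  than after standardization only changes the column's internal scaling,
  which the fold-wise z-scoring absorbs.
* **Inner-loop scoring** averages absolute error over inner held-out
  replicates, equally weighted per replicate. Grid ties go to the first
  pair in grid order (lambda varying fastest).
* **Pre-selection.** A first nested CV ranks predictors by the mean
  absolute standardized coefficient across outer-fold estimates (ties broken
  by fixed column order); a second nested CV is rerun with only the top-k
  columns for each requested k, and the best k is reported by MAE. k is
  deliberately *not* tuned in the inner loop — it is an exploratory sweep,
  and the all-features model remains the default. Subsets preserve the
  original column order so k = 63 reproduces the default model bit for bit.
* **Dummy baseline** predicts the training-mean age in each leave-one-out
  fold, which is exactly the elastic net's infinite-shrinkage limit — a
  property the test suite checks literally.
* **Marker associations** use Pearson correlation with two-sided
  t-distribution p-values ($t = r\sqrt{(m-2)/(1-r^2)}$), flagged at
  p < 0.05 without multiple-testing correction, per stratum
  (All/Male/Female); strata with fewer than 3 complete pairs or constant
  markers are skipped with a note.

## The 31 tree metrics

All metrics are pure functions of a rooted tree with branch lengths,
invariant to tip relabeling and child-order rotation. Population (not
sample) variances and natural logarithms are used throughout. The root
edge, when present, is not part of the tree graph.

* **Group I — spectral (8).** Let $P$ be the patristic distance matrix over
  *all* vertices and $\mathrm{MGL} = \mathrm{diag}(\text{rowsums}(P)) - P$
  the distance ("modified graph") Laplacian, which is positive
  semi-definite. `mMaxEigen` is its largest eigenvalue; `mMax_eigengap` the
  largest difference between consecutive descending eigenvalues (a
  modality heuristic for division structure) and `eigengap_pos` its
  position; `spec_skewness`/`spec_kurtosis` are the spectrum's moments and
  `spec_entropy` the Shannon entropy of the spectrum normalized to sum one
  (with $0\log 0 \equiv 0$). `AC_2` is the algebraic connectivity (second
  smallest eigenvalue) of the *unweighted* graph Laplacian of the tree —
  a topology-only robustness measure — and `lmax_graph` the largest
  eigenvalue of the branch-length-weighted Laplacian
  ($W_{uv} = $ branch length, the simplest weighting convention).
* **Group II — branch lengths (7).** Total, mean, median, population
  variance, maximum, Shannon entropy of normalized lengths, and the
  internal/terminal length ratio (0, with a warning, when the terminal sum
  is zero — an infinity guard).
* **Group III — classical imbalance (8).** Normalized Colless
  ($\sum_{\text{internal}}|L-R|$ divided by $(n-1)(n-2)/2$), normalized
  Sackin (mean topological tip depth),
  cherries over $\lfloor n/2\rfloor$, the Pybus–Harvey gamma statistic,
  treeness (internal over total branch length), B1, B2, and maximum
  topological depth. Non-binary nodes are resolved arbitrarily with
  zero-length edges (warned). On non-ultrametric trees gamma is computed
  with the mean tip depth as the present — a documented convention, since
  gamma is classically defined for ultrametric trees only.
* **Group IV — tip distances (6).** Mean, population variance and maximum
  of tip–tip patristic distances; the mean normalized by total branch
  length (`tipDistNorm`, 0 when total length is 0); mean and population
  variance of root-to-tip distances (`tipRootPatr`, `tipRootPatr_var` —
  zero variance characterizes ultrametric trees).
* **Group V — powergraph (2).** Largest and second-smallest Laplacian
  eigenvalues of the square of the unweighted tree graph (vertices adjacent
  iff within 2 edges). Squaring adds edges, so `pg_AC2` is never below
  `AC_2` — a property the tests exercise.

Each metric is registered by name in `metric_catalog()`, so an alternate
definition can be swapped in without touching the model layer. Degenerate
inputs (zero total length, sub-minimum tip counts) produce defined
sentinels or errors, never NaN.

## Tree inference conventions

* **p-distance** uses pairwise deletion of `?` states by default (the
  "raw" model convention); complete deletion is available behind a flag.
  Cell pairs with no comparable sites get distance 0 plus a warning with
  the pair count — aborting would make sparse subsamples unusable.
* **UPGMA** merges the closest pair at height $d/2$ with size-weighted
  average linkage updates. Ties are broken by the smallest (row, column)
  index pair in the current label order, making trees reproducible across
  platforms; exact tree equality with other implementations' internal
  tie-breaking is not a goal. The implementation is a simple $O(n^2)$-scan
  agglomeration (clarity over speed; $n = 700$ is small). Output trees are
  ultrametric by construction, verified to $10^{-9}$ relative tolerance on
  every tree the tests produce.
* **Newick** writing uses 15 significant digits so branch lengths
  round-trip to $10^{-12}$; labels with characters outside `[A-Za-z0-9.-]`
  are single-quoted. Maximum-likelihood inference is out of scope, but the
  metric and model layers accept any Newick tree, so externally inferred
  trees can be dropped in.

## The cohort simulator

No generative model is prescribed by the method itself, so the simulator is
an artifact-level construction whose job is to produce inputs with the
statistical structure the method assumes — an age signal carried by tree
shape — at desk scale. Its defaults are chosen once and fixed.

A sample of age $a$ is grown as a discrete-generation birth process:
one founder divides for $G = \texttt{divisions\_base} +
\texttt{divisions\_per\_year}\cdot a$ generations (defaults 30 + 1/yr).
Each division drops $\mathrm{Poisson}(\mu_{\mathrm{div}})$ new variants
(default 0.3) onto one random daughter — infinite sites, no recurrence or
loss, so every variant's carrier set is exactly one clade's tip set, an
invariant the tests check exhaustively. The population is capped at four
times the target cell count by uniform survival resampling; with
probability $\texttt{clone\_rate\_per\_year}\cdot a$ (default 0.01/yr,
capped at 1) one lineage acquires a survival weight of
`clone_advantage` (default 2) from a uniformly chosen origin onward — the
discrete analogue of a division-rate advantage and the mechanism that makes
imbalance grow with age; at most one driver clone arises per sample, the
simplest mechanism that suffices. Finally `cells_per_sample` tips
(default 1400) are sampled uniformly and the genealogy is collapsed to a
binary tree whose branch lengths are mutation counts; founder-to-MRCA
mutations are kept as a root edge.

Observation noise is site- and cell-independent: each (cell, site) receives
$\mathrm{Poisson}(\texttt{depth\_mean})$ total UMIs (default 12), zeroed
with probability `dropout` (default 0.6); carriers' UMIs support the
alternative allele, non-carriers' the reference. There are no doublets, no
ambient contamination, no expression structure and no chemistry-specific
artifacts — enough to exercise the 8-UMI/4-barcode filters, not a model of
a sequencer. Defaults were set so that a full-size sample yields on the
order of $10^3$ variants surviving the filters.

Every random stream derives deterministically from one master seed, with
independent per-sample substreams: identical configurations reproduce
byte-identical cohorts, and changing one sample's stream leaves the others
untouched.

**What passing synthetic tests does and does not show.** The simulator
demonstrates that the pipeline is *correct* (filters, distances, trees,
metrics, model plumbing) and that it *can* recover an age signal of the
kind it assumes. It does not show that real blood trees carry such a
signal, nor calibrate error in years on real cohorts: real data add
expression-dependent coverage, cell-type structure, doublets, caller
artifacts and germline contamination that the simulator deliberately
omits.

## Problem sizes and numerical choices

The test-suite and acceptance-script cohorts use 30 samples with ages
uniform on 21–82, 300 cells per sample and 2 pseudo-replicates of 150
cells — the package's chosen desk-scale rendering of the full design
(~1400 cells, 5 × 700 replicates). At this scale the cross-validated clock
consistently beats the dummy baseline (MAE lower on every seed we ran) with
a predicted-on-chronological slope well below 1; the Pearson correlation
fluctuates around 0.35–0.7 across master seeds because trees built from a
few dozen filtered sites are noisy — at full scale, with an order of
magnitude more sites per tree, the tree estimates and hence the correlation
stabilize. Coordinate descent uses tolerance $10^{-6}$ (tests verify KKT
conditions to $10^{-5}$ and objective monotonicity); eigen-solvers are
dense symmetric (`eigen(symmetric = TRUE)`), adequate up to the ~1400
vertices of a 700-tip tree.

## Known limitations

* The 31-metric catalogue fixes one concrete, group-faithful set; the
  original supplement enumerating alternatives is not reproduced, and exact
  numerical replication of unpublished definitions is a non-goal.
* Whether the 8-UMI rule should count alt-supporting UMIs only or total
  site coverage is ambiguous; alt-supporting is implemented (configurable
  via `min_umis` at both filter and encoding).
* The eigengap can be read as a gap magnitude or a modality count; both are
  exposed (`mMax_eigengap`, `eigengap_pos`). `AC_2` is computed on the
  unweighted Laplacian; the weighted variant would require choosing a
  length-to-weight convention.
* Post-selection inference corrections are out of scope; the pre-selection
  sweep is exploratory.
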
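# treeclock

**Biological age prediction from the shape of somatic-mutation cell lineage
trees.**

Somatic single-nucleotide variants (SNVs) accumulate in dividing cells and
are inherited along the cell lineage — natural barcodes that let a
phylogeny of single cells be reconstructed from single-cell RNA-seq variant
calls. `treeclock` is built on the hypothesis that the *shape* of such a
cell tree (depth, balance, spectral structure, tip-distance distribution)
measures biological age: lifetime divisions deepen the tree, and age-related
clonal expansions unbalance it. The package is aimed at computational
biologists working on aging clocks, somatic-mutation lineage tracing, or
clonal hematopoiesis who want a self-contained, testable rendering of the
whole chain.

## What it does

Starting from per-cell sparse alternative/reference UMI count matrices
(scSNV/Cell Ranger-style MTX + annotations), the pipeline:

1. removes likely germline variants (minor allele frequency > 1% in a
   population VCF) and applies two consecutive false-positive filters —
   a variant must be backed by **≥ 8 alt UMIs within a cell** to count as
   detected, and detected in **≥ 4 cells** to survive;
2. encodes cells as three-state pseudo-alignments (`A` detected / `R`
   reference / `?` missing) and draws partially overlapping
   pseudo-replicate subsets (5 × 700 cells of ~1400 by default);
3. infers rooted **ultrametric UPGMA trees from p-distances** (pairwise
   deletion of missing states);
4. computes a catalogue of **31 tree-shape metrics** in five groups —
   distance-Laplacian spectra (`mMaxEigen`, `mMax_eigengap`, ...), branch
   length statistics, classical imbalance indices (Colless, Sackin,
   cherries, gamma, B1, B2), tip-distance summaries (`tipDistNorm`,
   `tipRootPatr`, ...) and powergraph Laplacian features;
5. fits the **elastic net age regression**

   minimize over (mu, beta):
   `1/(2 N_tot) * sum_ij (y_ij - mu - x_ij' beta)^2
      + lambda * ( (1-alpha)/2 * ||beta||_2^2 + alpha * ||beta||_1 )`

   on 63 predictors (31 metrics + sex + 31 sex-interactions), with
   **grouped nested leave-one-out cross-validation** (a sample's
   pseudo-replicates are never split across train/test), exhaustive
   (lambda, alpha) grid search in the inner loop, feature pre-selection,
   a dummy-regressor baseline, external-cohort testing, age
   difference / age acceleration, and clinical-marker association tables.

A built-in **cohort simulator** (discrete-generation birth process,
infinite-sites mutations, age-scaled division counts, age-increasing driver
clones, Poisson UMI depth with dropout) generates fully synthetic cohorts
so that everything above runs and is tested without any sequencing data.

## Worked example

```r
library(treeclock)

cfg <- sim_config(n_samples = 18, cells_per_sample = 300,
                  age_range = c(21, 82), seed = 42)
cohort <- simulate_cohort(cfg)

features <- dplyr::bind_rows(lapply(seq_len(18), function(i) {
  filt <- filter_variants(cohort$matrices[[i]])        # >=8 UMIs, >=4 cells
  aln  <- encode_alignment(filt)
  reps <- subsample_pseudoreplicates(aln, n_reps = 2, cells_per_rep = 150,
                                     seed = 100 + i)
  trees <- infer_sample_trees(reps)                    # p-distance + UPGMA
  compute_feature_table(trees, sample_id = cohort$metadata$sample_id[i])
}))

design <- build_design(features, cohort$metadata)      # 63 predictors
cv <- nested_cv(design)                                # grouped nested LOOCV
glance(cv)
#> # A tibble: 1 × 7
#>     mae  mdae  rmse     r    r2     n r_defined
#>   <dbl> <dbl> <dbl> <dbl> <dbl> <int> <lgl>
#> 1  12.6  10.6  15.6 0.583 0.340    36 TRUE

glance(dummy_baseline(design))
#> # A tibble: 1 × 7
#>     mae  mdae  rmse     r    r2     n r_defined
#>   <dbl> <dbl> <dbl> <dbl> <dbl> <int> <lgl>
#> 1  15.3  16.1  17.9    -1     1    36 TRUE

aa <- age_acceleration(cv)
attr(aa, "slope")
#> [1] 0.566
```

Reading the output: the cross-validated clock predicts age with a mean
absolute error of 12.6 years versus 15.3 for the covariate-free dummy
baseline, and Pearson r = 0.58 between predicted and chronological age over
the 36 pseudo-replicates. (The dummy's r = −1 is the leave-one-out
artifact: its prediction is the mean of the *other* samples' ages, a
perfectly decreasing function of one's own age.) The slope of predicted on
chronological age is 0.57 < 1 — the regularization-induced compression that
`age_acceleration()` corrects by taking residuals from this trend line.

`autoplot(cv)` draws predicted-vs-chronological age (replicate dots, sample
means as crosses, y = x reference); `tidy(cv)` returns the per-fold
coefficient estimates. `run_pipeline(pipeline_config(...))` executes the
whole chain from one YAML-serializable config with per-stage caching and a
reproducibility manifest, and `inst/scripts/ctr.R` exposes the stages as a
small command line (`run`, `simulate`, `filter`, `metrics`, `fit`).

At this reduced scale (hundreds of cells, tens of filtered variant sites
per tree) performance is seed-sensitive; see the methods vignette
(`vignettes/treeclock-methods.Rmd`) for the model, all conventions, and
what synthetic results do and do not demonstrate.

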
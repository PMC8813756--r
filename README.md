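# placentamix

Benchmarking reference-based against reference-free cell-type
deconvolution of bulk placental DNA-methylation data.

Bulk placental methylation is a mixture over six cell types
(trophoblasts, stromal cells, Hofbauer cells, endothelial cells,
nucleated red blood cells, syncytiotrophoblasts) whose proportions vary
across samples, sampling sites and gestation. Epigenome-wide analyses
must correct for this, and two estimator families compete:

* **Reference-based (robust partial correlation).** For each sample,
  the marker-CpG beta vector `y` is fitted on the reference matrix `R`
  (marker CpG × cell type) by robust IRLS with Huber weights
  (c = 1.345, MAD scale), no intercept; negative coefficients are
  truncated and the rest rescaled so that `Σ_k p_k = 1`. A non-negative
  least-squares variant (`min ‖y − Rp‖² s.t. p ≥ 0`, then normalised)
  serves as the non-robust oracle.
* **Reference-free.** The beta matrix `B` (CpG × sample) is factorized
  as `B ≈ M Ωᵀ` with latent methylomes `M ∈ [0,1]` and per-sample
  proportions `Ω` on the unit simplex, by alternating constrained least
  squares with a provably non-increasing objective; the component count
  `K` is selected by a cross-fitted bootstrap deviance.

Because cohort-scale methylation data are rarely shareable, the package
ships a synthetic-cohort generator with known ground truth: Dirichlet
compositions around published study means (concentration 150),
gestational-age trends moved between trophoblasts and
syncytiotrophoblasts, marker CpGs with ≥ 0.5 cell-type separation, a
trimodal background beta landscape, and beta-scale noise. Around these
sit the full comparison pipeline: non-variable CpG filtering
(10th–90th percentile range < 5%), marker-CpG exclusion, SVD principal
components with 3×IQR outlier fences, a repeated 10-fold
cross-validation comparison of six linear models for PC1 (win counting,
RMSE with percentile CIs, winner's adjusted R²), per-CpG adjusted-R²
decomposition, and nonparametric composition statistics (Spearman
associations with Bonferroni control, paired signed-rank tests, relative
effects, and a permutation global rank-based multivariate test).

## Worked example

```r
library(placentamix)

cfg <- cohort_config(n_samples = 50, n_cpgs = 650, n_markers = 600,
                     study_preset = "CVS-ITU", seed = 1)
co  <- generate_cohort(cfg)
dc  <- deconvolve_cohort(co$betas, co$reference, method = "rpc")
dc
#> Reference-based deconvolution (rpc), 50 samples x 6 cell types, 600 markers
#> mean composition:
#>         Trophoblasts              Stromal             Hofbauer
#>               0.2636               0.1665               0.0027
#>          Endothelial                 nRBC Syncytiotrophoblasts
#>               0.0028               0.0039               0.5604
mean(abs(dc$proportions - co$true_proportions))
#> [1] 0.002605878
```

The estimated mean composition reproduces the first-trimester preset
(trophoblasts ≈ 0.26, syncytiotrophoblasts ≈ 0.57) and the mean absolute
error against the known truth is ≈ 0.003 at noise sd 0.02 — each
sample's six proportions always sum to exactly 1.

A paired first-trimester → term design shows the expected composition
shifts with their test statistics (medians in percentage points,
positive Z = larger at the first time point):

```r
pp <- generate_paired_proportions(n_pairs = 85, seed = 1)
paired_celltype_tests(pp$t1, pp$t2)
#> Paired signed-rank comparison (85 pairs, alpha = 0.01)
#>             cell_type median_t1 median_t2 median_difference     Z ...
#>          Trophoblasts     26.19      1.02            -25.18  8.01
#>               Stromal     17.27      0.00            -17.27  8.01
#>  Syncytiotrophoblasts     56.30     94.00             37.71 -8.01
#>  ...
```

The end-to-end pipeline (`run_benchmark(benchmark_config())`) simulates
four study cohorts, applies the full filtering/PCA/deconvolution/CV
sequence deterministically, and writes a JSON report plus per-stage CSV
artifacts.

## Package layout

* `R/synthetic-cohort.R` — cohort generator, study presets, paired design
* `R/deconv-reference.R` — robust and NNLS reference-based estimators
* `R/deconv-reference-free.R` — constrained factorization, K selection
* `R/filtering.R` — variability filter, PCA, outlier fences, correlation screen
* `R/model-selection.R` — six-model repeated CV, adjusted R², per-CpG R²
* `R/composition-stats.R` — rank-based composition statistics
* `R/pipeline.R`, `R/io.R` — end-to-end benchmark and validated I/O
* `vignettes/deconvolution-benchmark.Rmd` — the methods vignette
* `inst/scripts/placentamix-cli.R` — thin command-line wrapper
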
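# protflow

Headless, scriptable quality control and preliminary analysis for
mass-spectrometry proteomics and interactomics data.

After protein identification and quantification (FragPipe, DIA-NN, or any
tool that emits a proteins × samples matrix), the same routine questions come
first: did every run work, how much is missing, do replicates agree, which
proteins change between groups, and — for AP-MS experiments — which bait–prey
pairs rise above the background of non-specific binders. `protflow` packages
those steps as composable R functions, a batch pipeline with machine-readable
success/failure markers, and deterministic synthetic-data generators so the
entire system can be exercised and tested without any external download. It
is aimed at proteomics core facilities and analysts who want the first pass
over a dataset to be automatic, reproducible and scriptable.

## What it computes

**QC metrics** (for every dataset): per-sample identification counts and
missing-value percentages, per-protein identification coverage, pairwise
shared identifications with Jaccard indices, commonly identified proteins,
per-group coefficients of variation (CV = s/x̄ on raw-scale values), and
per-sample intensity summaries.

**Proteomics workflow**: consistency filtering (a protein is kept iff it is
observed in at least a fraction *f* — default ⅔ — of the samples of at least
one group), optional median or quantile normalization, left-censored
imputation (QRILC-style by default: per sample, the sorted observed log₂
values are regressed on standard-normal quantiles at plotting positions
*m* + (1−*m*)(i−½)/n, the fit giving μ̂ and σ̂ of the uncensored
distribution, and each missing cell is drawn from N(μ̂, σ̂) truncated above
at its *m*-quantile), PCA and average-linkage clustering on 1 − r (Pearson),
and differential abundance: per protein, log₂FC = x̄₁ − x̄₂ of log₂ values,
Welch's unequal-variance t-test, Benjamini–Hochberg adjustment, and volcano
classes *up*/*down*/*not significant* at |log₂FC| ≥ 1 and adjusted p ≤ 0.01
(defaults, inclusive boundaries).

**Interactomics workflow**: SAINTexpress input writing / output parsing,
CRAPome-style fold-change scores against control runs
(FC-A = (bait mean + c)/(all-controls mean + c); FC-B uses the top-k
controls; c = 0.1), high-confidence filtering on BFDR / FC-A / control
frequency, known-interaction mapping, MS-microscopy localization profiles
(marker-set aggregation rescaled so the top compartment reads 100), offline
hypergeometric enrichment with BH correction, and network export as
edge/node tables.

**MS inspector**: per-run total-ion-chromatogram metrics (trapezoidal AUC,
mean and maximum intensity) presented as an acquisition-time series with
relative drift against the series median.

**Colocalizer**: per-z-slice colocalization maps from multi-channel TIFF
stacks, combining channels by product or sum with linear or log scaling,
min–max rescaled to [0, 1].

## Worked example

```r
library(protflow)

sim <- generate_proteomics(n_proteins = 500, seed = 42)   # 2 groups x 4 reps
aligned <- align_samples(
  remove_contaminants(sim$matrix, read_contaminants(bundled_contaminant_file()))$matrix,
  sim$samples
)
aligned$matrix
#> <abundance_matrix> 490 proteins x 8 samples (intensity, linear scale)

identification_counts(aligned$matrix)
#> # A tibble: 8 × 2
#>   sample_id n_identified
#>   <chr>            <dbl>
#> 1 group1_R1          459
#> 2 group1_R2          453
#> # ...

filtered <- filter_by_consistency(aligned$matrix, aligned$samples)$matrix
imputed  <- impute_qrilc(filtered, seed = 42)$matrix
results  <- differential_abundance(
  imputed, aligned$samples,
  tibble::tibble(test_group = "group2", control_group = "group1")
) |> classify_volcano()

glance(results)
#> # A tibble: 1 × 5
#>   comparison       n_proteins  n_up n_down min_p_adj
#>   <chr>                 <int> <int>  <int>     <dbl>
#> 1 group2 vs group1        476    10     13  0.000220

dplyr::arrange(results, p_adj)[, c("protein_id", "log2fc", "p_adj", "volcano_class")]
#> # A tibble: 476 × 4
#>   protein_id log2fc    p_adj volcano_class
#> 1 PROT00179   -2.03 0.000220 down
#> 2 PROT00080    1.87 0.000725 up
#> 3 PROT00158   -1.89 0.000725 down
#> # ...
```

Ten contaminant-list proteins were removed before analysis, 476 of 500
proteins survived the two-thirds consistency filter, and at the default
volcano thresholds 23 proteins are called differential — the generator
planted 50 effects of 2 log₂ units, and the ones it misses are mostly proteins with
an imputed low-tail replicate (see the methods vignette for why that costs
sensitivity).

The same analysis runs end to end from a shell:

```sh
Rscript exec/protflow pipeline --config pipeline.json --out results_dir
# results_dir/ gains QC tables, intermediate matrices, differential results,
# parameter_record.json, and pipeline.success (or pipeline.failure naming
# the failed stage).
```

`plot_volcano()`, `plot_missing_values()`, `autoplot()` on a PCA fit,
`plot_ms_microscopy()` and friends give ggplot2 views of each result.

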
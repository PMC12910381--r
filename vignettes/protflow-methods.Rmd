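---
title: "Methods and design notes for protflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for protflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protflow)
```

`protflow` automates the first pass over quantified MS proteomics data:
quality control, preliminary whole-proteome analysis, and AP-MS interactor
filtering, plus chromatogram run-series metrics and image colocalization
maps. This vignette documents the models and conventions behind each step,
the parameters that matter, and the design choices made where more than one
reasonable convention exists.

## Input model

The central container is a proteins × samples table of strictly positive
quantifications with explicit missingness. Zeros in any input are converted
to missing values on ingest: in both spectral-count and label-free-intensity
conventions a zero encodes "not detected", not "abundance zero", and folding
the two into one representation makes every missing-value metric well
defined. Input dialects are autodetected from header signatures —
`Protein.Group` + `Run` columns mean a DIA-NN-style long report (pivoted to
wide, duplicate protein–run pairs aggregated by maximum, which is
order-independent and idempotent); per-sample `<sample> Intensity` /
`<sample> Spectral Count` columns mean a FragPipe-style combined report (a
file carrying both families yields a parallel intensity/count matrix pair);
anything else is treated as a generic matrix whose first column is the
protein id. Delimiters (tab, comma, semicolon) are sniffed from the header
row.

Contaminant removal happens before any other processing, matching on the
primary accession (the token before the first `;` in a protein-group id),
because protein groups commonly carry secondary accessions. A small bundled
list of common contaminants (keratins, trypsin, serum albumins, caseins) is
used when no list is supplied.

## QC metrics

Identification counts, missing-value percentages, per-protein coverage,
pairwise overlap/Jaccard, commonly identified proteins, per-group CVs and
intensity summaries are all computed on the *ingested* data, before
filtering or normalization, so they describe what the instrument and sample
preparation delivered. Conventions worth stating:

* CV is computed on raw-scale (unlogged) values with the n−1 standard
  deviation, per protein within each group, requiring at least two observed
  values; CV is conventionally a raw-scale statistic and log-scale CVs are
  not comparable across instruments.
* Quantiles use the linear-interpolation convention (R type 7), stated here
  so exported numbers are reproducible elsewhere.
* "Commonly identified proteins" is operationalized as a threshold on the
  detection fraction, default 1.0 (present in every sample). A top-N
  definition would also have been defensible; the threshold form is monotone
  and easier to reason about.
* Jaccard similarity of two samples with empty detection sets is defined as
  1 (they are identical as sets); the overlap diagonal equals the
  identification count.

## Proteomics workflow

### Consistency filtering

A protein is retained iff some group contains it in at least
`min_group_fraction` of its samples, with threshold `ceil(f · n_g)` and an
inclusive comparison, so with the default f = ⅔ a protein seen in 2 of 3
samples passes and 1 of 3 fails. The rule is deliberately per-group ("at
least one group"): a protein cleanly present in the treatment group and
absent from controls is biology, not noise. Lowering f never drops a
previously retained protein (monotonicity is property-tested).

### Normalization

Off by default: label-free intensities from modern search engines are
usually already normalized (e.g. MaxLFQ), and re-normalizing can erase real
global shifts. Two options are provided. Median normalization rescales each
sample's observed values so all sample medians equal the global median of
observed values. Quantile normalization is the classic rank/mean procedure
(ties averaged, samples with unequal observed counts mapped through
interpolated reference quantiles), delegated to `limma::normalizeQuantiles`;
an independent brute-force implementation of the same definition is used as
the oracle in the test suite. Variance-stabilizing normalization and
random-forest imputation are recognised option names that raise a clear
"not implemented" error rather than silently substituting a different
method.

### Left-censored imputation

Intensity missingness in label-free data is predominantly left-censored:
values disappear because they fall below the detection limit. The default
imputation models each sample's log₂ values as Normal and treats the missing
fraction *m* as the censored low tail. The sorted observed values are
regressed on standard-normal quantiles at plotting positions
`m + (1−m)(i−½)/n_obs` — the positions the observed order statistics occupy
*given* that the lowest m-fraction is unobserved — using the lower half of
the observed points (the tail nearest the censoring limit, least affected by
high-abundance skew). The intercept and slope of that fit estimate μ and σ
of the uncensored distribution, and each missing cell is drawn from
N(μ̂, σ̂) truncated above at its m-quantile, via inverse-CDF sampling of
U(0, m). Draws are deterministic given the seed (`withr::with_seed`, so the
user's RNG state is untouched). σ̂ is floored at 10⁻⁶ against degenerate
fits, and each sample must have at least 4 observed values — fewer indicates
filtering was too weak for imputation to be meaningful.

On simulated censored Normal(20, 1) samples with 20% censoring the
combined observed-plus-imputed mean recovers the generating mean to well
within 0.15 log₂ units (averaged over 100 seeds; the acceptance suite
recomputes this). Two properties worth understanding:

* Imputed values are guaranteed to fall below the *fitted* m-quantile. The
  realized observed minimum fluctuates around its own fitted position just
  above that bound, so occasionally a draw exceeds the observed minimum;
  empirically ~97% of imputed values land below it.
* The fit pools all proteins of a sample, so σ̂ reflects protein-to-protein
  spread (~2 log₂ units in typical data). A sporadically missing cell of a
  mid-abundance protein is therefore imputed far below that protein's other
  replicates. This is inherent to sample-wise left-censored imputation, and
  it costs differential-abundance sensitivity: any protein with one imputed
  replicate gains a large within-group variance and will usually be missed
  by a t-test at a strict adjusted-p threshold. On the synthetic conditions
  below, sensitivity is ≈0.5 with realistic intensity-dependent missingness
  and ≈0.77 even with purely random 2% missingness, while the
  false-discovery proportion stays far below the nominal level. Users who
  care about sensitivity for sporadically missing proteins should consider
  the group-mean imputation option, at the cost of anti-conservative
  variance estimates.

Alternatives provided: downshifted-normal imputation
(N(x̄ − 1.8·s, (0.3·s)²) per sample, the convention popularized by
spreadsheet-style proteomics tools), and group-mean imputation (missing cell
← mean of the protein's observed log₂ values in the sample's group; cells in
all-missing groups stay missing and the protein is flagged).

Ordering: normalization, then imputation, so imputation operates on values
in their final scale.

### PCA, clustering, differential abundance

PCA treats samples as observations and proteins as variables, mean-centered
but not scaled (protein variance carries information), with scores from the
SVD; variance-explained fractions are the squared singular values over their
sum. Clustering is average-linkage agglomeration on 1 − Pearson correlation
between samples; a zero-variance sample would make the correlation
undefined, so such pairs get correlation 0 with a warning. Both are checked
against brute-force eigendecomposition / naive agglomeration oracles in the
tests; the dendrogram is exported as Newick.

Differential abundance uses Welch's unequal-variance two-sample t-test on
imputed log₂ values — no test is canonical for this step, and Welch is the
robust default when group variances differ (as imputation guarantees they
sometimes will). The log₂ fold change is the difference of group means of
log₂ values, which for complete unnormalized data equals the log₂ ratio of
geometric means. Zero-variance groups get a variance floor of 10⁻⁹ on each
side so the statistic stays defined; affected proteins are flagged. p-values
are Benjamini–Hochberg adjusted within each comparison independently
(pooling across comparisons would make one contrast's p-values depend on
which other contrasts were requested). Volcano classes use inclusive
boundaries: up iff log₂FC ≥ +1 and adjusted p ≤ 0.01, down iff log₂FC ≤ −1
and adjusted p ≤ 0.01 (defaults; both configurable). Moderated-variance
(limma-style) testing is deliberately out of scope — the aim is the routine
first pass, not the best attainable power.

## Interactomics workflow

SAINTexpress is treated as an external component: the package writes its
three input files bit-exactly (tab-separated, headerless; controls flagged
`C`; zero-count pairs omitted; unknown prey lengths default to 100) and
parses its `list` output (`Bait`, `Prey`, `AvgP`, `BFDR` consumed, extra
columns ignored, scores validated to [0, 1]); it does not re-derive the
probabilistic model.

Fold-change scores follow the contaminant-repository convention: for each
bait–prey pair, FC-A = (mean bait count + 0.1)/(mean over all control runs
+ 0.1) and FC-B uses the mean of the top-3 highest control counts, so
FC-B ≤ FC-A always. The pseudocount keeps ratios finite for preys absent
from controls and is the score's resolution limit: a prey absent from all
controls with mean bait count 10 scores FC-A = 101. The high-confidence
filter passes a record iff FC-A ≥ 3, control frequency ≤ 0.5, and — only
when SAINT scores are present — BFDR ≤ 0.05; with no SAINT file the filter
is fold-change-only. Tightening any threshold can only shrink the passed
set (property-tested). Thresholds used are recorded in the run's parameter
record.

Known-interaction mapping is undirected (a pair matches in either order).
MS-microscopy profiles aggregate the average bait counts of passed preys
over compartment marker sets and rescale each bait's row so its strongest
compartment reads 100 (all-zero when nothing overlaps); the original
method's exact marker weighting is not reproduced — this is the transparent
set-sum variant, invariant to rescaling a bait's counts. Enrichment is a
local hypergeometric upper-tail test against a user-supplied annotation
table and background universe with BH correction — an offline, reproducible
replacement for web-service enrichment calls, which are out of scope along
with live interaction-database queries. Networks are exported as edge and
node tables (nodes flagged bait/prey/both) for any graph tool; no
renderer is embedded.

## Chromatogram run series

Chromatograms arrive as one JSON document per run (`run_id`, `file_name`,
ISO-8601 `acquisition_time`, `time_points` in minutes strictly increasing,
`tic` non-negative, free-form `metadata`) — the schema is validated with
field-level errors. Vendor raw-file parsing is out of scope; the documents
are the interchange format. Metrics are the trapezoidal AUC over (time,
TIC), the arithmetic mean and the maximum intensity; the run-series table
orders runs by acquisition time (ties by run id) and adds each metric
divided by its series median, a unitless drift ratio in which slow decay
across a sample series is immediately visible. Ion-mobility data are not
used.

## Colocalization maps

Multi-channel z-stacks are read from multi-page TIFF with a declared page
order (`zc`: channel fastest, or `cz`), the in-memory convention being a
(z, channel, y, x) array. The map for one z-slice combines two or more
channel planes elementwise by product (pixels bright in *every* channel) or
sum (union of signal), optionally compresses dynamic range with log(1+v),
and min–max rescales the final map to [0, 1]; a constant map becomes all
zeros. Normalization is applied to the combined map, not per channel, since
scaling is a display decision about the final image. More than two channels
are combined jointly in one reduction. Pearson/Manders coefficients and
segmentation are out of scope.

## Pipeline mode and reproducibility

A pipeline definition is a JSON or YAML document (`workflow`, `data_file`,
`sample_table_file`, `seed`, `options`); unknown workflow names and unknown
option keys are rejected with the valid-key list and a closest-match
suggestion. TOML was considered for the definition grammar; JSON/YAML were
chosen because both have first-class R parsers and round-trip cleanly.
Interactomics definitions must designate controls (an `is_control` column or
a `control_group` option) — control runs are what every fold-change score is
measured against.

`run_pipeline()` never lets an error escape: each stage runs under a
handler, and the output directory always ends with exactly one marker —
zero-length `pipeline.success`, or `pipeline.failure` naming the failing
stage and the error. Partial outputs are kept for debugging. The parameter
record written with every run lists *all* resolved options (defaults
included), the seed, and software versions, and is itself a valid pipeline
definition: pointing the runner at a previous run's record reproduces the
bundle byte-for-byte (timestamps live only in the run log, which is excluded
from that guarantee). All randomness (imputation) is seeded, so identical
inputs + seed give identical outputs. Directory watching and HTTP serving
are deployment plumbing, out of scope; the single-shot runner and the CLI
(`exec/protflow`) are the automation surface.

## Synthetic data and what the tests do (and do not) show

The generators produce every input the workflows consume, with ground truth:

* **Proteomics**: protein log₂ baselines ~ N(20, 2), replicate noise
  N(0, 0.25), a `de_fraction` (default 0.1) of proteins shifted ±2 log₂
  units in the last group; missingness = 2% completely-at-random plus
  intensity-dependent censoring whose probability rises logistically
  (scale 0.5 log₂ units) as a value falls below the 10th percentile of all
  values, saturating at `mnar_strength` (default 0.5 — near the detection
  limit roughly half of would-be observations drop out, giving ~8–10%
  overall missingness, typical of label-free data); 2% of proteins are
  relabeled with bundled contaminant accessions.
* **Interactomics**: true preys ~ NegBin(mean 10, dispersion 0.5) in their
  own bait's runs and absent elsewhere; background preys ~ NegBin(mean 5)
  everywhere, each forced present in ≥80% of control runs — the regime in
  which control-frequency and fold-change filters are informative. Negative
  binomial is the standard overdispersed model for spectral counts.
* **Chromatograms**: five shared Gaussian peaks plus baseline over a
  60-minute gradient, run i scaled by (1 − drift·i/n) with 1% lognormal
  amplitude noise, hourly timestamps; the expected last/first AUC ratio
  (1−drift)/(1−drift/n) is attached for closed-form checks.
* **Fixture tables**: marker/known-interaction/annotation tables consistent
  with the interactomics truth, and a 2×3-channel 64×64 stack with a planted
  colocalizing blob.

All generators are pure functions of (parameters, seed). What they do *not*
emulate: correlated missingness across samples, batch effects, retention-time
structure in quantification, charge-state artifacts, or shared peptides
between protein groups. Passing tests on this data demonstrates the
algorithms implement their definitions and recover planted structure under
the stated model — not that the defaults are optimal for any particular real
dataset.

Problem sizes used by the test and acceptance suites — 1000 proteins ×
(4 vs 4) over 20 seeds (50 for the null), 100 censored-normal samples of
size 100, 20 interactomics datasets of ~240 preys, oracle checks on ~100
random instances of ≤ 20×10 — were chosen to make every recovery estimate
stable to well within its decision margin while keeping a full run in the
order of seconds to a couple of minutes.

## Known limitations

* Sample-wise left-censored imputation penalizes sensitivity for proteins
  with sporadic (random) missingness, as quantified above; a
  protein-wise or hybrid imputation is the natural extension.
* The two-sample test is unmoderated; very small group sizes would benefit
  from empirical-Bayes variance shrinkage.
* FC-A/FC-B scoring assumes control runs are exchangeable with bait runs in
  depth; strongly unbalanced designs should normalize counts first.
* The MS-microscopy score is a marker-set sum, not the original weighted
  profile; compartments with many markers are favoured accordingly.
* QC metrics are not recomputed after normalization/imputation; they
  describe the data as submitted.
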
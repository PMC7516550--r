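# ceemdx

Epileptic-seizure detection in EEG recordings by **complementary ensemble
empirical mode decomposition (CEEMD)** and **gradient-boosted trees
(XGBoost)**, for researchers working on automated seizure detection who
want a fully inspectable, reproducible pipeline in R.

## What it does

A windowed EEG series $x(n)$ is decomposed into intrinsic mode functions
plus a residue,

$$x(n) = \sum_{j=1}^{M} \mathrm{IMF}_j(n) + R(n),$$

by running EMD on complementary pairs of white-noise-perturbed copies
$x \pm w_k$ and averaging the modes, which suppresses mode mixing without
leaving residual noise. From the raw series and every component the package
extracts a multi-domain feature catalogue — time, frequency,
time-frequency, and six entropy estimators (permutation, Shannon, spectral,
approximate, sample, and SVD entropy) — then prunes features by normalized
XGBoost gain importance (threshold 0.001) and evaluates the classifier with
stratified 10-fold cross-validation:

$$\mathrm{SEN} = \frac{TP}{TP+FN},\quad
  \mathrm{SPE} = \frac{TN}{TN+FP},\quad
  \mathrm{ACC} = \frac{TP+TN}{TP+TN+FP+FN},$$

each reported in percent with per-fold dispersion.

The EMD/EEMD/CEEMD machinery (extrema detection, mirrored cubic-spline
envelopes, sifting, noise-pair ensembles) and all entropy estimators are
implemented in the package; boosting is delegated to `xgboost`. A seeded
synthetic EEG generator (pink-noise background with alpha-band oscillation
vs. high-amplitude 3–5 Hz spike-wave trains) makes the entire pipeline
testable without clinical data. Readers for Bonn-style plain-text segments
and standard 16-bit EDF recordings (with sliding-window segmentation
against seizure-annotation sidecars) connect the pipeline to the public
EEG corpora.

## Worked example

```r
library(ceemdx)

# 100 seizure + 100 non-seizure synthetic 3-second segments at 256 Hz
config <- pipeline_config(
  synth = list(n_per_class = 100, seed = 7),
  decompose = list(method = "ceemd", n_pairs = 10L, seed = 7L),
  evaluate = list(k = 10L, seed = 1L)
)
result <- run_pipeline(config, out_dir = "benchmark-run")
result$cv
#> <seizure_cv: 10-fold stratified cross-validation (6.1 s)>
#>   SEN: 99.00 +/- 3.16
#>   SPE: 100.00 +/- 0.00
#>   ACC: 99.50 +/- 1.58
```

Mean sensitivity 99.00% means that across folds, 99% of held-out seizure
segments were recognized; specificity 100% means no background segment was
flagged. `top_features(result$ranking, 20)` lists the 20 most important
features with their component (raw / IMF_j / residue) and domain, and
`benchmark-run/` holds the feature table, importance ranking, JSON/text
reports, and the fully resolved configuration (package version, config
hash, seeds).

Individual stages are plain functions on tibbles and signals:

```r
sig <- read_bonn_segment("Z001.txt")        # 4097 samples @ 173.61 Hz
dec <- ceemd(as.vector(sig$samples), decompose_config(n_pairs = 10))
length(dec$imfs)
#> [1] 12
features <- extract_all(dec, sig)           # one row, 14 component blocks
```

A thin command-line interface with `synth`, `segment`, `decompose`,
`extract`, `train`, `evaluate` and `run` subcommands ships in
`inst/cli/ceemdx.R`.

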
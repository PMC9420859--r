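# moonsvm

Classification of **moonlighting proteins** — proteins that perform two or
more autonomous functions not explained by separate domains or splice
variants — from primary sequence alone. The package is aimed at
computational biologists who want an interpretable, fully reproducible
classical pipeline: sequence feature encoders, a closed-form supervised
projection, and a bagged linear-SVM ensemble, with a seeded synthetic data
generator so every stage runs and is testable without any database
download.

## What is inside

**Feature encoders** (pure functions of the sequence / profile):

* `pseaac()` — pseudo-amino-acid composition. The 20 residue frequencies
  f_i plus sequence-order correlation factors
  θ_k = (1/(L−k)) Σ_i [H(R_i) − H(R_{i+k})]², built from nine standardized
  physicochemical scales, weighted by ω (default 0.05) and normalized so
  Σ x_i = 1. Default layout: 9 scales × 5 tiers → a 65-D vector.
* `svmprot188()` — the SVMProt-188D descriptor: amino-acid composition
  (20) plus, for each of 8 physicochemical attributes, a
  composition/transition/distribution block (3 + 3 + 15), total 188.
* `psepssm()` — pseudo-PSSM: for a row-standardized PSI-BLAST profile,
  the 20 column means Ē_j and the 20 lag-ξ correlations
  G_j = (1/(L−ξ)) Σ_i [E_{i,j} − E_{i+ξ,j}]² (ξ = 1 → 40-D).

**Model** (fit per cross-validation fold, leakage-free):

* `fit_lda()` — two-class Fisher discriminant in closed form,
  w* = S_W⁻¹(μ0 − μ1) with unnormalized scatter matrices, a trace-scaled
  ridge for singular S_W, and a fixed orientation (class-1 mean projects
  higher). Used as a 1-D supervised projection.
* `train_svm()` / `train_bagging()` — linear soft-margin SVM (C = 1) and
  a bootstrap-aggregated ensemble (10 members by default) combined by
  majority vote; ties resolve by the sign of the mean decision score.
* `cross_validate()` — seeded stratified k-fold CV reporting ACC (%),
  precision, recall, F-score and exact rank-based AUC per fold and
  averaged; `comparison_grid()` sweeps feature sets × baseline learners
  (KNN/DT/MLP/RF/XGBoost/SVM) × LDA on/off on identical folds.

**I/O and data**: FASTA reading/writing with explicit nonstandard-residue
policies, a PSI-BLAST ASCII PSSM parser, label/feature-matrix TSV
round-trips, and seeded generators for labeled synthetic sequences and
sequence-consistent PSSM profiles (`generate_sequences()`,
`generate_pssm()`).

## Worked example

```r
library(moonsvm)

# two sequence classes differing in hydrophobic-group composition
recs <- generate_sequences(100, 100, c(50, 300), bias = 0.5, seed = 1)
X    <- encode_features(recs, "svmprot188")     # 200 x 188 matrix
cv   <- cross_validate(X, recs$label, k = 10, seed = 1)
cv
#> 10-fold cross-validation (seed 1)
#> mean ACC 98.5000%  Precision 0.991  Recall 0.980  F-score 0.985  AUC 1.000
head(round(cv$folds, 3), 3)
#>   fold n_test ACC Precision Recall F_score AUC
#> 1    1     20  95         1    0.9   0.947   1
#> 2    2     20  95         1    0.9   0.947   1
#> 3    3     20 100         1    1.0   1.000   1
```

The mean row says the full pipeline (per-fold z-scoring → Fisher LDA
projection to 1-D → 10-member bagging-SVM) recovers the planted
composition difference almost perfectly: 98.5% of held-out sequences are
labeled correctly, with precision/recall near 1 and a perfect ranking
(AUC 1.0). With `bias = 0` the same pipeline sits at chance (~50%),
confirming there is no leakage between training and test folds.

A thin command-line interface wraps the same functions
(`inst/cli/moonsvm.R`, subcommands `synth`, `extract`, `train`,
`predict`, `crossval`); run it with `Rscript` and `--help`-style usage is
printed on any malformed invocation.

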
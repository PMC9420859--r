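---
title: "Classifying moonlighting proteins from sequence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying moonlighting proteins from sequence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moonsvm)
```

## The problem

Moonlighting proteins (MPs) perform two or more autonomous biological
functions that do not arise from separate domains, splice variants or gene
fusions. Because a moonlighting function is rarely annotated and expensive
to establish experimentally, sequence-based classifiers are used to
prioritise candidates. `moonsvm` implements such a classifier as a chain of
interpretable classical components: sequence-derived feature encoders, a
supervised one-dimensional Fisher discriminant projection, and a bagged
ensemble of linear support vector machines, evaluated under stratified
k-fold cross-validation. The reference use case is a two-class benchmark
of 268 MPs versus 162 single-function proteins, which is why the synthetic
generator defaults to those class sizes.

## Feature encoders

**Amino-acid composition (AAC).** The 20 residue frequencies
$F_i = N_i / L$, the basis of both richer encoders.

**Pseudo-amino-acid composition (Pse-AAC, 65-D default).** AAC discards
residue order. Pse-AAC appends sequence-order correlation factors: for a
standardized property scale $H$ the tier-$k$ factor is

$$\theta_k \;=\; \frac{1}{L-k} \sum_{i=1}^{L-k} \bigl[H(R_i) - H(R_{i+k})\bigr]^2 ,$$

and the full vector is $x_i = f_i / (\sum_j f_j + \omega \sum_k \theta_k)$
for the 20 composition slots and
$x_{20+k} = \omega\,\theta_k / (\sum_j f_j + \omega \sum_k \theta_k)$ for
the pseudo slots, so the vector is non-negative and sums to one. The
squared-difference correlation kernel is the canonical choice in the
Pse-AAC literature and degenerates correctly for homopolymers (all
$\theta_k = 0$).

Two layout decisions were genuinely open and are worth recording:

* *Per-scale series.* The default configuration uses nine property scales
  (hydrophilicity, hydropathy, residue mass, pK1, pK2, pI, rigidity,
  flexibility, irreplaceability) with five tiers each, concatenated scale
  by scale: $20 + 9 \times 5 = 65$ components. A pooled mode (one series
  averaging over all scales, the classic single-$\lambda$ form) is also
  available via `pseaac_config(mode = "pooled")`.
* *Scale values are parameters, not algorithm.* The packaged table
  (`inst/extdata/pseaac_scales.tsv`) uses widely published indices —
  Hopp–Woods, Kyte–Doolittle, monoisotopic masses, free-amino-acid
  pK1/pK2/pI, a negated side-chain conformational entropy as rigidity, the
  Bhaskaran–Ponnuswamy flexibility index, and the BLOSUM62
  self-substitution score as an evolutionary irreplaceability proxy. Every
  scale is standardized to zero mean and unit (population) variance over
  the 20 residues before use, so any affine re-expression of an index
  leaves the encoder unchanged; users can supply their own table in the
  same TSV layout.

**SVMProt-188D.** Twenty AAC components plus, for each of eight
physicochemical attributes (hydrophobicity, normalized van der Waals
volume, polarity, polarizability, charge, secondary-structure propensity,
solvent accessibility, surface tension), a 21-component
composition/transition/distribution (CTD) block:

* composition — the three group frequencies (sum to 1);
* transition — for each unordered group pair, the count of adjacent
  residues whose groups differ, divided by $L-1$;
* distribution — for each group, the sequence positions of its first,
  25%, 50%, 75% and last occurrence (occurrence index
  $\lceil q \cdot n_g \rceil$, 1-based), each divided by $L$; an absent
  group contributes five zeros.

The grouping table is a hard partition: every attribute's three residue
sets are disjoint and cover the alphabet, a property asserted every time
the table is loaded. The packaged polarizability row places cysteine in
the medium group (`CPNVEQIL`); printed variants of this table sometimes
duplicate glycine there, which violates the partition invariant and is
corrected in the shipped file.

**Pse-PSSM (40-D).** Consumes a PSI-BLAST ASCII position-specific scoring
matrix (profile *generation* is out of scope; the reader accepts the
standard `-out_ascii_pssm` dialect and re-orders columns alphabetically).
Each profile row is standardized by its mean and root-mean-square
deviation (an all-constant row maps to zeros — "no information" rather
than a division by zero), then the encoder emits the 20 column means
$\bar E_j$ and the 20 lag-$\xi$ correlations
$G_j^{\xi} = \frac{1}{L-\xi}\sum_i [E_{i,j} - E_{i+\xi,j}]^2$. The default
$\xi = 1$ is the only value consistent with a 40-component output.

## Dimensionality reduction: Fisher LDA

With class means $\mu_0, \mu_1$ and the unnormalized within-class scatter
$S_W = \sum_j \sum_{x \in X_j} (x-\mu_j)(x-\mu_j)^{\top}$, the direction
maximizing between- over within-class scatter is
$w^* = S_W^{-1}(\mu_0 - \mu_1)$. `fit_lda()` implements exactly this
closed form and uses it purely as a supervised projection to one
dimension — no Gaussian classification model is attached. Numerical
choices:

* **Ridge.** In cross-validation folds of a 188-D encoding $S_W$ can be
  ill-conditioned or singular. The solve is therefore
  $(S_W + \lambda I) w = \mu_0 - \mu_1$ with the default
  $\lambda = 10^{-6}\,\mathrm{tr}(S_W)/d$; an exactly singular system at
  $\lambda = 0$ is an error naming the remedy.
* **Orientation.** The closed form leaves the sign free; $w$ is oriented
  so the class-1 (MP) mean projects higher, making projections
  reproducible.
* **Standardization.** Columns are z-scored before the scatter
  computation by default (the 188-D blocks mix frequencies and positional
  fractions of very different spread); centers and scales are estimated
  from the training data only and stored in the model, so per-fold
  fitting is leakage-free. Fitting LDA inside each fold is the default
  protocol; fitting once on all data remains possible by projecting
  before `cross_validate()` but is leakage-prone and not the shipped
  path.

## Classifier: linear SVM and bagging

The base learner is a soft-margin SVM with a linear kernel and penalty
$C = 1$ (the convention for this feature family; the quadratic program is
delegated to `e1071::svm`, and the fitted separator is reduced to its
explicit weight/bias form for serialization). The ensemble draws
`n_members = 10` bootstrap samples of the training set (fraction 1.0,
with replacement, one seeded substream per member; a draw that misses a
class is redrawn), trains one member per sample, and aggregates by hard
majority vote. Even-split ties fall back to the sign of the mean decision
score, which uses the available margin information instead of an
arbitrary class preference; the mean decision score is also the
ranking score used for AUC, being finer-grained than the vote fraction.
Ensemble size and bootstrap fraction are conventional bagging defaults
and are recorded in every report. No class weighting is applied by
default despite the 268/162 imbalance, matching the reference protocol.

## Evaluation

Metrics derive from confusion counts with MP as the positive class:
accuracy (reported in percent), precision, recall, F-score, and AUC
computed exactly as the Mann–Whitney statistic (ties count one half).
Zero-denominator conventions: precision and recall are defined as 0 when
their denominators vanish, and F is 0 whenever either is 0.
Cross-validation is stratified and seeded: per-class shuffling deals
samples so fold sizes differ by at most one and per-fold class
proportions deviate from the global ones by at most one sample. Reported
summary values are unweighted means over folds, not pooled confusion
counts. `comparison_grid()` evaluates feature sets against pluggable
baseline learners (KNN, decision tree, MLP, random forest, XGBoost, and
the package's SVM) on identical fold assignments, with LDA on/off as a
grid axis; an unavailable learner marks its cells skipped rather than
aborting the run.

## The synthetic generator — what it emulates, and what it does not

`generate_sequences()` draws two classes of i.i.d. residues differing in
the probability of the hydrophobic group `CVLIMFW`
($\tfrac12 \pm \mathrm{bias}/2$, uniform within the group, other residues
uniform), with lengths uniform on a configurable range (default 50–300,
a realistic span for globular proteins) and default class sizes 268/162
mirroring the benchmark composition. The signal is planted deliberately
in a grouping the 188-D encoder measures, so a working pipeline must
recover it: bias 0 gives exchangeable classes (chance-level accuracy),
bias 0.5 gives nearly separable ones. `generate_pssm()` emits profiles
with a +4 self-substitution score, −1 elsewhere, plus integer-rounded
Gaussian noise — the qualitative shape of a real log-odds profile.

What the generator does *not* emulate: residue autocorrelation, domain
structure, compositional drift with length, evolutionary profile
structure beyond self-substitution, and the subtle physicochemical
differences between real MPs and non-MPs. Passing tests on synthetic
data therefore demonstrate that the machinery is correct and leakage-free
— not that the measured accuracies transfer to real benchmark sequences.

## Problem sizes and determinism

The shipped tests and the reproduction script use 400 samples (200/200)
for the no-signal condition, 200 (100/100) for the separable condition,
10-fold cross-validation and 10-member ensembles — sizes at which every
stage of the pipeline is exercised with stable statistics. All
randomness (sequence draws, profile noise, fold assignment, bootstrap
resampling) flows from named substreams of a single integer seed, and
each seeded path is byte-reproducible run to run.

## Known limitations

* Only binary classification is supported; the Fisher projection as
  implemented is inherently two-class.
* The Pse-AAC scale values are replaceable defaults; results on real data
  should be reported together with the scale table used.
* The PSSM reader expects the PSI-BLAST ASCII dialect; other profile
  formats must be converted first.
* Bagging with very small minority classes can fail to draw two-class
  bootstrap samples; the error message identifies the condition.
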
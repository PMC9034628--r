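---
title: "Methods: subtype-specific gene selection and the CMS network classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subtype-specific gene selection and the CMS network classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmsnet)
```

## The problem

Colorectal tumours fall into four transcriptome-defined consensus molecular
subtypes: CMS1 (microsatellite-instability immune), CMS2 (canonical), CMS3
(metabolic) and CMS4 (mesenchymal). Given a genes-by-samples expression
matrix on the log2 scale and CMS labels for the training samples, `cmsnet`
builds a classifier in two stages: it first reduces the transcriptome to
*subtype-specific genes* by pairwise differential expression, then trains a
small feed-forward network on those genes. Everything downstream of raw data
— the test statistics, the network's forward and backward passes, the
optimiser — is implemented explicitly in the package and verified against
independent oracles in the test suite.

## Stage 1: pairwise differential expression

The four subtypes give six ordered pairs (CMS1 vs CMS2, CMS1 vs CMS3, …,
CMS3 vs CMS4). For each pair and each gene we compute:

* **log2 fold-change.** The package convention is that stored expression is
  already log2-scale (the microarray convention; `log_scale = FALSE` at load
  applies `log2(x + 1)`). On log2 data the log2 fold-change is the
  difference of group means — equivalently the log2 ratio of *geometric*
  means on the linear scale. A literal ratio of arithmetic means is only
  meaningful on linear intensities and is available via
  `log2_fold_change(..., log_scale = FALSE)`.
* **Welch t statistic.** `t = (Ā − B̄) / sqrt(S²_A/n_A + S²_B/n_B)` with
  sample variances and Welch–Satterthwaite degrees of freedom, two-sided p
  values. The unpooled form is used because real CMS cohorts are unbalanced
  (CMS2 is typically twice the size of CMS1/CMS3); with equal group sizes it
  reduces to the common equal-n formula. Zero-variance genes follow explicit
  conventions (`t = 0, p = 1` when means agree; `p = 0` with a warning when
  they differ) rather than being dropped silently.
* **Q value.** Benjamini–Hochberg step-up FDR adjustment, applied within
  each pair comparison across genes (a pooled mode across all six
  comparisons is available; per-pair is the default because each comparison
  is reported as its own family).

A gene is *subtype-specific* for a pair when `|log2FC| > 1` (a two-fold
change) and `Q < 0.05`. The final gene set is the union over the six pairs
with a fully deterministic order: pairs in the fixed order above, genes
sorted lexicographically within a pair, first occurrence kept. That ordering
is what makes retraining reproducible — it fixes the network's input layout.

## Stage 2: the network

The classifier is deliberately minimal: input (one unit per selected gene) →
768-unit ReLU representation layer → 128-unit ReLU representation layer →
4-unit softmax. Each layer computes `alpha(W x − theta)` with a per-unit
threshold `theta`. Two devices control overfitting:

* **Dropout** on the outputs of the two representation layers only (never on
  the input). Masks are Bernoulli with keep probability `p = 0.5` by
  default, stored with *inverted scaling* (surviving entries are `1/p`), so
  the masked activation is an unbiased estimate of the unmasked one and
  evaluation needs no rescaling.
* **L1 + L2 penalties** on `W1` and `W2` only; the output layer is never
  penalised. The total loss is
  `mean cross-entropy + l1 · (‖W1‖₁ + ‖W2‖₁) + (l2/2) · (‖W1‖²_F + ‖W2‖²_F)`.
  Cross-entropy is the standard negative log-likelihood of the true class,
  with probabilities clipped at 1e-12 so a confidently wrong prediction
  stays finite.

The backward pass is analytic. At the output, the softmax Jacobian is
`y_t(1 − y_t)` on the diagonal and `−y_t y_k` off it; combined with the
log-likelihood this collapses to the familiar `(probs − onehot)/n` error
signal, so the weight row of the true class is reinforced and the others
penalised. Hidden gradients propagate through the ReLU derivative and the
*same* dropout masks used in the forward pass; the L1 subgradient at exactly
zero is 0. The gradient check in the test suite (central finite differences
with frozen masks, every tensor, relative error < 1e-5) is the central
correctness test of the module.

Optimisation is mini-batch Adam (defaults `alpha = 1e-3`, `beta1 = 0.9`,
`beta2 = 0.999`, `eps = 1e-8`) with bias-corrected moments, verified
step-for-step against an independent reference implementation. The learning
rate is reduced tenfold after 10 epochs without improvement of the full-data
training loss, floored at 1e-5; training stops early after 20 flat epochs
or at `max_epochs` (200 by default). Initialisation is He-uniform for the
ReLU layers and Glorot-uniform for the output; all randomness
(initialisation, shuffling, dropout) derives from the single `seed` in
`train_config()`, making training bit-reproducible.

### Standardisation and cross-platform use

Inputs are z-scored per gene. The statistics are fit on the training data
and stored in the model bundle; prediction reuses them by default
(`standardize = "stored"`), which is correct for samples from the same
platform. For an independent cohort from a different platform,
`standardize = "cohort"` re-fits the per-gene statistics on the incoming
cohort; since cross-platform differences on the log2 scale are approximately
affine (location/scale), cohort z-scoring removes them exactly. On the
synthetic benchmark the stored-statistics route also tolerates a moderate
affine shift (+0.5 location, ×1.2 scale) with no measurable accuracy loss,
because the planted class separation is much larger than the induced input
perturbation; with weaker signal the cohort mode is the safer choice.

### A note on the penalty scale

The penalties are *sums* over weights while the data term is a *mean* over
samples. With ~2×10⁵ hidden weights, coefficients of 0.1–0.9 make the L1
subgradient (constant per weight) dominate every data gradient and drive the
network to the uniform output — training collapses to chance. On the
desk-scale synthetic benchmark the network learns cleanly for coefficients
up to ~0.01, and the cross-validation experiments in this package therefore
use `l1_coef = l2_coef = 0.001`. The package default remains 0.3, the
operating point reported for the method on full-transcriptome cohorts, but
users should expect to scale the coefficient down in proportion to the
penalty mass of their configuration; `regularizer_scan()` automates the
comparison on shared folds. A consequence worth stating plainly: on the
synthetic benchmark the accuracy-vs-coefficient curve over {0.1, …, 0.9} is
flat at chance level, so the "largest coefficient does no better than the
optimum" trend holds degenerately there.

## Evaluation

`confusion_counts()` produces one-vs-rest TP/TN/FP/FN per class;
`classification_metrics()` turns them into per-class and macro-averaged
sensitivity, specificity, precision (all percent), plus two accuracy
conventions that both appear in practice: overall accuracy (fraction of
correct predictions) and macro per-class accuracy (mean of one-vs-rest
`(TP+TN)/n`). A per-class ratio with a zero denominator (e.g. precision of
a never-predicted class) is excluded from the macro mean and counted in
`n_undefined`, rather than scored 0 — scoring it 0 would reward predictors
that simply avoid a class.

`cross_validate()` uses stratified folds (per-class sizes differ by at most
one) because the small CMS1/CMS3 classes would otherwise vanish from folds.
The default `per_fold` selection policy re-runs gene selection and
standardisation inside each training fold, so no test information leaks into
the features; the `global` policy (select once on the full data) is exposed
because published workflows often do this, and the output records which was
used. `holdout_split()` gives the stratified 9:1 protocol (512 samples →
460/52 up to per-class rounding).

`distance_correlation()` implements the Székely–Rizzo statistic from
doubly-centred Euclidean distance matrices, checked against a brute-force
double loop. Two cohorts of different sizes are compared through
`dataset_distance_correlation()`, which reduces each to its per-gene mean
profile over the shared genes — a stated convention, since gene-wise
profiles are the only objects the two cohorts share.

`top_weight_genes()` ranks genes by `|W1[neuron, gene]|` (ties broken by
gene id) for the first 10 layer-1 neurons, 100 genes each by default — the
first step of weight-based interpretability, producing lists ready for
external enrichment tools.

## The synthetic generator

`simulation_config()` describes a four-class log2-scale cohort: background
genes `Normal(baseline_mean, noise_sd)` in all classes, and for each of the
six subtype pairs a planted set of genes whose mean in the pair's first
class is shifted by `± effect_size` relative to the second (sign drawn per
gene and recorded in the truth table). Defaults — 60 samples per class,
2,000 genes, 50 planted genes per pair, `effect_size = 2`, `noise_sd = 0.5`,
baseline 7 — are the benchmark conditions used throughout the tests: the
sample and gene counts sit at the lower end of real colorectal microarray
series, a 2-log2-unit shift against 0.5 SD is a strong but realistic
marker-gene effect, and baseline 7 is a typical log2 intensity. Passing a
previous `truth` to `simulate_dataset()` regenerates an independent
replicate of the *same* population (same planted genes, fresh noise), which
is what train/test experiments need; a fresh seed alone would plant
different genes. `apply_platform_shift()` adds an affine location/scale
distortion (defaults +0.5, ×1.2 — a moderate between-platform difference on
the log2 scale).

What the generator deliberately does not emulate: heavy-tailed or count
(RNA-seq) noise, probe effects, batch structure beyond the affine shift,
correlated co-expression modules, and genes informative for more than one
pair (a config choice keeps planted genes disjoint so selector precision and
recall are unambiguous). Tests passing on this generator therefore
demonstrate the machinery — selection calibration, optimisation, evaluation
plumbing — not clinical performance on real cohorts, where effect sizes are
smaller, correlated and contaminated by technical structure.

## Numerical choices and degenerate inputs

* Softmax is computed with per-column max subtraction; probabilities are
  clipped at 1e-12 inside the loss only.
* Zero-variance genes standardise with scale 1 (to a constant) instead of
  dividing by zero.
* BH is applied to each pair's p vector with stable tie handling; the
  step-up running minimum is capped at 1.
* Pairs whose classes have fewer than 2 samples are skipped with a single
  consolidated warning; selection fails only when fewer than two classes
  remain usable.
* Distance correlation of a constant input is defined as 0 and flagged
  `degenerate`.
* Fold seeds in `cross_validate()` are derived as `seed + fold`, so the
  whole procedure is a pure function of its `seed` argument.

## Problem sizes used in the shipped experiments

The test-suite and acceptance experiments run at the generator defaults
(240 samples × 2,000 genes, ~300 selected genes feeding the full 768/128/4
network), with 10-fold cross-validation and a reduced penalty grid
{0.1, 0.3, 0.9}; optimisation-heavy unit tests use narrower hidden layers
(e.g. 32/16), which exercise identical code paths. These sizes were chosen
so the complete pipeline, including its determinism re-run, executes in
minutes on a single CPU while keeping every statistical property of the
full-size configuration.

## Known limitations

* The loss/penalty scale mismatch discussed above means the method's
  published operating point (coefficient 0.3) is not directly usable with
  mean cross-entropy at realistic widths; users must rescale.
* Macro metrics with excluded undefined classes change their effective
  denominator; `n_undefined` should be reported alongside.
* The gene-level input assumption (symbols, log2 intensities) is not
  checked against annotation; probe-level data must be collapsed upstream.
* `standardize = "cohort"` requires enough samples (and comparable class
  mix) for stable per-gene statistics; for single-sample prediction only
  the stored mode is available.
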
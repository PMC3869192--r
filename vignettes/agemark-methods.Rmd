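---
title: "Methods: age-discriminative feature selection for gut metagenome functional profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-discriminative feature selection for gut metagenome functional profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agemark)
```

## The problem

Human gut metagenomes can be summarized as functional profiles: for each
sample, the number of distinct non-redundant proteins assigned to each
functional feature — a Pfam family, a KEGG pathway or ortholog, or a GO
term. These counts measure the *diversity* of proteins within a family, not
gene expression. Such tables are wide (thousands of features), sparse
(roughly half the entries are zero in real cohorts), and confounded by
host factors such as country of origin. The question agemark addresses is
whether host age — a continuous, fuzzy variable — leaves a recoverable
signature in these profiles, operationalized as a binary classification
task: can a classifier trained on samples labeled *young* (age at or below
a cutoff) versus *old* (above it) rank new samples correctly, and at which
cutoffs does it do best?

## The pipeline

The pipeline is: (1) choose an age cutoff and label the cohort; (2) select
a small number of features on training data only; (3) fit a linear
soft-margin SVM on the selected features; (4) score a held-out sample;
(5) repeat under leave-one-out cross-validation over repeated random
subsets, reporting mean AUC with a 95% t-interval; (6) sweep the cutoff
across the age axis.

### TF-iDF

For feature $i$ in sample $j$,

$$\mathrm{TFiDF}_{ij} = \frac{n_{ij}}{\sum_k n_{kj}}
  \,\log\frac{|D|}{|\{j : n_{ij} > 0\}|},$$

the product of the feature's within-sample share and the log of cohort size
over the number of carrying samples. The weighting is label-blind and
favours *accessory* features: high frequency within a few samples, absent
from most. A feature present in every sample weighs zero, as does one
present in none.

Two choices the formula leaves open:

* **Log base.** Natural log. The base multiplies every weight by the same
  constant and cannot reorder features; it is exposed as `log_base`.
* **Per-feature aggregation.** The formula scores (feature, sample) pairs,
  but a ranking needs one score per feature. The default is the maximum
  weight over training samples, which directly expresses the accessory
  regime ("high frequency of occurrence in few metagenomes"); sum
  aggregation is available via `aggregate = "sum"`.

TF-iDF is always recomputed inside each cross-validation fold on training
samples only.

### mRMR

Minimum-redundancy maximum-relevance selection first discretizes each
feature column to $\{-1, 0, +1\}$ around its training mean at $t = 1$
standard deviation (the conventional default), then greedily selects
features: the first maximizes the mutual information $I(x_i; c)$ with the
young/old class vector, and each later step maximizes the *difference*
criterion

$$I(x_i; c) - \frac{1}{|S|}\sum_{x_j \in S} I(x_i; x_j),$$

relevance minus mean redundancy with the already-selected set $S$. The
quotient combination is available via `combination = "quotient"`; the
difference form is the default of the widely distributed reference
implementation and is what we use. Mutual information is the plug-in
estimate from the empirical contingency table, in bits. Ties at any step
break lexicographically, so a selection path is fully deterministic. The
per-step running relevance $D(S, c)$ and redundancy $R(S)$ (mean over all
ordered pairs of selected features, self-pairs included) are recorded in
the ranking's `trace` attribute.

### Grubbs-weighted selection

A control selector that isolates pure outlier-hunting: each feature's
abundance vector is Grubbs-tested (two-sided, $\alpha = 0.05$, single
non-iterative test, sample standard deviation); for each sample flagged by
some feature set, an SVM trained on the remaining samples restricted to
that set classifies it, and the features earn weight 1 when the
classification is correct; the top-weighted features are returned. Its
purpose is comparative: if TF-iDF's advantage came only from picking rare
features, this selector would match it — in practice it hovers at chance,
which is exactly the qualitative contrast the acceptance suite checks.

### Classification and evaluation

The classifier is a linear-kernel soft-margin SVM with $C = 1$ (the solver
is libsvm via e1071; the primal weight vector and intercept are extracted,
and the decision orientation is fixed so that a positive score always means
*old*, which keeps AUC well-defined across folds). Features are not scaled
by default — the zero pattern of sparse abundance profiles is part of the
signal — though per-fold z-scoring with training statistics is available
behind `scale = TRUE`.

AUC is computed in its Mann-Whitney form (ties half-credited) on the pooled
held-out scores of a run; pooling within a run and averaging across runs is
our reading of "mean and confidence interval of these measurements", with
the 95% interval taken as $\bar a \pm t_{0.975, n-1} s/\sqrt{n}$ across the
`n_runs` random subsets.

Pooled leave-one-out scores carry a known pessimistic bias: removing a
sample from the training set tilts the fitted model slightly against that
sample's class, so on label-permuted data the pooled AUC sits
systematically below 0.5 (we measured ~0.45, dipping below 0.40 at
strongly imbalanced cutoffs). agemark therefore centres each held-out
score by the mean decision score of its fold's training samples before
pooling — fold scores become comparable and the null is calibrated at 0.5
— while predicted labels still come from the uncentred model sign. Raw
pooling is available with `center_scores = FALSE`.

One further numerical note: with raw counts of magnitude $10^2$–$10^3$
and $C = 1$, the libsvm dual is effectively hard-margin and converges very
slowly on non-separable (e.g. permuted-label) folds. The bundled
acceptance study therefore runs the pipeline with the per-fold z-scoring
flag on; the package default remains unscaled. Subsets are simple uniform draws without
replacement — no stratification by age or country, matching the source
design. All randomness flows from one master seed through hashed child
seeds (per cutoff, per run), so any report is reproducible bit for bit and
no result depends on evaluation order.

## The synthetic-cohort generator

Real cohorts at this scale are not redistributable, so the generator
emulates their statistical structure and plants known signal for recovery
testing:

* **Background**: each of ~50% of feature slots is present per sample
  i.i.d. (presence 0.5), with counts drawn as negative binomial
  (mean 10, size 1) plus one — over-dispersed, as real functional tables
  are.
* **Sample-unique features**: exactly 15% of features occur in a single
  sample each, mirroring the observed fraction of Pfams unique to one
  metagenome.
* **Country batch effect**: each country multiplies a private random 10%
  of background features by 2 — visible in ordination, orthogonal to age
  by construction (planted features are excluded).
* **Ages**: either approximately uniform over 22–87 (the age-balanced
  design; the default, because every mid-age cutoff then has two usable
  classes) or skewed with ~85% of hosts over 40 (the large single-study
  design), in decade blocks.
* **Planted effects** at a chosen cutoff: *prevalence shifts* present in
  55% of the young and 11% of the old (the magnitude reported for the
  vitamin-B12 family CbiN), and *accessory bursts* present in a random 30%
  of the young only at 50x abundance. The default mix is five of each.
  Burst parameters are not pinned down by any published number; 30%
  coverage was chosen so that five bursts jointly cover ~83% of the young
  class, making the planted partition strongly rather than marginally
  recoverable — the regime the recovery tests are meant to certify. The
  two kinds deliberately target different selectors: bursts are the
  TF-iDF regime, prevalence shifts the mRMR regime.

What the generator does **not** emulate: phylogenetic correlation between
features, compositional closure, sequencing-depth variation, or graded
(non-step) age effects. Passing recovery tests therefore certifies the
pipeline's machinery — in-fold selection, leakage-free evaluation,
calibrated nulls — not performance on any real cohort.

Because the planted effects switch as a step at the cutoff, the AUC profile
across cutoffs is asymmetric: below the planted cutoff the "old" class is
contaminated by only a thin band of true-young hosts, so performance decays
slowly on that side and the peak has a shoulder rather than a spike. The
sweep-recovery check accordingly asks for the argmax within ±3 years of
the planted cutoff, not for an exact hit.

## Numerical choices and degenerate inputs

* Ties in every ranking break lexicographically by feature id; there is no
  hidden randomness anywhere in selection.
* Zero-variance feature columns discretize to all zeros and have zero
  Grubbs statistic (no outlier) by definition.
* An all-zero sample row is an error for the Hellinger transform (its
  composition is undefined) and gets an all-zero TF-iDF weight row.
* A fold whose training set loses a class is skipped with a warning and
  excluded from both the AUC and the accuracy denominators; a fold whose
  selector returns nothing falls back to the training-majority prediction
  with score 0.
* tbPCA fixes each component's sign so that its largest-magnitude loading
  is positive; when ordinating on a selected feature subset, relative
  abundances are recomputed within the subset so the Hellinger transform
  remains a valid composition on the reduced table.
* The GO-transfer threshold is an upper bound on the best-match e-value
  (default $10^{-5}$): transfer happens when the best hit is at or below
  it, the standard direction for homology-based annotation transfer.

## Problem sizes

The bundled tests and the acceptance script run the full pipeline at the
scale of a 120-sample, 500-feature cohort with 20 random subsets of 40
samples per cutoff and per-year cutoffs in a 34–46 window; oracle
equivalence checks (TF-iDF, mutual information, AUC, greedy mRMR steps)
run on matrices of tens of samples by tens of features, where brute-force
evaluation is exact and fast. These sizes were chosen to exercise every
code path at comfortably interactive runtimes while matching the subset
size and run count of the age-balanced design.

## Limitations

* The linear SVM is the only classifier, as in the source design; the
  module boundary would admit others, but none is provided.
* mRMR relevance is computed on discretized abundances; very weak graded
  effects can vanish below the $\pm 1$ sd thresholds.
* Grubbs weighting tests only the single most extreme sample per feature
  (the classical single-outlier test, non-iterative).
* The per-year sweep treats cutoffs independently; no smoothing or
  multiple-comparison control is applied to the profile, matching the
  descriptive use of the sweep.
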
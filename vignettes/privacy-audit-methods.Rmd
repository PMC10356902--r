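---
title: "Auditing the privacy cost of explanations: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing the privacy cost of explanations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A deployed medical-image classifier answers queries with a prediction, and —
increasingly — with explanations: attribution maps that localize evidence on
the input, and concept-based outputs (concept presence scores, concept
localization maps) that phrase the decision in clinician-level vocabulary.
Every extra output is extra information about the model, and a membership
inference attack (MIA) can use it to decide whether a particular image was in
the training set — a direct privacy breach when training data are patient
images.

`explainleak` packages this audit end to end: a controlled synthetic
benchmark with ground-truth concepts, victim classifiers trained under three
regimes (well-regularized baseline, deliberately overfitted, and
differentially private), the full explanation stack, and a suite of metric-
and classifier-based MIAs evaluated under two deployment scenarios.

## The synthetic benchmark

Real dermoscopy datasets with dense concept annotations are small and
access-restricted, so the audit runs on a synthetic analog: two-class images
in which a lesion-like base blob carries simple geometric shapes, and the
class is a deterministic function of which shapes are present.

* Eight concepts: ellipse, triangle, star, rectangle, cross, ring,
  dot-cluster, stripe, each with its own size and color range, drawn only
  inside the blob, possibly overlapping. Each image records per-concept
  presence bits and per-concept binary masks of each shape's own footprint
  (even where later shapes overpaint it) — ground-truth explanations.
* Class rule: class 1 iff (star AND triangle) OR cross; class 0 iff
  (ring AND rectangle) OR stripe. Presence vectors satisfying neither or
  both branches are resampled, so the rule is total and noiseless: the label
  is perfectly computable from the presence bits, and a sufficiently trained
  classifier can reach near-perfect accuracy. Ellipse and dot-cluster are
  distractors. Under independent presence draws with probability 1/2 the two
  branches are symmetric, so classes are balanced by construction.
* Portions: 4,800 train / 1,200 validation / 1,500 test plus a separate
  6,000-image concept-learning portion used only for concept classifiers.
* Resolution: the generator default is 128 px; the shipped analyses run at
  64 px (and 32 px for attack victims) to keep a full audit on one CPU in
  minutes. Shape sizes are fractions of the image side, so the geometry is
  resolution-independent. Discriminative shapes are kept small (radii
  0.08–0.13 of the image side), so class evidence stays sparse and localized
  — on average well under a quarter of the blob area.
* The shifted variant. The suboptimal deployment scenario needs a
  "slightly different population". `apply_distribution_shift()` perturbs
  four knobs: background texture amplitude, a per-image global color offset,
  a multiplicative shape-scale factor, and the pixel-noise sigma. The
  defaults (0.02, 0.15, 0.2, 0.02) were chosen once so that a baseline
  classifier loses only a few F1 points on shifted data while the
  distributions remain statistically distinguishable. All-zero deltas
  reproduce the base distribution bit for bit because the shifted generator
  consumes the identical random stream.

What the generator does *not* emulate: photorealistic skin texture,
annotation noise (masks are exact), label noise, class imbalance, or
inter-patient correlation. Passing tests on this benchmark therefore show
that the audit machinery is correct and that the qualitative orderings hold
under clean conditions; they do not quantify leakage on real dermoscopy
data.

## Victim models and training regimes

Networks are small CNNs written directly in the package (convolution via
im2col in C++, everything else in R): `small_cnn` is three strided
conv/group-norm/ReLU blocks with global average pooling and a linear head;
`resnet_groupnorm` is a strided stem plus three residual stages. There is
deliberately no batch normalization anywhere: group norm depends only on the
individual sample, which is what makes per-sample gradient clipping — and
hence DP-SGD — well defined. The final norm scale of each residual branch is
zero-initialized so blocks start as identities; this stabilizes training at
the default learning rate. Correctness of every layer's backward pass is
pinned by finite-difference tests.

* Baseline: SGD with momentum 0.9, batch 128, learning-rate grid
  {0.1, 0.01, 0.001} (each fully trained; ties toward the smaller rate), up
  to 200 epochs with early stopping (patience 30) on the validation loss, a
  plateau scheduler (patience 10, factor 10), light augmentation and
  weighted sampling; the best-validation checkpoint is kept. The shipped
  analyses use a single-value grid and a reduced epoch budget (around ten
  epochs at 64 px), which already reaches the high-90s weighted F1 on this
  noiseless task.
* Overfit: 50 epochs, no early stopping, no scheduler, no shuffling, no
  weighted sampling, no augmentation beyond normalization, last checkpoint
  kept — a deliberately leaky model whose train-test gap the attacks should
  exploit.
* DP: DP-SGD. Every per-sample gradient is clipped to L2 norm C (default 1),
  Gaussian noise with standard deviation sigma*C is added to the summed
  clipped gradient, and the accountant tracks the spent (epsilon, delta).
  When sigma is not given it is calibrated by bisection so the planned step
  count spends at most the target epsilon (default 5 at delta = 1e-5,
  mirroring the benchmark's epsilon brackets). Accounting uses the exact
  analytic Gaussian-mechanism bound at sampling rate 1 and integer-order
  Renyi-DP composition of the Poisson-subsampled Gaussian mechanism
  otherwise; both are tested against independently coded oracles (5%
  relative tolerance, the spec of record for this quantity).

Evaluation reports support-weighted F1 in percent, per-class precision and
recall, and the confusion matrix.

## Explanations

* Saliency: gradient of the target logit with respect to the input;
  per-pixel channel-max of the absolute value. The absolute-value +
  channel-max convention is fixed and documented so that attack features are
  well defined.
* Occlusion: window 15, stride 8 (window positions are clamped so the last
  window always touches the image border; overlapping contributions are
  averaged by per-pixel coverage). The occluded patch is filled with the
  image mean. Relevance is clean score minus occluded score of the
  *predicted* class.
* CAVs: for each concept, 100 linear classifiers (L2-penalized logistic
  regression on the GAP-layer activations of the concept portion) trained
  with different seeds for the balancing undersampling, each evaluated on a
  held-out 20%. The concept direction is the renormalized mean of the unit
  normals; ensemble quality is summarized by accuracy mean/std and the
  pairwise cosine matrix. Concept scores come from a one-dimensional
  logistic recalibration of the projection on the mean direction, so scores
  live in [0, 1] with 0.5 at the decision boundary. We use the mean CAV (not
  a vote over members) for concept predictions — the cheaper and more common
  choice; the ensemble members remain available.
* TCAV: the fraction of class-k samples whose directional derivative
  (gradient of the class-k logit with respect to the GAP activation, dotted
  with the concept direction) is strictly positive; exact zeros count
  against the score.
* CLMs: g-CLM is saliency of the linear concept score (activation dot mean
  direction); p-CLM is occlusion-style with the window replaced by a blend
  of the Gaussian-blurred image (sigma = window/4) weighted by a circular
  Gaussian (full blur at the center, original at the rim), tracking the
  calibrated concept score. Positive relevance supports concept presence.
  Blur parameters are package choices; the method of record fixes only
  window 15 / stride 8.

## Attacks

Metric-based attacks rank samples by one scalar and report AUC with members
as positives and ties at half credit. Polarities are fixed, not auto-tuned:
members are expected to show lower loss, higher maximum confidence, lower
entropy; prediction variance and the per-sample variances of attribution
maps and CLM sets enter raw. A reversed or uninformative metric can
therefore legitimately score below 50% — auto-flipping would disguise failed
attacks as weak successes.

Classifier-based attacks consume an attack vector: the chosen feature groups
(`TP` target prediction, `CP` concept prediction, `ATT_SAL`, `ATT_Occ`,
`gCLM`, `pCLM`), each flattened and standardized to zero mean/unit variance
per feature with statistics from the attack-training portion only, then
concatenated in spec order. Membership datasets are exactly balanced in
every portion. The SVM attack (RBF kernel, 67/33 split) applies a seeded
Gaussian random projection to 1,024 dimensions when vectors exceed 4,096
features. The FC attack is six linear layers (512-256-128-64-32-2) with
ReLU, SGD, at most 100 epochs, early stopping with patience 10, 45/22/33
split, test accuracy at the best-validation checkpoint. The convolutional
attack zero-pads the vector to a square multi-channel grid and uses a small
strided conv net under the same protocol.

Scenarios: members are always drawn from the victim's training split
(uniformly, without replacement; the validation split is never used).
Non-members come from the held-out same-distribution test split (optimal
deployment) or from a freshly generated shifted pool (suboptimal
deployment). Default 500 per side.

## Numerical and design notes

* Determinism: every stochastic step derives its seed from a global seed via
  fixed stage offsets (all below 2^31); regenerating with the same
  configuration is bit-identical, and metric-attack results reproduce
  exactly across reruns.
* Degenerate inputs: zero-variance attack features standardize to 0; a
  single-class membership vector, empty splits, mismatched CAV layers, and
  non-finite features raise errors naming the offending group/sample.
* Problem sizes in the shipped tests: unit tests run on a 32 px bundle
  (800/150/200/300) with a width-8 victim; the criteria tests on a 64 px
  bundle (2,000/400/500/1,200) with width-16 victims; the acceptance script
  on the full 4,800/1,200/1,500/6,000 bundle at 64 px (32 px for attack
  victims). These sizes are the package's study conditions, chosen so a
  complete audit runs on a single CPU.
* At these evaluation sizes a null AUC has standard error of roughly 2.4-2.6
  points per 250-500 samples per side; rank-statistic checks in the tests
  allow exactly two such standard errors, never more.
* Known limitations: concepts in this benchmark are strongly color-coded, so
  concept classifiers for shapes the victim has no reason to encode (the
  distractors) can sit near chance, and their CLMs are then noise — the
  localization sanity check accordingly requires 6 of 8 concepts, not all 8.
  The DP victims use the same small epoch budgets as the rest of the desk
  scale; their F1 is meant to sit strictly below baseline, not to be the
  best achievable private model.
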
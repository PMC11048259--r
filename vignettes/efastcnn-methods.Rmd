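---
title: "Methods: phantom model, two-stage CNN optimization, and LOSO evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom model, two-stage CNN optimization, and LOSO evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its science: the synthetic
ultrasound model, the classifier and its training rules, the two
optimization stages, the cross-validation protocol, and the numerical and
design choices made where more than one defensible option existed. Code
chunks are illustrative and not executed when the vignette is built; every
empirical statement here is one the package's test suite or acceptance
script computes itself.

## 1. The problem

An eFAST exam inspects standardized scan sites for free fluid (blood) or
free air in the abdominal and thoracic cavities. The package models this
as six independent binary image-classification problems: `RUQ` and `BLD`
(abdominal hemorrhage, B-mode), `PTX_B`/`PTX_M` (pneumothorax, B- and
M-mode) and `HTX_B`/`HTX_M` (hemothorax, B- and M-mode). The pipeline's
job is not a single classifier but a *procedure* for producing one per
site: hyperparameter selection, architecture search, and an honest
estimate of generalization to unseen subjects.

Because the swine dataset such a study uses cannot be redistributed, the
package ships a phantom generator whose role is to reproduce the
*statistical structure* the procedure must cope with, with a known ground
truth and a controllable effect size. All quantitative claims made by the
tests are claims about this generator, not about clinical imagery.

## 2. The phantom model

### Speckle

B-mode texture is modeled as fully developed speckle: a complex Gaussian
field whose magnitude is Rayleigh-distributed with scale `speckle_sigma`
(default 0.25 on the [0, 1] intensity scale — bright enough that anechoic
structures are conspicuous, dim enough that clamping at 1 is rare). A
correlation length `grain` (default 1.5 px) is imposed by Gaussian-
smoothing the real and imaginary components before taking the magnitude;
the components are re-standardized after smoothing so the marginal
Rayleigh scale is preserved. The closed-form mean `sigma * sqrt(pi/2)` is
verified by Monte Carlo in the tests.

### Site anatomy and the injury signal

Each site adds a deterministic template to the speckle background:

* `RUQ`: a bright, curved hepatorenal interface; positive frames darken a
  lens-shaped region hugging the interface.
* `BLD`: an anechoic bladder ellipse with **randomized size** plus
  posterior acoustic enhancement; positive frames add an anechoic pocket
  adjacent to the bladder. Bladder size and hemorrhage severity therefore
  vary independently — two changing variables — which deliberately makes
  this the hardest B-mode site, mirroring the clinical experience that
  pelvic views confound fluid with bladder geometry.
* `PTX_B`/`HTX_B`: vertical rib shadows and a bright horizontal pleural
  line. `HTX_B` positives insert an anechoic band below the pleural line.
  `PTX_B` positives only *suppress texture* below the pleura (blending
  toward the regional mean, no geometric cue): free air manifests as
  absence of structure, not as a dark mass, so the positive signal is
  deliberately weak.
* `PTX_M`/`HTX_M`: depth-versus-time matrices over a 5 s window sampled at
  100 columns/s (display ticks every 0.2 s). Negative captures show the
  "seashore" sign — static layered chest wall above the pleural line,
  granular column-varying speckle (lung sliding) below. `PTX_M` positives
  blend the sub-pleural region toward a temporally static, horizontally
  striated "barcode"; `HTX_M` positives insert an anechoic band that
  widens the pleural space.

The injury `severity` in [0, 1] scales both the extent and the contrast of
these signals. The generator is written so that **every random draw is
consumed whether or not the label is positive**, and the injury
modification is a deterministic function of those draws that vanishes at
severity 0. Consequently severity 0 yields a true null — matched-seed
positive and negative renders are bit-identical, and across seeds the two
classes are identically distributed — which the acceptance suite checks
with exact comparisons and a Kolmogorov–Smirnov test, alongside a
monotonicity check that the AUROC of a fixed anechoic-region discriminant
is non-decreasing in severity.

Every positive frame stores its ground-truth injury mask. Masks exist for
calibration and Grad-CAM audits only; they are never exposed to
classifiers.

### Subject effects

Per-subject random effects — additive gain offset (sd 0.05), multiplicative
speckle-grain factor (log-sd 0.15), anatomy depth shift (sd 0.025 of
height) and structure geometry jitter (sd 0.04) — are deterministic
functions of `(params, subject_seed)`, bounded so pixels remain clampable
to [0, 1]. These defaults were chosen once as a visible-but-not-dominant
level of inter-subject variability: strong enough that a classifier can
overfit its training subjects (making LOSO informative), weak enough that
the injury signal at severity 1 remains learnable. The whole cohort is a
pure function of `(params, base_seed)`.

### What the phantom does not model

No wave propagation, no transducer point-spread function beyond isotropic
smoothing, no motion artifacts, no probe-pressure or depth-gain variation,
and no cardiac or left-upper-quadrant sites. Passing tests therefore
demonstrate that the *pipeline machinery* behaves correctly on data with
ultrasound-like statistics; they do not certify performance on clinical
images.

## 3. Preprocessing

* **Rolling window.** Each 5 s M-mode capture is split into 25 one-second
  sections. The stride is `(duration − window)/(n_sections − 1)` — the
  unique even tiling that produces 25 overlapping one-second windows from
  5 s (stride 1/6 s). A window equal to the duration yields one section.
* **Geometry.** One shared inverse-map bilinear sampler implements
  resizing, rotation, scaling and heat-map upsampling, with pixel centers
  at integer coordinates and zero (anechoic) fill. This makes geometric
  behavior exactly specifiable: same-size resize is the identity, constant
  images stay constant, and a 90° rotation of a 2×2 grid is a pure
  permutation — all asserted in tests.
* **Augmentation** applies, in fixed order, y-axis reflection (coin flip),
  rotation uniform in ±`max_rotation`, and isotropic rescale uniform in
  `scale_range`. The optimization stages use ±36° and [0.90, 1.10]. The
  LOSO stage's rotation limit is stated in the protocol as "10%" without a
  unit; the package interprets it as ±10 degrees and exposes it as the
  `loso_policy()` default rather than hard-coding it.
* **Balancing.** Splits are exactly class-balanced: negatives are sampled
  without replacement to match the positives. Insufficient frames raise a
  typed `efastcnn_insufficient_data` condition reporting the per-class
  deficit.

## 4. The CNN engine

The classifier family is small and fully specified: `n_layers` blocks of
stride-1 "same" convolution (even kernel sizes pad asymmetrically,
floor((k−1)/2) on the leading edge) → ReLU → 2×2 max pool (stride 2, odd
trailing rows/columns dropped), then a fully connected layer with two
outputs, optional dropout on the two logits (the protocol places dropout
after the fully connected layer), and a softmax or softplus final
activation. The simple baseline is three blocks of 16/32/64 filters with
3×3 kernels. Filter ladders use half-up rounding of
`base * multiplier^(l−1)`, since fractional feature-map counts are
impossible. Pooling after *every* conv block is an extension of the
baseline's structure to the searched family, chosen for consistency; the
search space description specifies only the convolution parameters.

Softmax probabilities are computed with log-sum-exp stabilization. The
softplus head is not normalized by definition; for probabilities (loss and
AUROC) its two outputs are L1-normalized, and classification is by argmax
of the raw scores with exact ties predicting negative. Training minimizes
cross-entropy on these class probabilities. Optimizers use their
conventional defaults: RMSprop decay 0.9, ADAM (0.9, 0.999), SGDM momentum
0.9, epsilon 1e−8. Weights are He-initialized from a per-run seed.

Early stopping follows the validation-patience rule: an epoch improves if
its validation loss is strictly below the best so far (no minimum delta);
after `patience = 5` consecutive non-improving epochs training stops and
the best epoch's weights are restored. The rule is factored into the pure
function `early_stop_trace()` so it can be exercised on scripted loss
sequences, and a property test matches it against an independent
state-machine simulator on random sequences. A non-finite loss aborts the
run, which is recorded as a failure (blind accuracy 0 downstream) rather
than an exception.

The conv/pool forward and backward passes are implemented in
RcppArmadillo via im2col + GEMM; the test suite verifies all gradients
against central finite differences. There is deliberately no external
deep-learning dependency: the training loop is part of what is being
specified and tested.

## 5. Stage 1 — exhaustive grid and score aggregation

The grid is the Cartesian product of batch size {16, 64, 128}, optimizer
{RMSprop, ADAM, SGDM}, learning rate {0.001, 0.0005, 0.0001} and final
activation {softmax, softplus}: 54 unique runs, enumerated in a fixed
order (batch slowest). Each run is scored `max(accuracy − 0.5, 0)` from
blind-test accuracy, and its score is credited to the entry of each of its
four parameter values, so every parameter's column sums to the same grand
total (a conservation property the tests assert). The winner of each
parameter is its argmax; ties break toward the first listed value and are
logged. Blind-test accuracy is computed by argmax over the head's outputs
with ties predicting negative.

Stage-1 sample budgets at native scale: B-mode 2500/500/500
train/validation/blind-test images, M-mode 1250/250/250, balanced between
classes; all budgets scale proportionally for desk-scale runs.

## 6. Stage 2 — Bayesian architecture search

The search space: kernel edge 2–7 and depth 2–6 and base filters 2–16
(integers), multiplier in [1, 2] (real), dropout on the nine-level grid
0.1–0.9. The first 8 trials are uniform random (the protocol does not
state an initialization; 8 points give the surrogate a sane start in five
dimensions); afterwards a Gaussian process with Matérn-5/2 kernel on the
unit-cube-scaled parameters is fit to the history (lengthscale selected
from {0.1, 0.2, 0.3, 0.5, 1} by marginal likelihood, observation noise
1e−4 on standardized objectives) and the next trial maximizes expected
improvement over a random candidate set plus local perturbations of the
incumbent. Integers are handled by continuous relaxation and rounding;
an already-evaluated specification is never re-proposed (collisions are
perturbed away). A failing objective records 0 and the search continues.
The incumbent is non-decreasing by construction, and on a separable toy
objective the search recovers the exhaustive-oracle optimum in ≥95% of
seeded replicates (acceptance suite).

The objective is the blind-test accuracy of the trained candidate, exactly
as the protocol states. Note that this leaks the test set into model
selection; the package implements the stated protocol without correction
but provides `stage2_objective = "validation"` as the methodologically
conservative alternative. The top three architectures by objective (ties
to the earlier trial) advance to LOSO.

## 7. LOSO evaluation

Subjects are randomly partitioned into `k = 5` clusters whose sizes differ
by at most one (27 subjects → 6, 6, 5, 5, 5); each cluster acts as one
held-out "subject". The plan is persisted and shared across architectures
so all models see identical splits. Per split, training and validation
data come only from the retained clusters (sampled jointly so they never
share a frame) and blind-test data only from the holdout; subject
disjointness is a hard assertion, not a convention. Native budgets:
B-mode 16,000/2,000/2,000 total train/val/test frames, M-mode
4,000/500/500, class-balanced.

Metrics per split: accuracy, precision, recall, specificity and F1 from
the confusion counts — zero denominators yield `NA` flags, never errors —
plus AUROC for the positive class computed as the tie-corrected
Mann–Whitney probability (equal to the trapezoidal ROC area). Tests match
the metrics against hand-evaluated tables, an accuracy identity on random
tables, exhaustive pairwise-ordering enumeration, and `pROC::auc` as an
independent oracle. Aggregates are the mean and sample (n−1) standard
deviation over completed splits; a failed split is recorded with a
warning.

The reference-architecture arm deserves a caveat: MobileNetV2, DarkNet53
and ShrapML are registered as *reduced-scale synthetic stand-ins* (compact
CNNs of the corresponding character — light/deep/mid-depth). Their
canonical topologies and ImageNet weights are not reproducible in this
package; `pretrained = TRUE` warns and falls back to random
initialization. The registry accepts user-supplied builders under the same
names for anyone with faithful implementations.

## 8. Grad-CAM

For a target class, channel weights are the spatial means of the gradient
of the raw class score with respect to the final conv block's post-ReLU
feature maps (the head is linear in the pooled maps, so this gradient is
exact, not approximated); the map is the rectified weighted sum,
min–max-normalized to [0, 1] (an all-zero map stays zero) and bilinearly
upsampled. On trained severity-1 phantoms the tests assert the audit one
would hope for: mean heat inside the generator's truth mask exceeds mean
heat outside on true positives. Overlays use a red–yellow ramp
alpha-blended at 0.4.

## 9. Problem sizes used by the test and acceptance suites

The suites run the full machinery at desk scale, chosen as the smallest
sizes at which every statistical check retains power: 12–64 px renders;
cohorts of 2–27 subjects; the 54-run grid exercised in full for
enumeration/scoring and as a 2×2×1×1 sub-grid for end-to-end training;
Bayesian budgets of 5–30 trials; LOSO with k = 3–5; training sets of
16–200 frames with epoch caps of 2–8 (the 100-epoch protocol cap is a
ceiling, not a target — on the cleanly separable severity-1 phantom,
validation loss plateaus within a handful of epochs). The end-to-end
acceptance run uses 64×64 frames, ~225 frames per class per site, and
verifies that the simple CNN's blind-subject accuracy averaged over three
seeds is at least 0.8 at severity 1.

## 10. Known limitations

* Phantom realism is calibrated to qualitative descriptions of eFAST
  imagery, not to measured image statistics; no claim of acoustic
  fidelity is made.
* The stand-in reference architectures bound what the LOSO comparison can
  say about the true published networks.
* Dropout is applied to the two logits (where the protocol places it);
  with only two units this is a coarse regularizer, and large rates mainly
  inject label noise during training.
* The Gaussian-process search uses fixed candidate-set acquisition rather
  than gradient-based maximization of expected improvement; with ≤100
  trials in five dimensions this is ample, but the acquisition is
  intentionally pluggable.
* The stage-2 objective's use of blind-test accuracy is preserved from the
  protocol; treat the resulting "blind" numbers as optimistic unless the
  validation objective is selected.
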
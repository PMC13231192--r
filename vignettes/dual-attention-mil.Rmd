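---
title: "Dual-attention multiple-instance learning for patient-level ultrasound classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-attention multiple-instance learning for patient-level ultrasound classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(attnmil)
```

## The problem

A thyroid ultrasound examination produces a variable number of 2-D still
images per patient, while the diagnostic ground truth (histopathology after
biopsy or surgery) exists only at the patient level: a patient is labelled
malignant if *any* of their nodules was confirmed malignant. Annotating
individual images is expensive and often impossible retrospectively, so the
learning problem is weakly supervised. `attnmil` treats each patient as a
*bag* of image *instances* under the standard multiple-instance-learning
(MIL) assumption: a positive bag contains at least one positive instance, a
negative bag contains none.

## The model

For patient $i$ with bag $B_i = \{x_{ij}\}_{j=1}^{n_i}$ and label
$y_i \in \{0, 1\}$:

1. **Backbone.** Each instance is encoded by a convolutional backbone into
   a spatial feature map $h_{ij} = f_\theta(x_{ij}) \in
   \mathbb{R}^{C \times H \times W}$. The production configuration is a
   34-layer residual network with the classification layer removed
   ($C = 512$; a 256×256 input yields an 8×8 map from the total stride of
   32). The test-scale `tinycnn` backbone (four bias-free 3×3
   conv/batch-norm/ReLU blocks, each stride 2, channels 8→16→32→64) keeps
   every experiment in this package CPU-sized; on 64×64 inputs it yields a
   4×4 map with $C = 64$.

2. **Spatial attention with residual refinement.** Per instance, three 1×1
   projections $\psi_1, \psi_2, \psi_3 : C \to C'$ form queries from the
   full-resolution map and keys/values from a 2× bilinear downsample
   $\tilde h_{ij}$. The attention map is
   $\Psi_{12} = \mathrm{softmax}\!\left(\psi_1(h_{ij})^\top
   \psi_2(\tilde h_{ij}) / \tau\right)$, each row a distribution over the
   downsampled positions, and the refined map is
   $\psi_4\!\left(\Psi_{12}\, \psi_3(\tilde h_{ij})\right) + h_{ij}$ — a
   residual, so spatial attention enhances rather than replaces features.

3. **Gated instance attention.** Refined maps are globally average-pooled
   into vectors $v_{ij} \in \mathbb{R}^C$. Instance relevance is scored by
   a gated two-branch layer,
   $a_{ij} = w_c^\top\!\left(\tanh(W_a v_{ij}) \odot
   \sigma(W_b v_{ij})\right)$ with $W_a, W_b \in \mathbb{R}^{D \times C}$,
   normalised by a softmax within the bag into weights $\alpha_{ij}$, and
   the bag embedding is $z_i = \sum_j \alpha_{ij} v_{ij}$.

4. **Classifier and loss.** $p_i = \mathrm{softmax}(W^\top z_i + b) \in
   \mathbb{R}^2$; training minimises the mean cross-entropy
   $-\tfrac1N \sum_i \log p_{i, y_i}$.

The comparison baselines (`meanpool`, `maxpool`) share the backbone and
classifier code paths exactly and replace *both* attention stages by an
element-wise mean or maximum over the pooled raw backbone vectors.

## Design choices where the formulation is open

Several details of the formulation above admit more than one reading; the
package fixes them as follows.

* **Softmax axis of $\Psi_{12}$** — over the downsampled key positions
  (row-wise), so each query position distributes unit attention over keys.
  Any other axis breaks the semantics of the context product
  $\Psi_{12} \psi_3(\tilde h)$.
* **Projection kernels** — $\psi_1\ldots\psi_4$ are 1×1 convolutions
  (equivalently per-position linear maps), matching the matrix-product
  formulation; $\psi_1$–$\psi_3$ carry no bias, $\psi_4$ does.
* **$\psi_4$ zero-initialisation** — the module starts as the exact
  identity, which stabilises early training and makes the residual path
  testable exactly at initialisation.
* **$\tau$** is a fixed constant (default 128, configurable), not
  $\sqrt{d_k}$.
* **Downsampling** — bilinear at scale 0.5 under the corner-excluding
  convention, which is exactly 2×2 mean pooling; this makes the operation
  (and its adjoint) reproducible to machine precision. Odd feature sizes
  are rejected rather than resolved by an arbitrary convention.
* **Flattening order** — spatial positions are enumerated row-major over
  H then W; the loop-based oracle tests pin this order.
* **Dropout placement** — one dropout (rate 0.25 by default) on the
  attended context in the spatial module and one on the gated hidden
  activations in the instance module; both inactive at evaluation.
* **Padding semantics** — batches are zero-padded to the largest bag, but
  padded slots never enter the backbone, and their attention logits are
  $-\infty$, so their weights are exactly zero. Adding padding can
  therefore never change a prediction; a property test asserts this.
* **Masked softmax and empty bags** — an all-masked bag is an error, not a
  NaN.
* **Baseline scope** — the baselines replace the *dual-attention module*,
  i.e. both sub-modules; they pool raw (unrefined) backbone features. The
  alternative reading (baselines keep spatial refinement) would blur the
  module-level comparison.
* **Loss clamping** — probabilities are clamped at $10^{-12}$ inside the
  loss so float underflow cannot produce an infinite loss.
* **Weight decay** applies to weight matrices (conv kernels, attention
  projections, classifier) but not to biases or batch-norm scale/shift,
  the standard practice for SGD with decoupled parameter types.

## Training protocol

`train_config()` defaults encode the reference protocol: SGD with momentum
0.9 and weight decay $5\times10^{-4}$; base learning rate $10^{-3}$ with a
half-cosine warm-up from $10^{-3}/1000$ across the first epoch, then decay
by $\gamma = 0.1$ at epochs 50 and 75; 100 epochs; 10 patients per batch;
training-time augmentation by horizontal flip ($p = 0.5$) followed by a
rotation drawn from {0°, 90°, 180°, 270°} (the group generated is the same
in either order); resize to 256×256 and per-channel standardisation with
the ImageNet statistics $\mu = (0.485, 0.456, 0.406)$,
$\sigma = (0.229, 0.224, 0.225)$ — grayscale frames are replicated to three
channels so ImageNet-style backbones and their pretrained weights remain
usable. "Cosine warm-up" is read as a half-cosine ease-in; the name alone
does not fix a curve, and the end points ($10^{-6}$ at step 0, $10^{-3}$
after one epoch) are checked exhaustively in the tests.

The best model is selected by validation AUROC, with ties broken toward
the earlier epoch (the later of two equally good epochs has had more
opportunity to overfit). Whether early stopping should be layered on top
of the milestone schedule is left open by the protocol; the package trains
the full epoch budget and relies on best-epoch selection only.

Every source of randomness — splitting, initialisation, per-epoch
shuffling, augmentation, dropout — draws from a named sub-stream of one
master seed (`substream_seed()`), so each stage is independently
reproducible and two runs with the same seed agree to within floating-point
reassociation (the determinism test asserts loss agreement at $10^{-6}$).

## Cross-validation and metrics

Splitting is by patient, never by image. `split_patients()` holds out
`round(test_frac * P)` patients (ties rounded up — the protocol states only
"90%/10%") and deals the rest round-robin, per label, into $k$ disjoint
validation folds. Both the test split and the folds are label-stratified;
with unstratified folds the per-fold operating-point metrics would be
destabilised by class imbalance in small validation sets. The split file
records seed and counts.

AUROC uses the Mann–Whitney formulation with midrank tie handling; a
property test checks it against exhaustive pairwise concordance and
trapezoidal ROC integration for all $n \le 50$. AUPRC uses
non-interpolated step summation, which avoids the optimistic bias of
trapezoidal interpolation in PR space — worth documenting because external
comparisons must be apples-to-apples. Sensitivity, specificity, PPV and
NPV are reported at an operating point; the protocol presumes a
"predefined" point without defining one, so the package makes the
threshold a required, recorded configuration value with default 0.5 on the
malignancy score, plus an optional Youden-on-validation mode
(`youden_threshold()`). Ratios with zero denominators are flagged `NA`,
never silently zero. Fold summaries are arithmetic means with sample
standard deviations ($n - 1$).

## The synthetic cohort: what it emulates and what it does not

No clinical images ship with the package; every pipeline stage is instead
exercised on a synthetic generator whose ground truth is known at the
instance level.

* A **benign instance** is a bright ellipse with a smooth soft boundary on
  a darker background.
* A **malignant instance** shares the identical background/intensity model
  and differs in exactly two sonographically motivated cues: its boundary
  radius is modulated by a low-order (orders 2–4) random Fourier series
  (irregular margins), and 3–8 punctate high-intensity spots are planted
  inside the nodule (microcalcification proxies).
* **Speckle** is the first-order multiplicative model: a unit-mean
  Rayleigh factor blended at `speckle_scale` and clipped to $[0, 1]$.

Two calibrations keep the task honest. The Fourier modulation is
area-normalised in expectation so malignant nodules are not systematically
larger, and the intensity mass added by the spots is debited uniformly
from the nodule interior, so class is carried by *texture and shape*, not
by global brightness. A test fits a bag-level pixel-mean classifier and
requires it to sit near chance, while the trained model must exceed 0.9
AUROC on the same cohorts — passing both shows the network learned the
planted morphology, not a brightness shortcut. The generator does not
attempt physically realistic ultrasound (no beamforming, attenuation,
shadowing or anisotropy), so passing results bound what the *method* can
do when its assumptions hold; they say nothing about clinical performance
on real cohorts.

Defaults (200 patients, prevalence 0.5, bag sizes uniform on 3–12, witness
rate 0.3, 64×64 pixels, `speckle_scale` 0.35, `irregularity` 0.35) are
chosen once to mirror a mid-sized single-centre cohort: a few hundred
patients, a handful-to-a-dozen images each, and a minority of genuinely
informative frames per positive patient.

## The reference experiment

`synthetic_benchmark()` is the package's scaled-down stand-in for a
clinical comparison: the default cohort above, a stratified 10% test
hold-out, training on the first fold's training patients (~144 bags) with
the tinycnn backbone for 30 epochs, best-epoch selection on that fold's
validation patients, evaluation on the held-out test patients, and — for
the dual-attention variant — attention rankings of the positive test bags
scored against the planted instance labels (precision@1 against the
witness-rate random baseline of 0.3).

Two deliberate departures from the production defaults, both consequences
of the scale change and fixed before the experiment was run: the attention
widths shrink with the backbone ($C' = 32$, $\tau = 32$, $D = 64$ for
$C = 64$; the production ratios $C' = C/4$, $D = C/4$–$C/2$ are kept), and
the base learning rate is 0.015 — a randomly initialised small backbone on
~1100 images needs a larger step than the fine-tuning regime
(ImageNet-pretrained ResNet-34) the $10^{-3}$ default assumes; with
$10^{-3}$ and 30 epochs the loss barely leaves its plateau, and at 0.01
some seeds are still mid-descent when the epoch budget ends.

Problem sizes throughout the tests (cohort sizes of 10–200 patients,
image sizes 24–64, epochs 2–30) are the package's chosen desk-scale
operating points: large enough for the properties under test to be
non-trivial, small enough that the whole suite runs on one CPU core in
minutes.

## Numerical notes

* Softmaxes subtract the row maximum before exponentiation; the classifier
  tolerates logits of $\pm 1000$ exactly.
* Batch statistics use the population variance for normalisation and the
  unbiased variance for the running estimate (momentum 0.1); evaluation
  uses running statistics, so evaluation-mode predictions are deterministic
  and independent of batch composition.
* All backward passes are hand-derived and verified against central finite
  differences at $10^{-3}$ relative tolerance, and the attention forward
  passes against independent loop-based oracles at $10^{-5}$.
* Gradient bookkeeping is functional (no mutation), so a training step is
  reproducible given its RNG stream; the only accepted nondeterminism is
  floating-point reassociation inside BLAS.

A caution on interpreting the baseline comparison: the generator
implements the *pure* standard-MIL assumption, and its malignant cue — a
high-contrast punctate pattern detectable within a single instance — is
exactly the situation in which channel-wise max aggregation (an OR over
instances) is near-optimal by construction. On this synthetic task the
attention model consistently and clearly outperforms mean pooling (which
dilutes the witness signal), but it does not reliably exceed max pooling;
on large fresh evaluation cohorts max pooling is at least as accurate in
two of three seeds in every training regime we measured. The brittleness
that penalises max aggregation on real ultrasound — artifact-prone frames
whose echo patterns mimic malignant cues, noted as a dominant false-
positive mode in clinical use — is deliberately outside this generator's
scope, so the synthetic comparison should be read as a meanpool-trend
reproduction plus a shared-ceiling result against maxpool, not as evidence
about real cohorts. The acceptance suite states the maxpool comparison as
a strict inequality and reports it honestly.

## Known limitations

* The generator's nodules are single, centred and convex-ish; real frames
  contain multiple nodules, off-centre anatomy, probe annotations and
  acquisition artifacts.
* The ResNet-34 backbone is provided for architectural fidelity and loads
  external pretrained weights from a local RDS file, but training it from
  scratch on CPU is impractical; all in-package training evidence comes
  from the tinycnn configuration.
* AUROC on a 20-patient test split is coarse (granularity 0.01); the
  reference experiment therefore averages over seeds.
* No confidence intervals (DeLong/bootstrap), calibration or
  decision-curve analysis; the evaluation mirrors discrimination and
  operating-point reporting only.
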
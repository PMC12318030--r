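---
title: "Methods: lung-nodule CT classification with noduleCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lung-nodule CT classification with noduleCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

noduleCT implements a complete binary lung-nodule classification pipeline
for 2-D CT slices: adaptive Gaussian denoising, an attention residual
U-Net segmenter, a 201-dimensional hybrid feature extractor, and a
soft-voting ensemble of two CPU-trained neural classifiers. This vignette
explains the models, the choices behind every tunable, and what the
built-in synthetic benchmark does and does not demonstrate.

## The phantom generator

Real lung-CT cohorts are large, access-controlled downloads. To make every
stage of the pipeline testable on a laptop, `generate_phantom()` draws a
synthetic slice: a soft-tissue background (default intensity 0.65 on the
[0,1] float contract), two darker elliptical lung fields (drawn at 35% of
the background intensity, approximating the air-filled lung parenchyma of
a mediastinal-window CT), and — for the cancer class — one to three bright
Gaussian-profile nodule blobs (peak 0.90) placed entirely inside a lung
field. The ground-truth mask marks pixels within the nodule radius; the
label is 1 exactly when the mask is non-empty, which keeps labels and
masks consistent by construction. Additive Gaussian noise (default
sigma 0.05 for pipeline runs — strong enough that denoising visibly
matters, weak enough that nodule contrast ~0.6 dominates) finishes the
slice.

What the phantom does *not* emulate: Hounsfield-unit physics, vasculature
and airway texture inside the lung, pleural-wall attachment of nodules,
3-D partial-volume effects, and scanner-specific noise correlation. A
classifier that is perfect on phantoms has demonstrated that the
implementation learns and that the pipeline plumbing is correct — not
that it would transfer to clinical data. Benchmark accuracies here are
therefore read as software sanity checks, not clinical claims.

Determinism is a contract: every stochastic draw descends from one stated
integer seed (`withr::with_seed` scopes), so regeneration is
bit-identical and every experiment in the test suite is reproducible.

## Adaptive Gaussian denoising

The denoiser convolves with a discrete Gaussian kernel, renormalized to
unit sum so mean intensity is preserved (the analytic 1-D prefactor is
irrelevant after renormalization). The *adaptive* variant assigns each
pixel its own smoothing strength: local intensity variance in a 7-px
window, min–max scaled over the slice, interpolates the per-pixel sigma
in `[sigma_min, sigma_max]` — high variance (edges, nodule boundaries)
gets the light touch, flat noisy regions the strong one. The filter is
implemented as a bank of five fixed-sigma convolutions with per-pixel
linear interpolation between the two bracketing bank members; reflect
padding avoids halo artefacts at the lung border. Defaults
`sigma_min = 0.5`, `sigma_max = 1.5` px suit the 64-px phantom scale: on
the noisy benchmark (noise sigma 0.05) the adaptive rule reduces the
residual to the clean slice by roughly 40% while the plain filter at
`sigma_max` *increases* it by oversmoothing edges — which is precisely
the argument for adapting.

Image quality is scored with PSNR (`10·log10(MAX²/MSE)`, MAX = 1 on float
data) and mean SSIM with the standard constants (7-px Gaussian window,
sigma 1.5, K1 = 0.01, K2 = 0.03, dynamic range 1).

## Attention residual U-Net segmentation

The segmenter is an encoder–decoder. Each encoder stage is a residual
block (3×3 conv → PReLU → 3×3 conv, identity or 1×1-projection shortcut)
followed by a residual dual-channel attention block, with 2×2 max-pool
downsampling between stages; the decoder mirrors this with attention,
nearest-neighbour upsampling, concatenation of the matching encoder
attention output, and a residual block per stage. A 1×1 convolution plus
sigmoid yields the probability map, thresholded (default 0.5) into the
mask.

The attention block runs three parallel branches: global max pooling and
global average pooling each feed a channel-mixing layer and a PReLU;
their sum passes through the tanh-gated activation to become per-channel
attention weights. A third spatial branch (3×3 conv → PReLU → 3×3 conv)
processes the full map. Fusion is the attention-weighted input plus the
spatial branch, one more tanh-gated activation, and a residual connection
around the whole block. The residual guarantees attention can rescale but
never erase a feature — the failure mode that motivates attention-plus-
residual designs in the first place. The exact wiring between the pooled
and spatial branches is underdetermined by the usual block diagrams;
the sum-then-gate fusion used here is the simplest shape-safe reading
and is fixed as this package's definition.

Two activations appear throughout. PReLU carries one trainable negative
slope per channel (initialized at 0.25). The second is a
sigmoid-derivative weighted linear unit: the conventional form is
`s(x)·(1 + x·(1 − s(x)))` with the logistic `s`; the improved variant
gates the logistic through `tanh` first, `SF(x) = 1/(1 + exp(−tanh x))`.
Because the gate bounds the logistic argument to [−1, 1], the function
never saturates: for large |x| it grows linearly with slope
`s(1)(1 − s(1)) ≈ 0.197`. That unbounded-but-gentle tail is unusual — a
plain SiLU derivative tends to 0/1 — and it is implemented exactly as
defined, with its closed-form derivative used in backpropagation
(verified against finite differences in the test suite).

Design choices where the field offers options:

* **No batch normalization in the residual blocks.** Desk-scale batches
  (1–8 slices) make batch statistics noisy and break train/eval parity at
  batch 1; the residual connections already stabilize optimization at
  this depth.
* **Loss:** soft Dice (smooth constant 1) plus pixel BCE — the standard
  pairing for heavily class-imbalanced masks (a nodule is ~2% of a
  slice). BCE supplies gradients even where the sigmoid saturates; Dice
  supplies the overlap objective.
* **Optimizer:** Adam, learning rate 1e-3, threshold 0.5 — mirroring the
  classifier regimen.
* **Desk-scale architecture:** depth 3, 8 base channels, 64×64 inputs
  (~85k parameters). A deeper 512-px configuration is expressible through
  `seg_config()` but nothing in the tests needs it.

## The 201-value hybrid feature vector

Features are extracted from the *segmented* slice (image × predicted
mask) and concatenated in the fixed order
`[LGTrP 50 | PHOG 50 | deep 100 | entropy 1]`.

**Local Gabor transitional patterns (50).** A bank of four zero-mean
Gabor filters (orientations 0/45/90/135°, wavelength 4 px, envelope
sigma 2 px) is applied and the maximum response magnitude taken per
pixel; DC subtraction makes the response invariant to constant intensity
offsets. On that response map, each pixel gets an 8-bit transition code:
bit `l` is set when the intensities at radii 1 and 2 in direction `l`
*both* exceed the centre (ties break to 0), read as a consistent outward
intensity transition; off-grid samples are bilinear. Histograms with 10
equal-width bins over [0, 256) are taken over five regions (2×2 grid plus
whole map), each L1-normalized — 50 values. The region/bin layout is the
smallest natural factorization of the fixed total of 50.

**Pyramid HOG (50).** Sobel gradients give magnitude and orientation; the
orientation uses the full-quadrant arctangent of (y-gradient, x-gradient)
folded to [0°, 180°) — the standard unsigned convention, chosen over the
ambiguous printed ratio forms that drop quadrant information. Level 0 is
the whole image, level 1 its 2×2 cells; each cell votes
magnitude-weighted orientations into 10 bins, and the concatenated
10 + 40 vector is L1-normalized once. 10 bins × (1 + 4) cells is the
unique standard layout reaching 50.

**Deep features (100).** Two seed-initialized convolutional backbones —
an AlexNet-style plain stack tapped at a 256-unit fully connected layer
and a ResNet-style residual stack tapped at its 128-channel global
average pool — produce a 384-value raw tap, compressed to 100 by one
joint PCA fitted on the training split only. The backbones are
deliberately *untrained*: no pretrained weights can ship with the
package, and a fixed random convolutional network is a deterministic,
structure-aware projection that is entirely adequate for the
linearly-separable phantom classes. On real data one would substitute
ImageNet-pretrained taps of the same two families at their native 4096-
and 2048-dim layers; the joint-PCA interface is unchanged, and it also
sidesteps the question of how to split the 100 dimensions between the
two families. These are labelled synthetic backbones throughout.

**Improved entropy (1).** Shannon entropy `En` of the 8-bit-quantized
histogram is mixed with the normalized first-order entropy
`NEn = En_1/log2(N_m)` (support = levels actually present; a constant
image defines `NEn = 0`) using the data-dependent weight
`W = 2(1 − 1/(1 + e^En))`: `IEn = W·En + (1 − W)·NEn`. Note `W > 1`
whenever `En > 0`, so the complementary weight is negative and `NEn` is
effectively *subtracted* — the formula is applied exactly as defined and
this sign behaviour is intentional, not a bug. Quantization rounds to
`[0, 255]` so PNG-derived data maps exactly onto its 8-bit levels. A
plain-Shannon variant is available as an ablation switch.

## The classifier ensemble

Routing honours both halves of the architecture: the image classifier
sees the segmented slice; the feature classifier sees the 201-vector;
soft voting fuses their probability rows.

**ILN-TL (image path).** A frozen VGG-style convolutional trunk (the
desk-scale default is a 4-layer "mini" trunk producing a 4×4×32 map; a
full 13-conv VGG-16 layout is selectable) feeds a head of:
Lehmer-centred Gaussian normalization, a 5×5 depthwise separable
convolution, relu, max pooling then min pooling (the two-stage pooling
keeps both the strongest and the weakest local responses), two
dense(128, relu) + dropout(0.3) stages and a 2-way softmax. The
normalization maps each feature as `((X − mu_L)/(3·sigma) + 1)/2` with
`mu_L` the Lehmer mean (Q = 2) of the training values — the training
Lehmer mean lands exactly at 0.5 and ±3 sigma at the clip boundaries.
Statistics are fitted on the training trunk features and frozen. Because
the trunk is frozen, trunk features are precomputed once and only the
head trains (Adam, lr 0.001, batch 64, validation split 0.2, 50 epochs,
categorical cross-entropy). Freezing-only is a deliberate scope cut: a
fine-tuning mode would forfeit the precomputation and none of the
desk-scale experiments need it.

**DeepMaxout (feature path).** The 201-vector is treated as a 1-D
sequence: convolution (kernel 3, 16 channels), per-channel batch
normalization, max pooling (window 2), then a dense maxout block — the
elementwise maximum of 3 affine pieces, giving non-zero slope on both
sides of every hinge — and a 2-way softmax (Adam, lr 0.01, batch 32,
50 epochs). Three pieces is the smallest count that can represent
non-convex piecewise-linear activations.

**Soft voting.** Fused probabilities are the weighted mean of the two
rows with default weights (0.5, 0.5); the label is the fused argmax with
exact ties resolved to non-cancer — the conservative default for a
screening-style classifier.

## Evaluation

`split_dataset()` uses the floor rule `n_train = floor(fraction·n)` —
the unique rule consistent with the 2336-instance reference arithmetic
(1401/935, 1635/701, 1868/468 at 60/70/80%) — with largest-remainder
stratification on by default. `confusion_and_metrics()` reports the nine
standard confusion-matrix statistics; zero-denominator metrics report 0
with a warning so degenerate ablation arms still produce complete
reports. `roc_auc()` is computed in the rank (Wilcoxon) form, which is
exactly the trapezoidal area and the tie-aware pairwise probability; the
test suite cross-checks it against both an O(n²) pairwise oracle and
pROC. Repeat-run statistics (`mean/median/std/min/max` of accuracy) come
from seed-varied reruns of the whole pipeline — the repeat protocol is a
package definition, stated here because no external convention fixes it.

## Numerical and engineering notes

All networks run on a small in-package CPU layer engine (im2col
convolutions on base-R BLAS, hand-written backward passes, Adam). The
backward pass of every layer and of the assembled U-Net and attention
blocks is verified against central finite differences in the unit tests.
The input gradient of a same-padded convolution is computed as a
convolution with the spatially flipped, channel-transposed weights — one
GEMM rather than a scatter-add. Max/min pool ties route gradient to the
first winning position; the global-max-pool backward scatters to the
recorded argmax. Dropout is inverted dropout, active only in training.
Softmax cross-entropy uses the max-shift trick; probabilities are
clamped at 1e-7 only inside the BCE *value*, never in gradients.

Problem sizes in the shipped experiments are chosen for a single CPU:
64×64 slices, 200-phantom benchmark (160 train / 40 test), 8 segmentation
epochs in the pipeline default, 200 epochs for the single-slice capacity
check. At these sizes the full benchmark trains both classifiers and the
segmenter in a few minutes.

## Known limitations

* Phantom realism as above; no 3-D context.
* The untrained deep-feature backbones and mini trunk measure pipeline
  correctness, not representation quality.
* The segmenter's Dice on the benchmark (~0.85 at 8 epochs) reflects the
  deliberately short training schedule, not a capacity limit — the
  single-slice check reaches Dice ≥ 0.95.
* Batch normalization statistics in DeepMaxout are batch-size dependent;
  with the fixed seeds and batch plans used here this is deterministic,
  but changing batch sizes changes results beyond RNG effects.
* The soft-voting weights are fixed, not learned; alternative fusions
  (hard voting, stacking) are out of scope.
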
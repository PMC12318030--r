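# noduleCT

Binary lung-nodule classification on 2-D CT slices, end to end: adaptive
Gaussian denoising, attention residual U-Net segmentation, a
201-dimensional hybrid feature vector, and a soft-voting ensemble of two
neural classifiers. Everything — including the networks — runs on a small
built-in CPU layer engine, and a synthetic CT-phantom generator makes the
whole pipeline reproducible on a laptop with no data downloads. The
package is aimed at researchers who want a tested, desk-scale reference
implementation of this pipeline family to study, ablate, or port to real
cohorts.

## The method

Given a noisy slice `Img`, the pipeline computes

1. **Denoising** — `Img_pre = AG(Img)`: an adaptive Gaussian filter whose
   per-pixel smoothing sigma decreases with local intensity variance
   (strong smoothing in flat regions, light touch on edges). Quality is
   scored by PSNR and SSIM against the clean reference.
2. **Segmentation** — `Img_seg = Img_pre ⊙ M`, with the mask `M` from an
   attention residual U-Net: residual blocks, each followed by a
   dual-channel attention block (global-max-pool and global-average-pool
   branches gate per-channel weights through a tanh-gated sigmoid-weighted
   activation; a parallel 3×3 conv branch adds spatial detail; a residual
   connection wraps the block), trained with soft-Dice + BCE.
3. **Features** — `f = [LGTrP(50) | PHOG(50) | Deep(100) | IEn(1)]`:
   local Gabor transitional patterns, pyramid histograms of oriented
   gradients, PCA-compressed convolutional taps, and the entropy mixture
   `IEn = W·En + (1−W)·NEn` with `W = 2(1 − 1/(1+e^En))`.
4. **Classification** — soft voting `Y = argmax_i Σ_j w_j p_ij` over a
   transfer-learning LeNet-style image classifier (frozen VGG-style
   trunk, Lehmer-mean Gaussian normalization
   `N_Z = ((X−μ_L)/3σ + 1)/2`, depthwise separable convolution, max/min
   pooling, dense head) and a DeepMaxout feature classifier
   (conv → batch norm → pool → maxout pieces → softmax), `w = (0.5, 0.5)`.

Evaluation reports the nine confusion-matrix metrics (accuracy,
sensitivity, specificity, precision, F-measure, MCC, NPV, FPR, FNR),
rank-based ROC-AUC, Dice/Jaccard for the masks, and repeat-run accuracy
statistics. See `vignettes/noduleCT-methods.Rmd` for the full model
account and design rationale.

## Worked example

```r
library(noduleCT)

cfg <- pipeline_config(n = 60L,                       # 60 phantom slices
                       segmentation = seg_config(epochs = 6L),
                       seed = 42L)
report <- run_pipeline(cfg)
print(report)
```

```
Evaluation report (test n = 12 )
  accuracy    0.917
  sensitivity 0.833  specificity 1.000
  precision   1.000  f-measure   0.909
  mcc         0.845  npv         0.857
  fpr         0.000  fnr         0.167
  auc         1.000
  dice        0.715  jaccard     0.648
  psnr 26.05 -> 29.80 dB  ssim 0.497 -> 0.922
```

Reading it: of the 12 held-out slices (floor-rule 80/20 split, stratified)
11 are classified correctly; the one miss is a cancer slice read as
non-cancer (sensitivity 0.833, specificity 1.000). The fused scores rank
every cancer slice above every non-cancer slice (AUC 1.000). The
segmenter, trained for only six epochs here, reaches mean Dice 0.715 on
the held-out masks, and the adaptive filter lifts PSNR by ~3.8 dB and
SSIM from 0.50 to 0.92 against the clean phantoms. Larger runs (200
slices, default 8 epochs) reach test accuracy 1.0 on this synthetic
benchmark — a statement about implementation correctness, not clinical
performance.

Individual stages are exposed directly: `generate_dataset()`,
`adaptive_gaussian_filter()`, `train_segmenter()` / `segment()`,
`extract_feature_vector()`, `train_ensemble()` / `predict_ensemble()`,
`soft_vote()`, `split_dataset()`, `confusion_and_metrics()`, `roc_auc()`.
A thin command-line front end lives at `inst/cli/noduleCT.R`
(`simulate`, `preprocess`, `run` subcommands over YAML configs).

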
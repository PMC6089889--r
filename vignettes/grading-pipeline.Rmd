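---
title: "Automated Gleason grading of TMA spots: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated Gleason grading of TMA spots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gleasonet)
```

## The problem and the pipeline

Gleason grading assigns prostate cancer specimens an architectural grade:
pattern 3 (well-formed, separated glands), pattern 4 (fused, cribriform or
poorly formed glands) and pattern 5 (sheets or single cells without gland
formation). The composite score is the sum of the most and second-most
predominant patterns (6–10); specimens without cancer are benign. Manual
grading is laborious and has limited inter-pathologist reproducibility,
which motivates automated annotation of tissue-microarray (TMA) spot
images.

`gleasonet` implements the full pipeline:

1. **Tissue detection** (`detect_tissue()`): Gaussian filtering of the
   luminance image, Otsu thresholding (tissue is the darker class on a
   white background), then dilation followed by erosion with a disc.
2. **Patch extraction** (`extract_patches()`): 750 × 750 px patches on a
   375-px grid; a patch is labelled by the unique non-zero annotation
   inside its central 250 × 250 window and discarded if that window holds
   no or several annotation classes.
3. **Patch classification** (`build_network()`, `train_classifier()`): a
   depthwise-separable convolutional network (width multiplier
   $\alpha$, default 0.5: 16 up to 512 channels; $\alpha = 1$ gives
   32–1024) over 224 × 224 inputs, trained with balanced mini-batches of
   32, cross-entropy loss, and either Adam (learning rate $10^{-3}$, the
   from-scratch regime) or SGD with Nesterov momentum 0.9 (learning rate
   $10^{-4}$, the fine-tuning regime for externally injected weights).
   Augmentation: resize to 250, random 224 crop, right-angle rotations,
   flips, mild colour jitter.
4. **Pixel-level annotation** (`convert_to_fcn()`,
   `probability_map()`): the global average pooling layer becomes a local
   $k \times k$ average pooling with stride 1 ($k = 7$ for 224-px
   inputs), the classifier becomes a 1 × 1 convolution, softmax is applied
   per location and a factor-32 nearest-neighbour upsampling restores the
   input resolution.
5. **Scoring** (`class_weights()`, `assign_score()`): per-class weights
   $w^k = \sum_{ij} o^k_{ij} / \sum_{ijk} o^k_{ij}$ over tissue pixels,
   thresholded as $w^k_{final} = I\{w^k > c\}\, w^k$ with $c = 0.25$;
   primary and secondary patterns are the two largest surviving cancer
   weights and the composite score their sum; a spot with no surviving
   cancer pattern is benign.
6. **Evaluation** (`quadratic_kappa()`, `macro_recall()`,
   `consensus_precision()`): quadratic weighted kappa
   $\kappa = 1 - \sum w_{ij} O_{ij} / \sum w_{ij} E_{ij}$,
   $w_{ij} = (i-j)^2/(N-1)^2$, with expected counts from the marginals.
7. **Interpretation** (`class_activation_map()`): class activation maps of
   patches classified correctly with probability > 0.8 (strict).
8. **Survival** (`stratification_report()`): risk groups low (score ≤ 6,
   including benign), intermediate (7), high (≥ 8); Kaplan–Meier curves
   with log-transformed Greenwood 95% bands; pairwise two-tailed logrank
   tests with Benjamini–Hochberg correction over the three comparisons.

## The synthetic cohort generator

No clinical images ship with the package; `generate_spot()` renders
synthetic TMA spots so that every stage runs and is testable offline. A
spot is a circular tissue disc (radius 0.47 of the raster side) on a light
background, partitioned into angular sectors that realize the requested
region area fractions — sector areas are essentially exact, which makes
ground-truth scores exact by construction. Textures encode the
architectural criteria, not histological realism:

* **Benign**: sparse large glands (thin epithelial rim, wide white lumen);
* **G3**: many small, well-separated ring glands;
* **G4**: random-walk chains of fused glands plus cribriform discs
  (epithelial sheets pierced by small round lumens);
* **G5**: dense nuclear speckle without lumens.

Because the patterns differ in gland count, lumen area and stained
fraction, a texture classifier is learnable from moderate data; the test
suite asserts this separability directly. What the generator deliberately
does *not* emulate: stain variability and artefacts, nucleus-level ground
truth, stromal/epithelial segmentation, intermediate or ambiguous
morphologies, and spatial autocorrelation of grades across a microarray.
Passing tests therefore demonstrate the correctness of the pipeline's
machinery, not clinical-grade performance on real H&E.

`generate_cohort()` draws composite scores from a configurable mix (the
default loosely imitates a score-balanced test cohort) and realizes each
score with region recipes whose fractions stay well clear of the
$c = 0.25$ threshold (e.g. score 7 = G3 0.45 + G4 0.35 + benign 0.15).
`generate_pattern_cohort()` renders *region-pure* spots (one pattern per
spot, deterministic largest-remainder class composition) — the training
condition, mirroring the fact that training patches come from within
pathologist-delineated regions, while mixed-score spots are the evaluation
condition. Survival times are exponential with the hazard multiplied by
`ratio` per risk tier (default 3; a per-score-unit variant is available)
and independent uniform censoring on [0, 120] months — the simplest model
with a controllable hazard ordering.

## Numerical and design choices

* **Network engine.** The depthwise-separable network, batch
  normalization, backpropagation and both optimizers are implemented in
  single-precision C++ (RcppArmadillo); GEMM-based pointwise convolutions
  and contiguous per-channel depthwise loops. Batch normalization uses
  $\epsilon = 10^{-3}$ and running-statistic decay 0.9; inference always
  uses running statistics, so predictions are independent of batch
  composition. Flush-to-zero arithmetic is enabled: subnormal activations
  otherwise dominate run time late in training. Strides follow the
  standard layout (blocks 2, 4, 6, 12); He initialization; dropout 0.2
  before the classifier.
* **Gradient verification.** Backpropagation was verified against central
  finite differences in a double-precision build of the same kernels
  (agreement to $10^{-8}$); the shipped single-precision engine is checked
  at the head of the network, where fp32 finite differences are well
  conditioned, and end-to-end by optimization tests.
* **Padding.** Convolutions use zero same-padding with the trailing-pad
  convention. The patch-equivalence oracle feeds single patches through
  the converted network directly, where the centre pooling window equals
  global pooling exactly.
* **Seamless tiling.** Whole-spot inference embeds the image in a neutral
  margin (the dataset-mean colour) and extracts every tile with a halo of
  5 cells — the convolutional stack's 315-px receptive field radius
  rounded up to cells — so the stitched feature map is identical for any
  tiling. Stride-1 pooling averages over the in-bounds window only. A
  `border_px` attribute (half the input size) flags the band where the
  receptive field extends past the image.
* **Scale-matched inference.** Training patches are downscaled by
  `resize_to / patch_size` (250/750 = 1/3); `probability_map()` therefore
  shrinks the spot by `training_scale(geometry)` before the FCN so tissue
  textures appear at the scale the classifier saw, and maps back to native
  pixels by nearest neighbour.
* **Scoring edge cases.** The benign channel enters the denominator of
  $w^k$ but never the primary/secondary selection; a spot is benign iff no
  cancer pattern exceeds $c$. The strict inequality zeroes all classes
  only in the all-equal tie, contradicting the rule's stated guarantee;
  the default `tie_rule = "argmax"` keeps the largest-weight class (the
  literal `"strict"` behaviour is available). Exact ties between cancer
  patterns resolve to the lower (less aggressive) pattern.
* **Spot-level ordinal embedding.** Kappa over spot scores uses ranks
  (Benign, 6, 7, 8, 9, 10) → 1…6 with unit spacing; treating benign as
  rank-adjacent to score 6 is the simplest consistent reading and is
  flagged in evaluation reports.
* **Survival details.** Kaplan–Meier and logrank computations are
  delegated to the `survival` package (log-transformed Greenwood bands;
  censored subjects at a tied time remain at risk); tests validate them
  against hand product-limit arithmetic and a permutation reference.
  Benign spots are grouped with low risk. BH correction spans the three
  pairwise comparisons.
* **Geometry profiles.** The `"half"` profile (spot 1550 px, patches
  375/188/125) with `resize_to = 107`, `crop_size = 96` keeps the
  resize-to-crop ratio of the full protocol at a 96-px network input. The
  package's desk-scale experiments — and the reported numbers — use
  $\alpha = 0.25$, 96-px inputs, 16 region-pure training spots (~850
  patches), 2000 balanced iterations, 5 holdout spots and a 10-spot mixed
  test cohort; these sizes give stable results while a full run remains a
  matter of minutes on one CPU. The full profile (3100-px spots,
  $\alpha = 0.5$, 224-px inputs, 50 000 iterations) is the configured
  default of `pipeline_config("full")`.

## Limitations

* The synthetic textures are far easier than real H&E; desk-scale recall
  (≈ 0.9) says nothing about performance on clinical cohorts.
* ImageNet pre-training is exposed only as a weight-injection hook
  (`set_model_weights()` + the fine-tune regime); no pretrained weights
  ship with the package, so the finding that fine-tuning outperforms
  training from scratch is not reproduced.
* Single-threaded CPU training only; the engine is sized for the selected
  architecture family, not a general deep-learning framework.
* Artefact and stroma-specific exclusion, percent-pattern or tertiary
  reporting, and Grade Group conversion are out of scope.
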
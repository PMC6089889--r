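# gleasonet

Automated Gleason grading of prostate tissue-microarray (TMA) spot images,
end to end: a four-class convolutional patch classifier (benign, Gleason
pattern 3, 4, 5) is trained on annotated subregions, converted into a fully
convolutional pixel-level annotator, and its per-class probability maps are
aggregated into composite Gleason scores, which are evaluated by ordinal
agreement statistics and survival stratification. A synthetic TMA-spot
generator with ground-truth region masks and linked survival records makes
every stage runnable and testable without any clinical data.

The package is aimed at computational-pathology researchers and method
developers who want a complete, dependency-light reference implementation
of this grading pipeline in R.

## The method

* **Patch classifier.** A depthwise-separable convolutional network with
  width multiplier α (α = 0.5: channel widths 16 → 512; α = 1: 32 → 1024)
  over 224 × 224 inputs; global average pooling, dropout 0.2, softmax over
  the four classes. Training uses balanced mini-batches of 32 (8 per
  class), cross-entropy loss, and Adam (lr 0.001) from scratch or SGD with
  Nesterov momentum 0.9 (lr 0.0001) for fine-tuning injected weights.
  Patches are 750 × 750 px on a 375-px grid, labelled by the unique
  annotation in their central 250 × 250 window (mixed or empty windows are
  discarded), resized to 250 and randomly cropped to 224 with rotations,
  flips and colour jitter.
* **Pixel-level annotator.** The trained network is converted to a fully
  convolutional one: global pooling → 7 × 7 average pooling with stride 1,
  classifier → 1 × 1 convolution, softmax per location, ×32 upsampling.
  Applied tile-wise with receptive-field halos, it yields per-pixel class
  probabilities o<sup>k</sup><sub>ij</sub> over the detected tissue.
* **Scoring rule.** Per-class weights
  w<sup>k</sup> = Σ<sub>ij</sub> o<sup>k</sup><sub>ij</sub> / Σ<sub>ijk</sub> o<sup>k</sup><sub>ij</sub>,
  thresholded as w<sup>k</sup><sub>final</sub> = 𝕀{w<sup>k</sup> > c}·w<sup>k</sup>
  with c = 0.25. The primary and secondary Gleason patterns are the two
  largest surviving cancer weights; the composite score is their sum, and a
  spot with no surviving cancer pattern is benign.
* **Evaluation.** Quadratic weighted kappa
  κ = 1 − Σ w<sub>ij</sub>O<sub>ij</sub> / Σ w<sub>ij</sub>E<sub>ij</sub>
  with w<sub>ij</sub> = (i−j)²/(N−1)², macro-average recall, and per-class
  precision against the consensus of two raters.
* **Survival.** Risk groups low (score ≤ 6), intermediate (7), high (≥ 8);
  Kaplan–Meier curves with 95% bands and pairwise two-tailed logrank tests
  with Benjamini–Hochberg correction.

See the methods vignette (`vignettes/grading-pipeline.Rmd`) for the
synthetic-data model, numerical choices and design decisions.

## Worked example

Score a synthetic cohort from ground-truth probability-map fixtures and
stratify survival:

```r
library(gleasonet)

co <- generate_cohort(40, spot_size_px = 512, seed = 42, keep_images = FALSE)
maps <- lapply(co$spots, function(s)
  one_hot_probability_map(s$mask, smoothing = 0.2, s$spot_id))

class_weights(maps[[1]])
#> Benign     G3     G4     G5
#>  0.800  0.067  0.067  0.067
assign_score(class_weights(maps[[1]]))
#> <gleason_assignment> Benign
#>   weights: Benign 0.800, G3 0.067, G4 0.067, G5 0.067

scores <- score_cohort(maps, scoring_config(threshold = 0.25))
head(scores, 3)
#> # A tibble: 3 × 4
#>   spot_id   primary secondary score
#>   <chr>       <int>     <int> <int>
#> 1 spot_0001      NA        NA     0
#> 2 spot_0002      NA        NA     0
#> 3 spot_0003       3         4     7
```

Spot 1 is benign (weight 0.80 on the benign channel; no cancer pattern
exceeds c = 0.25); spot 3 carries Gleason 3 + 4 = 7. Agreement with the
ground truth and survival separation of the score-derived risk groups:

```r
lab <- function(s) ifelse(s == 0, "Benign", as.character(s))
glance(rater_agreement(lab(co$clinical$true_score), lab(scores$score),
                       c("Benign", "6", "7", "8", "9", "10")))
#> # A tibble: 1 × 3
#>       n kappa macro_recall
#>   <int> <dbl>        <dbl>
#> 1    40     1            1

tidy(stratification_report(scores, co$clinical))
#> # A tibble: 3 × 6
#>   group_a      group_b      statistic  p_value available p_adjusted
#> 1 low          intermediate      6.05 0.0139   TRUE         0.0209
#> 2 low          high             12.0  0.000526 TRUE         0.00158
#> 3 intermediate high              1.50 0.221    TRUE         0.221
```

Scoring the label-smoothed fixture maps recovers every true score
(kappa = 1), and the simulated hazard ordering (ratio 3 per risk tier)
separates the low- and high-risk groups (BH-adjusted logrank p ≈ 0.002 on
this 40-spot cohort).

Training the classifier and producing probability maps from images follows
the same grammar (`extract_cohort_patches()` → `train_classifier()` →
`convert_to_fcn()` → `probability_map()`); `run_pipeline()` orchestrates
all stages, and `inst/cli/gleason-pipeline.R` is a thin shell entry point.

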
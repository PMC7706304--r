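# spikeseg

Semantic segmentation of wheat spike (ear) regions in RGB field plot
images, for crop phenotyping: given plot photographs across the season
(booting through grain filling), label every pixel as *spike* or
*background* so that yield-related traits — spikes per unit area, ear
emergence timing — can be quantified instead of scored by eye.

The package implements the full FCN-8 pipeline in R with hand-written
forward/backward passes (Rcpp/RcppArmadillo, im2col + BLAS):

* **Network** — VGG16-style encoder (five blocks of 3×3 convolutions,
  depths 64/128/256/512/512, max-pool after each block), fully
  convolutional head (conv6 7×7 and conv7 1×1, depth 4096, dropout 0.5),
  and a skip decoder: 1×1 score layers on conv7/pool4/pool3, learned ×2
  upsampling with element-wise fusion twice, a final learned ×8 upsampling
  and a per-pixel 2-class softmax. A `width` multiplier scales every
  filter count for desk-scale work; width 1 is the full ~134M-parameter
  architecture.
* **Training** — pixelwise cross-entropy `L = −Σ_j t_j log y_j`, momentum
  SGD `v_t = γ v_{t−1} + η ∇_θ J`, `θ ← θ − v_t` (η₀ = 0.001, γ = 0.9,
  minibatch 20), inverse-time decay `η_e = η₀/(1 + 0.0016 e)`, He
  initialisation (σ = √(2/n_l), zero biases), early stopping on
  validation cost with patience 20, and a pretrained-encoder loading hook
  for transfer learning.
* **Inference** — sliding-window tiling with edge clamping; overlapping
  tile probabilities averaged into an h × w × 2 prediction map; argmax
  mask with ties to background.
* **Evaluation** — pooled-confusion GA / per-class accuracy / MA /
  IoU / MIoU (`IoU = tp/(tp+fp+fn)`), per-growth-stage reports,
  micro-averaged precision–recall curves, and encoder activation-map
  inspection.
* **Synthetic scenes** — a generator for wheat-plot-like images (sky,
  textured canopy, stems, soil, grass-like distractors, illumination and
  noise) with exact spike masks, so the entire pipeline is testable
  without field data.

## Worked example

Train the desk-scale model on synthetic scenes and evaluate it per growth
stage (about 4 minutes on one CPU):

```r
library(spikeseg)
bench <- synthetic_benchmark(seed = 7, verbose = FALSE)

round(bench$holdout_iou, 3)
#> [1] 0.771

print(bench$stage_report[, c("group", "GA", "MA", "spike_iou")], digits = 3)
#>           group    GA    MA spike_iou
#> 1       booting 0.917 0.575   0.00818
#> 2       heading 0.901 0.913   0.21770
#> 3     flowering 0.910 0.909   0.56038
#> 4 grain_filling 0.932 0.921   0.63816
#> 5       overall 0.915 0.909   0.43637
```

The held-out spike IoU (0.771, pooled over 50 unseen 96×96 tiles) shows
the width-1/8 network recovers the synthetic spikes it was trained to
find. The stage table shows the pattern field studies report: spike IoU
rises as spikes develop (booting is nearly hopeless, grain filling best),
while *global* accuracy is flattering at booting precisely because almost
everything there is background — the reason GA alone is never trusted for
this task.

Predict on a full image and inspect what the encoder responds to:

```r
scene <- generate_scene("flowering", seed = 42)
mask  <- predict(bench$fit, scene$image, window = 96)
maps  <- activation_maps(bench$fit, scene$image, blocks = c(1, 3, 5))
```

A thin command-line wrapper covers the same workflow
(`inst/cli/spikeseg synth|sample|train|predict|evaluate --config run.yaml`).

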
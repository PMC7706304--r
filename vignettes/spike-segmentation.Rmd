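---
title: "Segmenting wheat spikes with an FCN-8: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting wheat spikes with an FCN-8: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(spikeseg)
```

## The problem

Wheat yield traits — spikes per unit area, spikelets per spike, timing of
ear emergence — are still mostly scored by eye in the field. A first step
toward automating them is semantic segmentation: deciding, for every pixel
of an RGB plot image, whether it belongs to a spike (ear) or to the
background of canopy, soil, sky and incidental clutter. Field imagery makes
this hard: illumination swings from overcast to over-exposed, spikes at
booting are barely emerged slivers, and grass patches share both the hue
and the fine texture of spikes.

`spikeseg` implements a complete, desk-testable pipeline for this task:
an FCN-8 encoder–decoder network, its full training recipe, sliding-window
inference over large plot images, the standard segmentation metrics, and a
synthetic scene generator that provides exact ground truth so every stage
can be exercised and verified without field data.

## The model

The network is the classic FCN-8 built on a VGG16-style encoder:

* **Encoder** — five blocks of 3×3, stride-1 convolutions (2, 2, 3, 3, 3
  layers; 13 in total) with filter depths 64/128/256/512/512, ReLU after
  every convolution and a 2×2, stride-2 max-pool after every block. Each
  pool halves the spatial extent, so the block outputs P1…P5 live at
  1/2 … 1/32 of input resolution.
* **Fully convolutional head** — the former fully connected layers become
  convolutions: conv6 (7×7, depth 4096) and conv7 (1×1, depth 4096), each
  followed by ReLU and dropout (p = 0.5). The original 1000-class
  classifier layer is dropped; this task has two classes.
* **Skip decoder** — 1×1 score layers map conv7, P4 and P3 to per-class
  maps. The conv7 score is upsampled ×2 by a learned transposed
  convolution (kernel 4, stride 2), centre-cropped to the P4 score's size
  and fused by element-wise summation; the result is upsampled ×2 again
  and fused with the P3 score; a final learned ×8 upsampling (kernel 16,
  stride 8) restores the input resolution. Fusing fine, shallow score maps
  with coarse, deep ones is what recovers spike boundary detail.
* **Softmax** — a per-pixel 2-class softmax yields the probability field.

`arch_config(width = )` scales every filter count; width 1 is the full
architecture (about 134M parameters), width 1/8 the desk-scale variant the
test-bench trains. Shapes are width-independent, which the suite exploits.

Two wrinkles deserve a note. The cited architecture has 13 convolutional
layers by its own block listing (2+2+3+3+3); descriptions sometimes
miscount this as 12, and we implement the self-consistent 13. And the He
initialisation we use draws weights with standard deviation
`sqrt(2 / n_l)` for fan-in `n_l` — the variance, not the deviation, is
`2 / n_l`; biases start at zero. Upsampling kernels are initialised to
bilinear interpolation rather than noise, the standard starting point for
learned upsampling: random upsampling kernels destroy the spatial
correspondence the skip fusion relies on.

### Spatial bookkeeping

All convolutions use same-padding, so only the pools change extent and the
decoder's arithmetic is exact: with kernel 4 / stride 2 / pad 1 the ×2
transposed convolutions produce exactly twice their input, and kernel 16 /
stride 8 / pad 4 exactly eight times. The centre-crop steps the
architecture specifies therefore trim nothing for inputs whose sides are
multiples of 32 — we keep them because they define behaviour, and we
require input extents divisible by 32 rather than silently padding: the
sampling and tiling layers only ever produce such windows (96, 128, 512),
and padding would invent pixel content at borders.

## Training recipe

The recipe is implemented exactly as specified by its hyperparameter
table, each piece separately testable:

* **Loss** — mean per-pixel cross-entropy in nats, probabilities clipped
  to `[1e-7, 1 - 1e-7]`. Averaging over pixels and batch makes the
  learning rate independent of batch and window size. There is no class
  weighting: imbalance is addressed at evaluation, not by reweighting the
  loss.
* **Optimizer** — minibatch SGD with momentum,
  `v ← γ v + η ∇θ J; θ ← θ − v`, γ = 0.9, minibatch 20. The update is
  implemented directly (not via a backend's optimizer) so the recurrence
  can be checked against its closed form `v_k = ηg(1−γ^k)/(1−γ)`.
* **Schedule** — η₀ = 0.001 with "decay 0.0016 per epoch". That phrase
  admits two readings; we take inverse-time decay
  `η_e = η₀ / (1 + 0.0016 e)` as canonical (the standard convention the
  printed constants fit) and expose multiplicative decay as an option.
* **Early stopping** — validation cost is recorded each epoch (dropout
  off); if it has not decreased for 20 consecutive epochs, training stops
  and the weights of the lowest-validation-cost epoch are restored. The
  training history keeps a per-epoch parameter-norm fingerprint, which is
  how the tests prove the restored weights really are the best epoch's.
* **Transfer hook** — `load_pretrained_encoder()` replaces exactly the 13
  encoder convolution tensors from a named weight store and reports
  skipped names; shape conflicts fail loudly, naming the layer. Whether to
  fine-tune everything afterwards or freeze the encoder is exposed via
  `freeze_encoder`; full fine-tuning is the default, matching the usual
  practice when the new task's imagery differs strongly from the
  pretraining corpus. Actual pretrained weights are an external input —
  the package ships only the loading contract, which is what the tests
  pin down.

Gradients are computed by hand-written backward passes for every layer
(im2col/BLAS convolutions, pool argmax scatter, transposed-convolution
adjoints), verified against central finite differences to ~1e-7 relative
error in the development checks and exercised indirectly by every training
test.

## Inference

Plot images are far larger than a trainable window, so prediction slides a
window (default 512, the better-performing training size) across the image
at a configurable stride. The tiling rule places offsets at stride
multiples and clamps a final row/column of tiles to the image edge, so
coverage is total and no padding is fabricated. Overlapping predictions
are combined by averaging probabilities — not logits, not max — because
averaging keeps every pixel on the probability simplex, is
order-independent, and makes the stitched map equal a brute-force
accumulate-and-divide oracle to machine precision. The final mask is the
per-pixel argmax with exact ties going to background.

## Evaluation

All metrics derive from pooled pixel confusion counts: global accuracy
`GA = Σ n_ii / n_p`, per-class accuracy `n_ii / t_i` and its mean MA, and
per-class IoU `tp / (tp + fp + fn)` with its mean MIoU. Three conventions
matter and are tested:

* **Pooling, not averaging.** Group and overall rows pool confusion over
  all member pixels; the overall row is therefore not the mean of group
  rows. On stage-grouped data the two genuinely differ, and pooling is
  what makes a dataset-level row consistent with its own summary table.
* **Undefined classes are excluded, not invented.** A stage with no true
  spike pixels has undefined spike accuracy; we exclude it from MA/MIoU
  and flag the exclusion rather than scoring 0 or 1, which would bias
  early-stage reports in opposite directions.
* **GA is not enough.** Under 1% spike prevalence an all-background
  prediction scores GA = 0.99 with spike IoU = 0 — exactly the divergence
  that makes booting-stage GA look flattering. The package reports both
  families side by side, and precision–recall curves (micro-averaged over
  a group's pixels, 101 thresholds) for threshold-free comparison.

## The synthetic scene generator

`generate_scene()` composites a sky band, a textured green canopy with
stem strokes, soil patches, and spikes drawn as textured ellipses with awn
strokes; the mask is exactly the union of rendered spike footprints (awns
included — thin-structure labels are ambiguous in real annotation, and
including them keeps the ground truth self-consistent). Distractor grass
patches share the canopy hue but carry a spike-like stripe frequency,
reproducing the false-positive regime real fields exhibit; a global
multiplicative illumination field with a smooth gradient (clipping in
"sunny" scenes) and additive Gaussian noise emulate exposure variation.
Stage defaults order expected spike coverage as booting < heading <
flowering ≈ grain filling, with hue shifting toward gold late in the
season; real per-stage spike prevalence is not documented quantitatively
anywhere we know of, so these fractions are package choices, exposed in
`scene_params()` and fixed once.

`generate_season()` writes image/mask pairs plus a manifest, realising a
stage mix by largest-remainder rounding (the default mix 12/22/37/19 of 90
mirrors a realistic campaign in which flowering is imaged most). Years map
to split roles (2015 train, 2016 validation, 2017 test) but a manifest
`role` column overrides this — the year assignment is a study convention,
not part of the method.

What passing on synthetic scenes does **not** show: robustness to real
sensor noise, occlusion by leaves, true canopy geometry, weather, or the
full variability of field illumination. The generator's purpose is
verification — exact masks, controllable difficulty, determinism — not
photorealism; results on it bound nothing about field data.

## The desk-scale benchmark

`synthetic_benchmark()` is the package's end-to-end check: a width-1/8
network, He-initialised, trained on 200 synthetic 96×96 tiles sampled from
flowering/grain-filling scenes with the standard hyperparameters
(minibatch reduced to 8 for the small problem), early stopping as usual,
at most 15 epochs — the run converges well within that budget at this
scale. It reports spike IoU pooled over 50 held-out tiles from unseen
scenes and a per-stage report on a fresh synthetic season (3 scenes per
stage, 192×192, window 96). Problem sizes were chosen so the whole
benchmark runs in minutes on one CPU while still exercising every stage of
the pipeline; the expectation, encoded in the acceptance tests, is
held-out spike IoU ≥ 0.6 and booting scoring below flowering — the same
qualitative ordering field studies report, for the same reason (barely
emerged spikes offer few pixels and weak texture evidence).

## Numerical choices and degenerate inputs

* Probability clipping at 1e-7 bounds the loss; a perfect prediction costs
  ≤ 1.2e-7 nats.
* Argmax ties go to background, making the all-uniform map decode to
  all-background.
* Masks binarize 8-bit intensities at ≥ 128, robust to anti-aliased
  annotation exports; RGB mask files must be channel-identical.
* Grayscale images are replicated to 3 channels; alpha is dropped; more
  channels are an error.
* Non-finite gradients abort training with a diagnostic rather than
  silently corrupting the parameters.
* All randomness (initialisation, sampling, shuffling, dropout, scenes)
  is seed-pinned and restores the caller's RNG state.

## Known limitations

* No data augmentation, adaptive optimizers, warm-up, or CRF-style
  post-processing — deliberately out of scope of the recipe implemented.
* The full-width network is provided and shape/parameter-verified, but
  training it to field-grade accuracy requires GPU-scale compute and real
  annotated imagery; the package's quantitative claims are confined to
  the synthetic benchmark.
* FCN-16/FCN-32 exist only as ablation behaviour (zeroing skip branches),
  not as first-class variants.
* Inference requires window sizes that are multiples of 32; arbitrary
  image sizes are handled by clamped tiling, not by padding.
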
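---
title: "Point-supervised ear counting: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Point-supervised ear counting: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`earcount` counts dense plant organs — rice ears in fixed-area quadrat
images — from point annotations: one marked pixel per ear, no boxes, no
masks. This vignette is the package's own account of the method: the
model and its assumptions, the parameters that matter, what the
synthetic data generator does and does not emulate, the numerical
choices, and the known limitations.

## 1. The counting model

A fully convolutional network maps an H×W RGB image to an H×W×2
per-pixel softmax `S` over {background, ear}. Inference thresholds at
the argmax (ties at probability exactly 0.5 go to background), labels
the connected components of the foreground, and reports the number of
blobs as the count. The model is therefore not a segmenter in the usual
sense: it only needs to place *one* blob inside each ear, not to trace
its outline.

Training uses the localization-counting loss, the sum of four terms:

* **image-level** — the most confident pixel of every present class is
  pulled toward certainty, and the best ear pixel is suppressed in
  ear-free images. With two classes the "absent ear" branch
  `-log(1 - max S_ear)` is identical to `-log S_bg` at the ear-argmax
  pixel, which is how the gradient is implemented.
* **point-level** — negative log ear-probability at the annotated
  pixels only; everything unlabeled is ignored, which is what makes
  single-pixel supervision sufficient.
* **split** — wherever a predicted blob covers ≥ 2 annotation points, a
  marker-seeded watershed over the topography `-S_ear` (seeds at the
  points, restricted to the blob) produces ridge pixels; the loss
  pushes those ridge pixels to background with weight equal to the
  blob's point count. One published rendering of this term reads
  "mean of S over the boundary with no logarithm", which contradicts
  its own prose (the boundary is to be *classified as background*, so a
  log-likelihood is needed) and collides with the false-positive term's
  symbol; this package implements the log form with point-count
  weighting, and keeps the printed rendering available as
  `variant = "printed"` for comparison.
* **false-positive** — negative log background-probability over every
  pixel of blobs containing no point, which suppresses spurious
  detections.

All four terms are unnormalised sums, with the per-pixel loss clamped
at `log(1e-12)`. Whether the split and false-positive terms should be
normalised by their pixel counts is genuinely underdetermined; the
unnormalised sums are the default here and the gradient-clipping
described below absorbs their scale.

## 2. Backbones and training

Three backbones share one layer framework (convolution via im2col and
BLAS, ReLU, 2×2 max-pooling, bilinear upsampling, spatial batch norm,
residual blocks), all ending in a 1×1 two-class head and returning
full-resolution probabilities:

* `tiny` — four convolutions around a single 2× pool/upsample pair,
  ~7.5k parameters. Every test and the acceptance runs train this one;
  it exists so that from-scratch training is a desk-scale experiment.
* `vgg16-fcn` — the thirteen VGG-16 convolution layers with a 1×1
  classifier at stride 32 and a 32× bilinear upsample (FCN-32s layout).
* `resnet50-fcn` — the (3,4,6,3) bottleneck stages of ResNet-50. Batch
  norm uses the batch-size-1 form (per-channel statistics over space),
  matching the training regime; the stem pool is 2×2/stride 2, the one
  simplification this framework makes to the stem.

The optimizer is plain SGD with momentum 0.9 and weight decay 5e-4 over
single images (batch size 1) at a fixed learning rate — momentum and
weight decay presuppose an SGD host, and no schedule is used because
none is needed at this scale. The default learning rate (1e-5) is the
fine-tuning regime appropriate to a pretrained backbone (`pretrained =`
accepts a serialized model); training `tiny` from scratch wants ~1e-4.
Larger steps (3e-4 and above) can converge on easy imagery but sit near
a stability edge: once blobs merge, the split term's spiky gradients
plus momentum push the optimizer into collapse-and-recover cycles, so
1e-4 is the rate all of the package's from-scratch experiments use.

Two numerical choices matter for from-scratch stability, both visible
in the training logs if disabled:

* **Background-prior head initialisation.** The classifier head starts
  with bias (+2, −2) and weights scaled by 0.01, so the untrained model
  predicts background everywhere. Started from a random head instead,
  half the image is foreground, the first images' split/false-positive
  terms emit gradients orders of magnitude above the point terms, and
  SGD-with-momentum collapses the ear channel into a dead all-background
  state it cannot leave. With the prior, blobs grow outward from the
  annotated pixels and the split/FP terms activate only once real blobs
  exist. (The same device is standard in dense detection heads.)
* **Gradient clipping.** The split term's magnitude scales with ridge
  length × point count, so a single image whose blobs momentarily merge
  can still dominate an epoch. The per-image logit gradient is clipped
  to Euclidean norm 25 (`max_grad_norm`), preserving direction.

Gradients of the loss with respect to the logits use the exact
cross-entropy form `weight · (S − e_class)` per selected pixel, bounded
even where probabilities underflow; the analytic `dL/dS` (used by the
finite-difference tests) agrees with it through the softmax Jacobian
wherever the clamp is inactive.

## 3. The seeded watershed

The split term needs instance boundaries from markers. The watershed
here has exactly specified semantics so that an independent brute-force
implementation can verify it: elevations within the region are
quantized into 256 bins; a monotone water level starts at the lowest
frontier bin; each iteration simultaneously floods all frontier pixels
at or below the level, assigning a pixel to the unique neighbouring
basin or marking it as ridge when ≥ 2 distinct basins touch it.
Synchronous updates make the result independent of pixel visiting
order; wavefronts advance one ring per iteration, so two seeds in a
uniform bar meet at the central column — the ridge. Blob analysis and
the watershed default to 8-connectivity (dense canopies merge more
readily; 4 is available), and connected-component labeling is a
vectorized min-label propagation checked against a flood-fill oracle —
the labeling in EBImage is fixed at 4-connectivity, hence the in-house
routine.

## 4. Quadrat preprocessing

Field protocols fix the sampled area with a red square frame. Frame
detection follows a ray-casting scheme: from two points per side,
offset ±25% of the image size from the centre, rays walk outward in
quarter-pixel steps until they meet a red pixel (HSV window: hue within
20° of red, saturation ≥ 0.45, value ≥ 0.25 — thresholds are
arguments); the two hits define each side's inner-edge line and
adjacent lines intersect in sub-pixel corners. The wide ±25% baseline
matters: hits carry ±½-pixel quantisation error, and corner error grows
with the ratio of corner distance to ray-pair separation. Rectification
maps the detected quadrilateral to a full rectangle with a homography
(align-corners convention, bilinear sampling) and transports annotation
points through the same map.

Augmentation is deliberately minimal: horizontal flip and one 90°
counter-clockwise rotation, giving the ×2 and ×3 dataset sizes. Both
are raster bijections, so annotation transport is exact and per-image
counts are conserved — the property the augmentation tests assert. The
90° angle is chosen because it keeps the raster rectangular with no
interpolation; the flip axis and rotation angle are otherwise free
choices. Resizing (e.g. to 25% for annotation) uses bilinear sampling
with the half-pixel-centre convention; points that collide after
rounding are deduplicated with a warning, since a one-pixel mask cannot
encode multiplicity — the same rule the mask writer applies.

## 5. The classical baseline

The non-learned comparator converts RGB to the HSI intensity
`(R+G+B)/3`, binarizes (Otsu by default), removes small components,
then erodes and dilates with a disk whose radius lies strictly between
the ear half-width and the leaf half-width — erasing thin ears,
retaining broad leaves — XORs the leaf image against the denoised
foreground to isolate the ears, removes residue, and counts components.
Its published description is garbled at the morphology step
("remove the ear with the expansion through corrosion"); the
erosion-then-dilation reading implemented here is the only mechanically
coherent one, flagged as a reading rather than asserted as authorial
intent. The committed fixture (`inst/extdata/baseline_six_ear.yaml`)
documents a configuration where the mechanism provably engages.

## 6. The synthetic field generator

No public point-annotated quadrat dataset exists to test against, so
the generator builds one with exact ground truth: a low-frequency
textured green canopy; ears as speckled yellow ellipses (length 10–16
px, width 3–5 px at 64×64 — the scale real ears occupy after the
protocol's 25% resize) with one annotation point per ear at the centre,
jittered by ≤ 20% of the minor axis; optional broad leaf blades;
optional red frame (ears strictly inside); global illumination in
[0.75, 1.15]; additive Gaussian noise. Three presets mirror a
clear/noisy/red-shifted quality grading of field photos. With
`overlap_fraction = 0` ears keep a one-pixel clearance so 8-connected
blobs stay distinct; raising it places ears adjacent or overlapping,
which is what exercises the split loss.

What it does **not** emulate: perspective and lens distortion, specular
highlights, wind blur, growth-stage phenology, and the long-tailed
occlusion patterns of real canopies. Passing tests on this imagery
demonstrates that the loss, optimization and counting chain are
correct and that the method recovers counts when its assumptions hold;
it does not certify field accuracy, which must be established on real
annotated photographs.

## 7. Problem sizes and study conditions

The package's own experiments, chosen once and used by both the test
suite and `scripts/acceptance.R`:

* augmentation cardinalities on 1100 synthetic 96×96 images (→ 2200 and
  3300);
* parameter recovery: `tiny`, 100 epochs, 80 training / 20 held-out
  64×64 images, counts uniform in [3, 12], no overlap, learning rate
  1e-4 — held-out MAE is compared against 1.5 and against the
  constant-mean-count predictor;
* red-frame recovery over 50 seeded 128×128 frames, half rotated up to
  ±15°, corner tolerance 2 px;
* baseline comparison on a 25-image suite of thin ears over broad
  leaves, where the trained LC pipeline must match or beat the
  classical counter's MAE; its model trains at 1e-4 for 60 epochs on 40
  images drawn from the same field model.

## 8. Known limitations

* Counting by connected components cannot separate ears whose predicted
  blobs merge *and* whose annotations fall in the same blob only at
  training time; at inference nothing splits a merged blob. Dense
  overlap beyond the training distribution will undercount.
* The accuracy-rate metric averages `1 - |error|/truth` and can go
  negative for gross errors; images with a true count of zero are
  excluded from it (division by zero) and reported separately. The
  range-normalised RMSE is undefined when all true counts coincide and
  is reported as `NA` with a warning.
* From-scratch training is only demonstrated for `tiny`; the deep
  backbones are provided for transfer-learning workflows and verified
  for shape, gradient-flow and determinism, not trained to convergence
  in the tests.
* Everything runs on one CPU in plain R; per-image training cost is
  ~60 ms at 64×64, which is ample for the package's experiments but not
  for production-scale training.
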
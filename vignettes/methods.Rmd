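---
title: "Counting pigs with an attention-augmented one-stage detector"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting pigs with an attention-augmented one-stage detector}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigdetect)
```

## The problem

Counting pigs in a finishing pen from fixed cameras is hard for exactly one
reason: pigs cluster. Bodies overlap, occlude each other, and blend into a
concrete floor of similar tone. `pigdetect` approaches counting as detection:
an anchor-based one-stage convolutional detector predicts a box for every
animal, duplicate boxes are removed by non-maximum suppression, and the
count is simply the number of surviving detections above a confidence
threshold. Detection-based counting has the advantage over density-map
regression that every counted animal is localized and can be audited
visually.

Two ingredients target the occlusion problem specifically:

* **Shuffle attention** blocks in the backbone re-weight features cheaply.
  The feature map is split into groups; half of each group passes through a
  *channel* gate (global average pooling followed by a per-channel sigmoid
  gate — *what* is informative), the other half through a *spatial* gate
  (group normalization followed by a per-channel affine and sigmoid gate —
  *where* is informative). A channel shuffle then interleaves channels
  across groups so information flows between them. The block adds only
  `3 C` parameters at width `C` (under 1% of a single 3×3 convolution at
  `C = 64`) and never amplifies an activation, since every gate lies in
  (0, 1).

* **Focal-CIoU** localization loss. The CIoU loss
  `1 − IoU + ρ²/c² + αv` penalizes overlap, center distance (normalized by
  the enclosing-box diagonal) and aspect-ratio disagreement. Its focal
  variant multiplies by `IoU^γ` (default `γ = 0.5`), so slots that already
  overlap their target — the scarce positive-leaning samples — dominate the
  regression signal rather than the many badly-overlapping ones.

## Model

The architecture is the familiar compact one-stage layout: a backbone of
Conv blocks (convolution, per-channel normalization, SiLU `x·σ(x)`), C3
cross-stage-partial blocks, and an SPPF pooling pyramid; a top-down (FPN)
plus bottom-up (PAN) neck; and three 1×1-convolution heads at strides 8, 16
and 32. Each head cell predicts, for each of 3 anchors: box offsets
`(tx, ty, tw, th)`, an objectness logit, and class logits. Shuffle-attention
blocks sit after each backbone C3 stage by default; the insertion list is
configuration, which is what makes the ablation arms (`plain`, `sa`, `fc`,
`sa_fc`) pure configuration.

Decoding is bounded in both directions:

* center: `bx = (2σ(tx) − 0.5 + col)·stride` — at zero logits a slot decodes
  to its cell center;
* size: `bw = anchor_w · (2σ(tw))²` — bounded by 4× the anchor, which is why
  target assignment uses a size-ratio filter of 4.

The objectness output is calibrated as `pr(obj) × IoU`: at positive slots
the confidence target is the IoU between the decoded box and its assigned
ground truth, recomputed each step and not differentiated through (a
fixed-1.0 target is available as `vbar_mode = "one"`).

## Loss and training

The composite loss is `L = L_loc + L_cls + L_conf`: Focal-CIoU summed over
positive slots, per-class binary cross-entropy at positives, and objectness
BCE with negatives down-weighted by `λ_noobj` (default 0.5 — the reference
training setup names the hyperparameter without a value, so the default
follows common practice; it is configurable). Probabilities are clamped at
`1e-7` before logs. Ground truths are assigned to the cell containing their
center on every scale and to every anchor within the size-ratio filter;
slot collisions go to the first ground truth in input order. The trainer
additionally enables *neighbor-cell assignment* (`neighbor_cells` in
`run_config()`, off by default in `assign_targets()`): the two adjacent
cells nearest the object's fractional center also become positives.
Because the center decode `2σ(tx) − 0.5` spans (−0.5, 1.5) cells, a
neighbor cell can still reach the true center; tripling the positives
roughly triples the localization and objectness signal per image, which
matters most in the short desk-scale runs.

Details that matter for a CPU trainer:

* **Backpropagation** is implemented in the package (im2col + GEMM
  convolution kernels in C++, hand-derived backward passes for every block
  including both attention branches and the channel shuffle). Gradients were
  verified against central finite differences for every layer type.
* **Normalization statistics.** Conv blocks normalize with the sample's own
  per-channel spatial statistics at both training and inference (instance
  normalization). Per-sample statistics keep single-image gradient
  accumulation exact and deterministic regardless of batch composition —
  the batch-size-independent variant of the usual batch normalization — and
  using the identical transform at inference means the network is evaluated
  exactly as it was trained, with no train/test statistics mismatch.
* **Box gradients** flow through an analytic BCE path for objectness and
  class terms, and central finite differences (step `1e-4`) through the
  smooth decode-and-CIoU composition for the four box outputs — at 8 scalar
  CIoU evaluations per positive slot this costs less than the convolutions
  and avoids hand-maintaining the long CIoU derivative. The focal weight
  `IoU^γ` is treated as a constant per step, for optimization stability.
* **Per-term gradient scaling.** For optimization, the localization
  gradient is normalized by the *sum of focal weights* `Σ IoU^γ` (so the
  focal factor redistributes the regression signal across positives without
  shrinking its overall magnitude; at `γ = 0` this reduces to the positive
  count), class gradients are averaged over positives, and objectness
  gradients are averaged over positive and negative slots separately, the
  negative side weighted by `λ_noobj` times a background-suppression gain
  (default 8). Without the separation, the ~25:1 slot-to-positive imbalance
  makes the positive objectness signal vanish at desk scale; without the
  background gain, false positives are suppressed too slowly. The
  *reported* loss components remain the plain sums, so ablations and
  logging stay comparable.
* **Weight averaging.** The returned model carries an exponential moving
  average of the weights (decay 0.999, ramped in over the first few hundred
  steps), the standard practice in one-stage-detector training; it both
  improves and stabilizes the end-of-run evaluation relative to the raw
  final SGD iterate, whose quality fluctuates with the last few noisy
  steps.
* **Optimizer**: SGD with momentum 0.937 on all parameters, weight decay
  5e-4 on convolution weights, initial learning rate 0.01 with linear
  warmup (3 epochs by default) and cosine decay. The learning-rate schedule
  is not specified by the reference setup; cosine-with-warmup is the
  package's choice. Heads start with 10×-reduced weights and a low
  objectness bias (≈8 expected objects per scale), so the initial
  prediction is "anchor prior at each cell center, mostly background" —
  the best-calibrated starting point.

The documented *reference preset* is 100 epochs, batch 16, learning rate
0.01, momentum 0.937 at 320×320 input. The *tiny preset*
(`tiny_config()`: 160 px input, 1/8 width, minimal depth) exists so the
whole pipeline — training included — runs on one CPU core in minutes; the
package's own validation uses it with 100 training scenes and 30 epochs.

## Synthetic pen scenes

The farm footage this class of detector is built for is not publicly
available, so the package ships a seeded generator of *statistically*
similar scenes: a textured concrete-like background (two camera-angle
presets: plain overhead texture, or oblique with stripes and a vertical
light gradient), global illumination jitter, and a truncated-Poisson number
of elliptical bodies (mean 15, clamped to 5–25 — matching the reported
average of about 15 animals per frame) with top-lit shading, random
orientation, and a cap on pairwise occlusion (default 40% of a body's
area). Labels are exact by construction: each ground-truth box is the tight
bounding box of that ellipse's own rasterized mask, unaffected by later
overpainting (amodal annotation, as a human annotator would draw it).

What the generator deliberately does **not** model: pig-shaped silhouettes
(heads, legs), motion blur, wire/railing occluders, dirt, and the
long-tailed illumination of real barns. Consequently, passing end-to-end
tests on synthetic scenes demonstrates that the *pipeline* — assignment,
loss, backpropagation, decoding, NMS, metrics, counting — is correct and
trainable, not that the tiny trained network would transfer to a real farm.
Absolute accuracy numbers on synthetic scenes are not comparable to numbers
reported on farm datasets.

Anchor priors are not hand-set: `kmeans_anchors()` clusters training-label
(w, h) pairs under an IoU distance (Lloyd iterations, seeded
initialization) and returns 9 area-sorted anchors, three per scale. The
body-size range (major half-axis 6–11% of the frame side, elongation
0.45–0.65) was chosen once as representative of near-overhead views of
finishing pigs and is not tuned per experiment.

## Evaluation stack

Matching is greedy per image in descending confidence; a detection claims
the unmatched ground truth of highest IoU and is a true positive when that
IoU exceeds 0.5. Precision, recall and F1 follow the usual definitions with
0-conventions when denominators vanish. AP is the all-points interpolated
area under the monotone precision envelope (`∫ P(R) dR`); a 101-point
sampled mode exists as a cross-check. mAP averages AP over classes (one
class here, so mAP = AP).

Counting accuracy is not defined in the reference literature, so both
candidate definitions are implemented: the default
`100·(1 − mean |pred − gt| / gt)` (mean relative count error, floored at
0), and an exact-match rate. Report tables round half-up to two decimals;
comparative columns use `100·(a − b)/b`.

NMS thresholds default to IoU 0.45 / confidence 0.25 — conventional values,
configurable everywhere they appear.

## Numerical choices and degenerate inputs

* Boxes are half-open pixel intervals (`width = x2 − x1`, no +1); IoU of two
  zero-area boxes is 0 by convention; corner/center conversion is exact.
* The aspect term is implemented in its squared form
  `v = (4/π²)(atan(w?/h?) − atan(w/h))²`, which keeps `v ∈ [0, 1]` and the
  weight `α = v/(1 − IoU + v)` well-defined; an unsquared variant seen in
  some write-ups can be negative and is exposed as `as_printed = TRUE` for
  comparison only. `α` is defined as 0 when `v = 0`, covering the
  `IoU = 1` corner.
* Group normalization in the spatial attention branch treats the branch's
  channels as a single normalization group with ε = 1e-5 and identity-
  initialized affine; the attention group count `G` defaults to 8 (neither
  is fixed by the reference description; both are configuration).
* Gate weights initialize to zero and gate biases to one (the reference
  shuffle-attention initialization), so a fresh attention block scales all
  activations uniformly by `σ(1) ≈ 0.73` — insertion never reshapes an
  untrained network's features asymmetrically, and gradients passing
  through the block are attenuated only mildly at the start of training.
* All tolerances in the package's own tests are absolute 1e-9 for exact
  geometry, 1e-6 for hand-evaluated losses.

## Known limitations

* Training is single-threaded and CPU-bound; the reference preset at
  320×320 is hours, not minutes. The tiny preset is the supported desk
  scale.
* Only single-class scenes are generated, matching the task; the metrics
  stack handles multiple classes but is exercised most heavily with one.
* The decoded-box expansion bound (4× anchor) means objects more than 4×
  larger than every anchor on every scale are undetectable by
  construction; `kmeans_anchors()` on representative labels avoids this.
* Mosaic augmentation composes same-coordinate crops of four scenes rather
  than re-scaling each tile; it preserves box geometry exactly but explores
  less scale variation than full mosaic pipelines.
```
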
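---
title: "Methods: a lightweight detection-transformer family for tomato ripeness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a lightweight detection-transformer family for tomato ripeness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripedetr)
```

## The problem and the model family

Selective harvesting of field tomatoes needs a detector that simultaneously
(i) localizes fruits under occlusion by leaves, fruit overlap and uneven
illumination, (ii) grades each fruit into one of five visual maturity
classes — `unripe`, `half_ripe`, `ripe`, `overripe`, `rotten` — and (iii)
runs in real time on modest hardware, which makes the parameter and FLOP
budget a first-class design target alongside accuracy.

`ripedetr` implements a configurable real-time detection-transformer
(RT-DETR-style) family for this task. The baseline is the ResNet-18 variant
of that architecture: a convolutional backbone emitting feature maps S3/S4/S5
at strides 8/16/32; a single transformer encoder layer applied only to S5
(attention-based intra-scale feature interaction, "AIFI"); a cross-scale
feature-fusion neck (CCFM) with top-down and bottom-up paths; and a DETR-type
decoder that selects its initial object queries from encoder tokens by a
localization-aware score, refines reference boxes iteratively, and is trained
with Hungarian bipartite matching plus denoising query groups. There is no
non-maximum suppression: the decoder predicts a set directly.

Four independent switches lighten or strengthen this baseline, and map 1:1
onto config flags:

* **`pconv_block`** — partial convolution in the backbone. A PConv applies a
  dense $k \times k$ convolution to only $c_p$ of the $c$ channels (a
  contiguous block; we convolve the *first* $c_p$, the choice with the
  contiguous-memory rationale) and copies the remaining $c - c_p$ channels
  through unchanged. Its cost is $h\,w\,k^2c_p^2$ multiply-accumulates, so at
  the default ratio $r = c_p/c = 1/4$ a PConv costs exactly $1/16$ of the
  dense convolution it replaces, and its memory access
  $h\,w\,2c_p + k^2c_p^2 \approx h\,w\,2c_p$ is a quarter of the dense
  access. In a PConv residual block we substitute the *second* 3×3
  convolution of each basic block; the residual topology, strides,
  normalization and activations are untouched. This is the one substitution
  whose accounting matches the published sizes of the model family this
  package reimplements: every stage of the ResNet-18 backbone then sheds the
  same ~3.5 GFLOPs at a 640×640 input, and converting the last three stages
  sheds 5.81 M parameters. The default lightweight setting converts stages
  2–4 and keeps stage 1 dense (early features need full spatial mixing).

* **`aifi_dat`** — deformable attention in the S5 encoder layer. A uniform
  reference grid of points (cell centers, normalized to $[-1,1]$; grid
  factor 1, i.e. full S5 resolution — S5 is only 20×20 at 640 input, so
  nothing is gained by downsampling it further) is shifted by offsets
  predicted from the query tokens by a small offset network (depthwise 5×5
  convolution → GELU → 1×1 projection to 2 channels, tanh-bounded to ±2 grid
  cells). Keys and values are bilinearly sampled at the shifted points with
  the kernel $g(a,b) = \max(0, 1-|a-b|)$, out-of-range points clamped to the
  border (the bilinear kernel's support ends there, and clamping avoids
  undefined reads). A learned relative-position bias table of size
  $(2H{-}1)(2W{-}1)$ per head is bilinearly interpolated at the continuous
  query–key displacement and added to the attention logits. Head count 8 and
  feed-forward width 1024 follow the baseline encoder layer; the whole
  switch adds ~0.02 M parameters.

* **`slimneck_ssff`** — a slim fusion neck plus scale-sequence fusion.
  GSConv halves the output channels with a dense convolution, produces the
  other half with a 5×5 depthwise convolution of the first half, concatenates
  and applies the fixed two-group channel shuffle (reshape to $2 \times c/2$,
  transpose, flatten — invertible). A GS-bottleneck sums a two-GSConv path
  with a depthwise shortcut; VoVGSCSP wraps GS-bottlenecks in a cross-stage
  block with one ("one-off") concatenation-aggregation. The scale-sequence
  module (SSFF) projects P3/P4/P5 to half width, resizes P4/P5 to stride-8
  resolution (nearest-neighbour, for determinism), stacks the three maps
  along a new scale axis, fuses them with a 3×1×1 3D convolution (valid over
  the scale axis, collapsing it), and expands back; its output is added into
  the stride-8 path, the one that carries small objects. Which baseline
  blocks to substitute is not uniquely determined by the family description;
  we fixed the subset by profiler calibration (below): the two lateral 1×1
  fusion convolutions become GSConv and the stride-16 bottom-up fusion block
  becomes VoVGSCSP (expansion 0.5, one bottleneck). Substituting *every*
  fusion block would shed ~2.2 M parameters, several times the published
  delta of this family (~0.4–0.7 M), so the conservative subset is the one
  consistent with the accounting.

* **`inner_eiou`** — the box regression loss. EIoU decomposes into overlap,
  center-distance and width–height terms:
  $\mathcal{L}_{EIoU} = (1 - \mathrm{IoU}) +
  \rho^2(b, b^{gt})/c_d^2 + (w - w^{gt})^2/C_w^2 + (h - h^{gt})^2/C_h^2$,
  with $c_d, C_w, C_h$ the diagonal, width and height of the smallest
  enclosing box. Inner-IoU evaluates the overlap on auxiliary boxes that
  share each box's center but are scaled by a factor `ratio`:
  $\mathrm{inter} = (\min(b_r^{gt}, b_r) - \max(b_l^{gt}, b_l))_+
  \,(\min(b_b^{gt}, b_b) - \max(b_t^{gt}, b_t))_+$,
  $\mathrm{union} = (w^{gt}h^{gt} + wh)\,\mathrm{ratio}^2 - \mathrm{inter}$,
  and $\mathcal{L}_{Inner\text{-}EIoU} = \mathcal{L}_{EIoU} + \mathrm{IoU} -
  \mathrm{IoU}_{inner}$. At `ratio = 1` the auxiliary boxes coincide with the
  originals and Inner-EIoU equals EIoU identically. `ratio < 1` rewards
  center alignment (helpful for small fruit); the default is 0.70, with the
  sweep values {0.70, 0.75, 0.80, 1.10, 1.13, 1.15} selectable. The raw
  inner intersection can be negative for disjoint auxiliary boxes; we clamp
  it at zero, the standard IoU convention. All losses come with analytic
  gradients (piecewise, following the min/max case structure), verified in
  the test suite against central finite differences.

## Profiling convention and calibration

The profiler is the package's accounting surface, and its convention is
frozen once for all configurations: one fused multiply–add = 2 FLOPs;
convolutions, linear maps and the two attention matrix products are counted;
normalization, activation, resize, softmax and pooling are not; PConv layers
cost $h\,w\,k^2c_p^2$ MACs with pass-through channels free. Accounting is a
pure function of architecture and input size, registered layer-by-layer at
build time by the same builders that materialize weights, so counts and
execution cannot drift apart.

Where the family leaves hyperparameters open (decoder depth, query count,
hidden widths, exact slim-neck substitution set, block-internal wiring), we
fixed them by calibrating the profiler against the family's published sizes,
in this order: first the baseline (19.97 M / 57.3 G at 640×640), then the
PConv backbone variant (14.17 M / 46.7 G), then the neck variants. The
frozen result — ResNet-18-vd stem (three 3×3 convolutions), decoder depth 3,
300 queries, width 256, feed-forward 1024, RepC3 fusion blocks of depth 3 at
expansion 0.5, encoder box-refinement applied to the selected top-K tokens —
profiles at 19.82 M / 57.5 G (baseline), 14.01 M / 46.9 G (PConv backbone),
19.57 M (slim neck + SSFF) and 13.78 M / 47.2 G (all switches), i.e. within
about 1 % of the published figures, with every ordinal relation (GFLOPs
strictly decreasing in the number of PConv stages; neck parameter order
SSFF > baseline > slimneck+SSFF > slimneck) reproduced. Two single-switch
GFLOP rows (slimneck-only, SSFF-only) deviate by a few percent — the
substitution subset trades them for agreement on the combined configuration —
and are reported as a known limitation.

## The synthetic scene generator

The generator exists so that every downstream module is testable without
downloads or GPUs. It emulates the statistical structure of outdoor
smartphone captures of tomato plants: several fruits per 640×640 image,
class-dependent coloration, leaf occluders, and lighting variation. Fruits
are shaded ellipses (radial value gradient plus a specular highlight toward
the light); the five classes occupy disjoint hue intervals — green, yellow-
orange, red, deep red/purple, brown with dark Poisson-distributed blemishes —
with class-dependent saturation/value ranges, so the generated class is
recoverable from rendered hue (the suite checks ≥95 % recovery on unoccluded
fruits; this is generator self-consistency, not a biological claim). Leaves
are green elliptical blobs drawn over a fruit's rim with the configured
Bernoulli probability, covering under half the fruit so every fruit stays at
least ~20 % visible. Lighting multiplies the value channel by 1.15 (sun),
0.70 (shade) or 0.95 (overcast). Every scene is a pure function of its spec
and seed (byte-identical regeneration).

Augmentation follows the standard photographic corruptions at their
conventional ranges: mean blur with odd kernels 5–15 (integral-image box
filter, truncated at the border so a constant image is exactly unchanged),
random crops of 40–80 % of the image side, rotations of ±60°; outputs are
resized to 640×640 and boxes are transformed with the image. A rotated box
becomes the axis-aligned hull of its clipped corner polygon; boxes whose
visible area falls below 25 % of the original are dropped (the survival
floor is a package decision; no standard rule exists). Datasets are written
as COCO-detection JSON or YOLO txt labels with a YAML manifest, and a 70/10/20
split uses floor/floor/remainder rounding — the only rule consistent with
2275/325/651 out of 3251 items.

What the generator does *not* model: perspective, specular leaf texture,
fruit clusters sharing stems, sensor noise, or the chemistry (soluble solids,
pH) that accompanies visual maturity. Passing tests therefore demonstrate
correctness of the algorithms and plumbing, not field-ready accuracy.

## Training at desk scale

`run_train()` is a CPU-scale path: the feature pipeline (backbone, encoder,
neck, decoder attention stack) is frozen at its seeded initialization and
executed once per image; the final decoder layer's classification head and
box-refinement MLP are then optimized with Adam using analytic gradients of
the full set-prediction loss — Hungarian matching (assignment treated as
fixed per step, targets detached), IoU-weighted focal classification, L1, and
the configured IoU-family loss through its analytic gradient. The smoke
preset (16 scenes at 320×320, width-reduced model, 300 full-batch steps,
learning rate 5e-3 — a linear-probe-scale rate chosen a priori) reduces the
training loss by well over half in under a minute on one CPU. Full
end-to-end backpropagation through the attention stack is deliberately out
of scope; the default configuration records the reference training setup
(batch size 4, 100 epochs, learning rate 1e-4, 640×640) for completeness.

## Evaluation

Detections are matched greedily in confidence order (a true positive needs
the same class and IoU ≥ threshold with a not-yet-matched ground truth;
duplicates are false positives). AP integrates the interpolated
precision–recall staircase at 101 recall points; mAP50:95 averages IoU
thresholds 0.50–0.95 in steps of 0.05; classes without ground truths are
excluded from the mean with a warning. Precision/recall/F1 are
macro-averaged and reported at the confidence threshold maximizing macro F1
(the reporting threshold convention is otherwise unstated in this family;
both choices are package decisions). The confusion matrix adds a background
row/column: unmatched detections count as (predicted class, background),
missed ground truths as (background, true class). The FPS harness
(`time_inference`) reports mean wall-clock seconds per image and its
reciprocal; it is hardware-dependent and excluded from any acceptance
check.

## Numerical choices and degenerate inputs

* Zero-area boxes: warned about, results defined via clamping.
* Inner intersection clamped at 0; attention masks use a −1e9 logit.
* Query selection breaks ties by token index (stable under reordering).
* Nearest-neighbour resize inside the neck for determinism; bilinear
  elsewhere (augmentation, sampling) with border clamping.
* Split rounding: floor for train and validation, remainder to test.
* Parameter counts are stored exactly and reported to two decimals in
  millions; GFLOPs to one decimal.
* Problem sizes in the test suite (smoke model widths 16–128, 96–320 px
  scenes, 250–1000-case Monte-Carlo loops) were chosen so the whole suite
  runs in about a minute on one CPU while keeping every law exact and every
  stochastic bound comfortably non-marginal.

## Known limitations

* The profiler reproduces the published accounting to ~1 % but not to the
  printed digit; the residual reflects wiring details the family description
  leaves open (and that calibration cannot uniquely recover).
* The slimneck-only and SSFF-only GFLOP rows deviate by a few percent from
  the published single-switch figures (see above).
* Head-only training cannot reach meaningful detection accuracy on real
  imagery; it demonstrates the optimization path, not a trained detector.
* The deformable-attention bias table is sized by the build-time S5 extent;
  forwarding at other input sizes interpolates the same table (a modelling
  choice, not an error).
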
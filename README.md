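# ripedetr

A lightweight, configurable real-time detection-transformer (RT-DETR-style)
model family for **tomato ripeness grading**, implemented for fully
reproducible CPU-scale experimentation in R.

Ripeness-selective harvesting needs a detector that localizes fruit under
leaf occlusion, overlap and uneven light, grades each fruit into five
maturity classes (`unripe`, `half_ripe`, `ripe`, `overripe`, `rotten`), and
stays light enough for real-time use on modest hardware — so the parameter
and FLOP budget is a first-class result, not a footnote. This package is for
researchers and engineers who want to study *that budget* and the model
mathematics exactly: every architectural variant can be built, profiled
layer-by-layer, run forward, and exercised end-to-end on synthetic scenes,
with no GPU, downloads, or external data.

## The model family

The baseline is the ResNet-18 variant of RT-DETR: backbone features S3/S4/S5
at strides 8/16/32, a single transformer encoder layer on S5 (AIFI), a
cross-scale fusion neck (CCFM), and a DETR-type decoder with IoU-aware query
selection, denoising query groups and Hungarian matching (no NMS). Four
independent switches lighten or strengthen it:

| switch | what it does |
|---|---|
| `pconv_block` | partial convolution in the backbone's residual blocks: convolve only `cp = c/4` channels (cost `h·w·k²·cp²`, exactly 1/16 of dense at ratio 1/4), pass the rest through unchanged |
| `aifi_dat` | deformable attention in the S5 encoder layer: keys/values sampled at offset-shifted reference points, with interpolated relative-position bias |
| `slimneck_ssff` | GSConv/VoVGSCSP slim-neck substitutions plus scale-sequence fusion: P3–P5 stacked on a scale axis and fused by a 3×1×1 3D convolution into the small-object path |
| `inner_eiou` | box loss `L_EIoU + IoU − IoU_inner`, the overlap term evaluated on center-shared auxiliary boxes scaled by `ratio` (default 0.70) |

where `L_EIoU = (1 − IoU) + ρ²(b, bᵍᵗ)/c_d² + (w − wᵍᵗ)²/C_w² + (h − hᵍᵗ)²/C_h²`
decomposes into overlap, center-distance and width–height terms, all with
analytic gradients.

Also included: a deterministic synthetic ripeness-scene generator (hue-coded
classes, leaf occluders, lighting variation; mean-blur 5–15 / crop 40–80 % /
rotate ±60° augmentation; COCO-JSON and YOLO label output; seeded 70/10/20
splits), a parameter/FLOP profiler whose convention is frozen across all
configurations, detection metrics (P/R/F1, per-class AP, mAP50, mAP50:95,
confusion matrix, FPS harness), and a CPU head-training path.

## Worked example

```r
library(ripedetr)

ablation_table(list(
  base          = model_config(),
  pconv         = model_config(pconv_block = TRUE),
  dat           = model_config(aifi_dat = TRUE),
  slimneck_ssff = model_config(slimneck_ssff = TRUE),
  full          = model_config(TRUE, TRUE, TRUE, TRUE)))
#>          config pconv_block aifi_dat slimneck_ssff inner_eiou params_m gflops
#> 1          base       FALSE    FALSE         FALSE      FALSE    19.82   57.5
#> 2         pconv        TRUE    FALSE         FALSE      FALSE    14.01   46.9
#> 3           dat       FALSE     TRUE         FALSE      FALSE    19.84   57.5
#> 4 slimneck_ssff       FALSE    FALSE          TRUE      FALSE    19.57   57.8
#> 5          full        TRUE     TRUE          TRUE       TRUE    13.78   47.2
```

Each row is a full model instantiated and profiled at a 640×640×3 input
(multiply–add = 2 FLOPs; normalization/activation/resize excluded). Swapping
the last three backbone stages to PConv blocks removes 5.81 M parameters and
10.6 GFLOPs; the full lightweight configuration needs 30 % fewer parameters
and 18 % fewer GFLOPs than the baseline.

```r
sc <- generate_scene(scene_spec(n_fruits = 4, occlusion_prob = 0.3, seed = 42))
sc$boxes
#>         x1        y1        x2       y2 cls
#> 1  12.2296 162.52365  86.01446 225.5921   4
#> 2   8.1086 451.34671 101.99752 553.9774   3
#> 3 118.7948 244.66178 213.14012 326.8509   3
#> 4 347.4783  88.01287 463.72379 213.4432   4

iou(c(0, 0, 4, 4), c(2, 2, 6, 6))                    # 0.1428571
inner_eiou(c(0, 0, 4, 4), c(2, 2, 6, 6), ratio = 0.7) # 1.068558
```

The scene is byte-identical for a fixed seed; classes are recoverable from
rendered hue (class 4 = rotten, 3 = overripe here). The loss example shows
the auxiliary-box penalty exceeding plain EIoU (0.968254) for this
poorly-centered pair.

The training smoke path (16 synthetic 320×320 scenes, width-reduced model,
300 Adam steps on the detection heads, frozen features) prints, via
`run_train(ripedetr_config("smoke"))`:

```
trained 300 steps: loss 20.3428 -> 3.2830
```

an 84 % training-loss reduction in under a minute on one CPU, after which
`run_eval()` returns finite, reproducible metrics on the training scenes.

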
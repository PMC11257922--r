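Package: ripedetr
Title: Lightweight Detection-Transformer Toolkit for Fruit Ripeness Grading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A configurable real-time detection-transformer (RT-DETR style)
    model family for grading tomato ripeness into five classes, built for
    CPU-scale, fully reproducible experimentation. Provides a ResNet-18-style
    backbone with switchable partial-convolution (PConv) residual blocks, an
    intra-scale encoder switchable between multi-head and deformable attention,
    a cross-scale fusion neck switchable to a GSConv/VoVGSCSP slim-neck with
    scale-sequence feature fusion, and the IoU-family box regression losses
    (GIoU, EIoU, Inner-EIoU) with analytic gradients. Includes a synthetic
    ripeness-scene generator with COCO/YOLO annotation output, a deterministic
    parameter/FLOP profiler, detection metrics (precision, recall, F1, AP,
    mAP50, mAP50:95, confusion matrix), and a head-training smoke path.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    png,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
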
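Package: soystage
Title: Lightweight Transformer Detection of Soybean Growth Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Object detection of the nine ordinal soybean growth stages
    (VE through R8) with a compound-scaled inverted-bottleneck backbone, a
    channel-mapper neck with group normalization, and a deformable-attention
    encoder-decoder head using task-aligned predictors and class-frequency
    adaptive denoising queries. Includes the full training stack (quality
    focal loss, L1 plus generalized-IoU box loss, Hungarian set matching,
    warmup/multi-step schedules), a COCO-protocol evaluator with scale
    buckets, an analytic parameter/FLOP profiler with a weighted efficiency
    score, and a procedural synthetic greenhouse-scene generator so the whole
    pipeline runs end-to-end on CPU without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
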
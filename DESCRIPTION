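Package: quantseg
Title: Int8 Quantization and Fixed-Point Accelerator Simulation for 3D
    U-Net Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-training 8-bit dynamic fixed-point quantization of 3D
    U-Net-style segmentation networks, with batch-normalization folding,
    power-of-two (shift-based) scale factors, a bit-exact integer inference
    engine, and a cycle-approximate behavioural model of a four-stage
    (configure/load/execute/write-back) double-buffered convolution
    accelerator with computation-block partitioning and zero-block skipping.
    Includes Dice and pixel-accuracy evaluation, NIfTI volume input/output
    for four-modality MRI (flair, t1, t2, t1ce), and a synthetic phantom
    generator so the whole pipeline can be exercised without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    RNifti,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
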
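Package: aggrgan
Title: Aggregated GAN Synthesis of Brain-Tumor MRI Slices with Style Transfer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates synthetic grayscale brain-tumor MRI slices by training
    three small generative adversarial networks (two DCGAN variants and a
    Wasserstein-divergence GAN), fusing the best two outputs per reference
    image with an edge-priority pixel-wise aggregation driven by
    Gaussian-smoothed Sobel edge maps, and refining the fused image by
    multi-layer neural style transfer (Gram-matrix style loss, content loss,
    total-variation loss, L-BFGS). Includes a four-metric image-quality suite
    (global SSIM, PSNR, histogram Kullback-Leibler divergence, sharpness
    difference), a deterministic brain-like phantom generator so the whole
    pipeline is testable without any MRI dataset, and an orchestrator that
    emits an eight-method evaluation table.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    RNifti,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
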
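Package: ribclear
Title: Bone Suppression in Chest Radiographs with Autoencoders, U-Nets and
    Wasserstein GANs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Paired image-to-image regression for suppressing rib and clavicle
    shadows in chest radiographs. Provides a synthetic chest-phantom generator
    with ground-truth rib masks and the field's augmentation operators, three
    model families (convolutional denoising autoencoder, U-Net with a pluggable
    encoder backbone, and a conditional Wasserstein GAN with a critic), composite
    training objectives (pixel, MS-SSIM, Sobel gradient, perceptual and
    adversarial terms with gradient penalty), an MS-SSIM/PSNR metric stack
    validated against brute-force oracles, supervised and adversarial training
    with Adam and reduce-on-plateau scheduling, and region-wise bone-mask
    evaluation of reconstructions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    Rcpp,
    rlang,
    stats,
    tibble,
    tiff,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
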
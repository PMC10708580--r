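Package: stripefill
Title: Dual-GAN Inpainting of Stripe Saturation Artifacts in Anterior
    Segment OCT Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Removes stripe-shaped saturation artifacts from anterior
    segment optical coherence tomography (AS-OCT) B-scans by adversarial
    inpainting.  Two U-Net generators and two PatchGAN discriminators are
    trained jointly with a structural-similarity loss, a spectral (FFT)
    L1 frequency loss, pixel L1, adversarial and cycle-reconstruction
    terms.  A synthetic corneal-phantom generator with known epithelium,
    Bowman's-layer and endothelium boundaries supplies paired
    clean/corrupted training data, and the package ships masked-region
    PSNR/SSIM and Dice/pixel-accuracy/F1/Jaccard evaluation metrics plus
    a command-line interface.  All network forward and backward passes
    are implemented in the package with compiled convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    png,
    yaml,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
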
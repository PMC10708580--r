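# stripefill

Dual-GAN inpainting of stripe-shaped saturation artifacts in anterior
segment OCT (AS-OCT) images, implemented as an R package with its own
compiled network engine.

## The problem

AS-OCT B-scans of the cornea often contain a bright vertical stripe — a
saturation artifact produced where the corneal surface is normal to the
beam and reflects it straight back into the detector. The stripe covers the
corneal tissue and blurs the layer boundaries (the anterior epithelium
surface EP, the posterior surface of Bowman's layer BL, and the posterior
endothelium surface EN), degrading corneal segmentation and every clinical
parameter derived from it. `stripefill` removes the stripe by *inpainting*:
reconstructing plausible tissue inside a known artifact mask while leaving
every other pixel untouched.

## The method

Two U-Net generators and two PatchGAN discriminators are trained jointly on
paired images: `G_A` maps artifact images *s* to artifact-free images *w*,
`G_B` maps back. `G_A`'s raw output is always composited with the binary
artifact mask *m* (1 = repair region):

    G_A(s) = s ⊙ (1 − m) + ŝ ⊙ m

so repairs are confined to the stripe by construction. Training minimizes

    L_total = λ_SSIM · L_SSIM + λ_F · L_F + λ_1 · L_1
            + λ_adv · L_adv + λ_recon · L_recon,
    (λ_SSIM, λ_F, λ_1, λ_adv, λ_recon) = (50, 1, 100, 1, 1)

where `L_SSIM` is one minus the structural-similarity index between
generated and target images (both directions), `L_F` is the L1 distance
between their 2D FFT spectra, `L_1` the pixel L1 distance, `L_adv` the
usual GAN log-likelihood scored by 70×70-receptive-field patch
discriminators, and `L_recon` the cycle-reconstruction L1 of `G_B(G_A(s))`
and `G_A(G_B(w))`. Optimization uses RMSprop (generator lr 5e-4,
discriminator lr 1e-4, batch 4). All forward and backward passes — 4×4
stride-2 convolutions and transposed convolutions, layer/batch norm,
dropout, and the analytic gradients of the SSIM and spectral losses — are
implemented in the package (im2col + BLAS kernels under `src/`), so no
deep-learning framework is required.

Because clinical CASIA data are private, the package ships a synthetic
corneal phantom: a bright three-band circular arc (epithelium, Bowman's
layer, stroma-to-endothelium) with known EP/BL/EN boundary curves, variable
tilt, multiplicative speckle, and stripe corruption with configurable width
and position. Evaluation reports masked-region PSNR/SSIM and boundary
Dice / pixel accuracy / F1 / Jaccard.

## A worked example

```r
library(stripefill)

## paired phantom dataset: 32 training / 8 test images, 64x64,
## test stripes wider than training stripes
dir <- tempfile()
build_dataset(32, 8, dir,
              params = phantom_params(64, 64),
              train_mask_params = mask_params(c(6L, 12L)),
              test_mask_params  = mask_params(c(12L, 20L)),
              seed = 1)

## fit the dual GAN (scaled-down: 150 steps, 16 base channels)
cfg <- train_config(image_size = 64, base_channels = 16, max_channels = 128,
                    disc_base_channels = 16, steps = 150, seed = 1,
                    log_every = 25)
fit <- dualgan(dir, cfg)

## inpaint the held-out images and score the repaired regions
evaluate(dir, fit)
#> Inpainting metrics over 8 images
#>   mean psnr          19.6274
#>   mean psnr_before    0.9987
#>   mean ssim           0.8217
#>   mean ssim_before    0.0060
```

`psnr_before`/`ssim_before` score the corrupted input against the clean
image over the masked pixels — the before-inpainting baseline. After 150
steps the inpainted stripes recover ~19.6 dB masked-region PSNR from a
~1 dB baseline, and a simple threshold trace of the anterior corneal
surface on the inpainted images reaches a Dice overlap (tolerance 2 px) of
about 0.86 versus 0.71 on the corrupted ones.

```r
rec <- predict(fit, artifact_image, mask)   # or inpaint(artifact_image, mask, fit)
plot(fit)                                   # loss trajectory
```

A command-line wrapper with `synth | train | inpaint | evaluate`
subcommands is installed at
`system.file("cli", "stripefill", package = "stripefill")`.

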
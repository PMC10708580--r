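---
title: "Dual-GAN inpainting of AS-OCT saturation artifacts: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-GAN inpainting of AS-OCT saturation artifacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stripefill)
```

## The task and the model

A saturation artifact in an anterior-segment OCT B-scan is a bright
vertical stripe crossing the cornea, caused by a specular reflection at the
point where the corneal surface is normal to the beam. `stripefill` treats
its removal as unpaired-style image translation with paired supervision:
generator `G_A` maps artifact images `s` to artifact-free images `w`,
generator `G_B` maps back, and two patch discriminators `D_A`, `D_B` judge
the realism of each direction.

The single structural commitment of the method is the mask composite: the
output of `G_A` is always

```
G_A(s) = s * (1 - m) + s_hat * m
```

with `m` the binary repair mask. This is applied in `[0,1]` storage space
after de-normalizing the network's `[-1,1]` tanh output, which makes the
outside-mask identity *bit-exact*, not merely approximate — an inpainted
image can never disagree with its input outside the stripe, trained or not.
The same composite is applied to `G_A` inside the cycle pass
`G_A(G_B(w))`, with `G_B(w)` itself as the base image, because the
composite is part of what "applying `G_A`" means here; `G_B`'s output is
used raw, since only the artifact-removal direction carries the guarantee.

### Networks

Generators are 8-stage U-Nets (4×4 kernels, stride 2, so each encoder stage
halves the resolution and depth 8 bottoms out at 1×1 for 256×256 input):
the encoder is one convolution, six Relu–Conv–LayerNorm blocks and a
Relu–Conv bottleneck; the decoder is seven
Relu–ConvTranspose–BatchNorm–Dropout blocks (dropout 0.5 in all seven) and
a Relu–ConvTranspose–Tanh head, with skip connections pairing encoder stage
`k` to decoder stage `depth - k`. Channel widths double from
`base_channels` (default 64) and are capped at 512. For test images of side
`2^d < 256`, depth is auto-reduced to `d` so the bottleneck stays 1×1; this
small-image mode is what the test suite exercises at 32–64 px.

Discriminators are PatchGANs: five 4×4 convolutions
(Conv–LeakyRelu, three Conv–BatchNorm–LeakyRelu, Conv–Sigmoid). Only the
layer count and the 70×70 receptive field are fixed by the design; the
stride schedule `(2, 2, 2, 1, 1)` with padding 1 is the unique standard
schedule realizing 70, and `receptive_field()` (the analytic recursion) is
cross-checked in the tests against `receptive_field_empirical()`, which
backpropagates from a single output unit through positive-weight probes and
measures the gradient footprint. Unstated constants are filled with the
standard values for this model family: LeakyReLU slope 0.2, Gaussian
weight initialization with sd 0.02, batch-norm momentum 0.1. The masks are
*not* fed to the networks — they enter only through the composite and the
region-restricted metrics.

### Losses

All five terms are means (over pixels, frequency bins, patch scores, and
batch), so the weights `(50, 1, 100, 1, 1)` are comparable across image
sizes.

* **SSIM loss** `E[1 - SSIM(target, generated)]`, both directions. The
  similarity index is computed with the classic 11×11 Gaussian window
  (σ = 1.5) and constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`; a
  `type = "global"` option computes the literal single-window form with
  whole-image statistics, which is also what narrow mask crops fall back
  to. Losses are evaluated in storage space, so `L = 1`.
* **Frequency loss**: mean complex modulus of the difference of
  unnormalized 2D FFT spectra, both directions. The modulus (not separate
  real/imaginary L1, which differs by at most √2) is used as the literal
  norm of a complex number. The FFT convention matters because λ_F
  multiplies it; the unnormalized forward transform is fixed and tested
  against a naive O(N⁴) DFT.
* **Pixel L1** and **cycle-reconstruction L1** as usual.
* **Adversarial**: the reported value is the GAN log-likelihood
  `E[log D(real)] + E[log(1 - D(fake))]` summed over both
  generator–discriminator pairs. Discriminators ascend it; generators
  descend the *non-saturating* surrogate `-E[log D(fake)]`, the standard
  stable choice, with gradients taken through the sigmoid in logit space
  for numerical safety. Scores outside `(0, 1)` are rejected loudly, since
  they indicate a missing sigmoid.

Every differentiable term ships its analytic gradient (`ssim_loss_grad()`,
`frequency_loss_grad()`, `l1_loss_grad()`); the SSIM gradient
backpropagates through the windowed means/variances via the adjoint
convolution, and the spectral gradient uses the DFT adjoint
`Re(F(conj(D)/|D|))/N` with a zero subgradient at `|D| = 0`. All of them,
and the full network backward passes, are verified against central finite
differences in the tests.

### Training loop

One discriminator step (both discriminators) then one generator step (both
generators) per batch; RMSprop (alpha 0.99, eps 1e-8, recorded in the
checkpoint config) with lr 5e-4 / 1e-4 and batch 4. No gradient clipping:
the adversarial term is the standard log loss, not a Wasserstein critic.
Setting `weights$adversarial = 0` skips the discriminators entirely and
`weights$reconstruction = 0` skips the cycle passes, so the published
ablations (`w/o L_SSIM`, `w/o L_F`) and a purely supervised regression are
all weight settings, not code paths. A run is fully determined by
`config$seed` (weights, batch order, dropout); checkpoints carry the RNG
state, so resuming reproduces an uninterrupted run exactly.

## The phantom generator

Clinical AS-OCT volumes are private, so the package generates what the
method actually needs from data: a dark background, a bright, tilted,
three-band corneal arc with known boundary geometry, multiplicative
speckle, and stripe corruption.

* **Geometry.** The cornea is a circular-arc annulus of radius
  `arc_radius` (default `1.1 × width`, apex at 18% of the image height)
  with three radial bands — epithelium, Bowman's layer,
  stroma-to-endothelium — of default thicknesses (3.1%, 2%, 10.5%) of the
  image height and intensities (0.65, 0.85, 0.45) over a 0.05 background.
  These are plausible desk-scale proportions for a cropped corneal B-scan,
  chosen once for visual similarity to published figures, not fitted to
  data. Tilt rotates the arc about the image center (a rotated circle is
  again a circle, so only the center moves); equal and opposite tilts of a
  centered arc give exactly mirror-symmetric noiseless images, which the
  tests exploit as a geometry oracle.
* **Boundary labels.** EP, BL and EN are the upper circle intersections per
  column, one pixel per column where the curve crosses the frame, and
  always ordered EP < BL < EN within a column. They are regenerated from
  the manifest seed rather than stored.
* **Speckle.** Multiplicative, `clean * (1 + strength * g)` with `g`
  standard normal (strength 0.25 by default), clipped to `[0, 1]` — the
  standard desk-scale approximation of OCT speckle. It is *not* a physical
  speckle model: no coherent PSF, no depth decay, no A-scan structure.
* **Corruption.** A single vertical stripe per image; width and center are
  drawn uniformly from configured ranges (defaults 8–24 px train, 24–40 px
  test at 256 px, so test stripes are wider than anything seen in
  training, as in the published protocol). The stripe is filled with
  intensity 1.0 by default — a saturated white stripe, matching the
  physical appearance of the artifact. A fill of 0.0 is available because
  the alternative reading of the corruption equation (multiplying the
  image by the mask) blacks the region out instead; the choice is a
  configuration, not a code path.

What passing tests on phantoms do **not** show: robustness to real corneal
morphology (pathology, limbus, iris), real speckle statistics, device
noise, or artifacts that are not a single vertical stripe with a known
mask. The mask is assumed given; mask *detection* is out of scope.

## Metrics

"Repaired-region" quality is computed as masked-pixels PSNR
(`10 log10(L²/MSE)`, capped at 100 dB when MSE = 0) and mask-bounding-box
SSIM (a windowed index needs a 2D neighborhood; narrow boxes use the
global-window mode). Full-image modes are available. Segmentation quality
uses Dice, pixel accuracy, F1 and Jaccard on boundary-curve masks; because
the ground truth is a 1-px curve, both curves are optionally dilated
vertically by a tolerance (0 = strict; the end-to-end checks use 2 px,
roughly the rounding width of the rendered boundary). Dice ≡ F1 and
Dice = 2J/(1+J) are asserted exactly, as identities, in the tests. Two
empty masks score 1 by convention. A learned-perceptual metric (LPIPS) is
deliberately absent — it requires pretrained perceptual-network weights;
the report schema simply leaves room for merging such a column externally.

## Numerical choices and problem sizes

* Images: `[0, 1]` storage space on disk (8-bit PNG, v/255; masks stored
  {0, 255}, binarized at 128), `[-1, 1]` inside networks; the conversion
  is affine and exact.
* Coordinates: row 0 at top, 0-based columns, stripe ranges half-open.
* The test and acceptance runs use 64×64 phantoms, 16 base channels
  (capped at 128), batch 4, and 50–150 optimization steps — sizes chosen
  so the whole suite runs on one CPU in minutes while still showing the
  qualitative behaviour of interest: supervised descent, discriminator
  separation of real from fake, and a large masked-PSNR and boundary-Dice
  improvement of inpainted over corrupted images (about 19.6 dB vs 1 dB
  and 0.86 vs 0.71 Dice in the worked example). At these sizes the
  absolute published clinical numbers are out of reach by design; the
  acceptance surface therefore checks identities, oracles and
  improvement *directions*, not clinical values.
* The epoch budget is expressed in steps and config-controlled; no
  learning-rate schedule, clipping, or early stopping.

## Known limitations

* One artifact stripe per image; masks are inputs, not inferred.
* The phantom omits pathology and acquisition physics, so results on it
  bound nothing about clinical data.
* Batch-norm statistics come from batches of 4; very small batches at
  inference fall back to running statistics.
* Training at the full 256×256 / 64-channel scale is possible but slow on
  a single CPU; the engine is written for correctness and desk-scale
  experiments, not throughput.
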
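---
title: "Bone suppression on synthetic chest phantoms: models, losses and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bone suppression on synthetic chest phantoms: models, losses and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(ribclear)
```

## The problem

Rib and clavicle shadows overlay the soft tissue in a chest radiograph and
can hide or mimic pathology. Bone suppression treats their removal as a
paired image-to-image regression: given a source radiograph $X$ with bones
and a registered target $Y$ with bones suppressed, learn a mapping
$G(X) \approx Y$. ribclear implements three model paradigms for this
mapping — a convolutional denoising autoencoder (the ribs are treated as
structured corruption of the clean soft-tissue signal), a U-Net (encoder–
decoder with skip connections), and a conditional Wasserstein GAN whose
critic scores (source, suppression) pairs — together with the composite
objectives, the MS-SSIM/PSNR metric stack, and a region-wise bone-mask
evaluation.

Clinical paired data (digitized radiographs with bone-suppressed
counterparts) cannot ship with a package, so every component here is
exercised on *synthetic chest phantoms* with known ground truth.

## The phantom generator

`generate_phantom_pair()` builds the clean target as a smooth soft-tissue
background — a seeded sum of six low-frequency cosine components (at most
`background_smoothness` = 3 cycles per image side by default) with two
darker elliptical lung fields — plus optional Gaussian nodule blobs
(present in **both** images, since nodules are soft tissue) and Gaussian
acquisition noise. The source adds curved additive rib bands and clips to
$[0,1]$:

$$\text{target} = \mathrm{clip}(\text{background} + \text{nodules} + \text{noise}),
\qquad \text{source} = \mathrm{clip}(\text{target} + \text{ribs}).$$

Each rib is a band around a curved centerline with a super-Gaussian cross
profile $A\exp(-\ln 2\,(2d/w)^4)$, which equals half its amplitude $A$
exactly at $d = w/2$. The ground-truth rib mask is therefore *exactly* the
geometric band of each rib (overlay above half-amplitude), and overlapping
ribs combine by maximum so the overlay never exceeds `rib_intensity`.
Outside the mask the source–target difference is below half-amplitude by
construction; clipping can only shrink it.

Defaults (`rib_count = 8`, `rib_intensity = 0.25`, widths 4–8 px at
128 px, `nodule_amplitude = 0.12`, `noise_sigma = 0.01`) were chosen once
as a visually plausible rib-to-tissue contrast for a normalized
radiograph; the study configurations below scale the widths with the
image size. Everything is a pure function of the config (including its
seed): repeated calls are bit-identical.

```{r phantom, eval = FALSE}
pair <- generate_phantom_pair(phantom_config(image_size = 128, seed = 1))
autoplot(pair)
```

What the phantoms deliberately do **not** model: beam hardening, scatter,
anatomy-correlated rib placement, and the global intensity calibration of
real digitized radiographs. Passing the training criteria here shows the
*machinery* learns to remove structured additive interference; it does not
certify clinical performance.

## Augmentation

`augment_pair()` implements the standard operator set: rotation
($\pm 10°$), per-axis translation ($\pm 5$ px), horizontal flipping,
zooming, and the intensity filters (median, maximum, minimum, unsharp
masking with $x + a\,(x - G_\sigma x)$, defaults $a = 1$, $\sigma = 1$).
Geometric operators apply with identical parameters to source, target and
mask (nearest-neighbour for the mask), so pair registration is preserved
exactly; intensity filters apply identically to source and target and
leave the mask untouched. Whether the original augmentation pipeline
filtered both members of a pair or only the source is not documented
anywhere we could follow; filtering both is the choice here, because a
filter applied to one side only would change the residual bone signal
itself. Edges are handled by reflect-padding before the geometric
transform and center-cropping back, so output size always equals input
size. `expand_dataset()` exposes a multiplier and an operator catalog
(first copy unaugmented, draws seeded) rather than hard-coding any
particular expansion schedule.

## Metrics

SSIM compares luminance $l$, contrast $c$ and structure $s$ over sliding
11×11 Gaussian windows ($\sigma = 1.5$, valid positions only):

$$\mathrm{SSIM}(x,y) = \frac{(2\mu_x\mu_y + c_1)(2\sigma_{xy} + c_2)}
{(\mu_x^2 + \mu_y^2 + c_1)(\sigma_x^2 + \sigma_y^2 + c_2)}$$

with the standard stabilizers $c_1 = (0.01L)^2$, $c_2 = (0.03L)^2$,
$c_3 = c_2/2$ (unstated in the source work; the conventional values are
adopted). MS-SSIM evaluates the contrast/structure term on a dyadic
pyramid (2×2 mean pooling between scales, another convention choice) and
the luminance term at the coarsest scale:

$$\mathrm{MS\text{-}SSIM} = \Big[\prod_{j=1}^{M-1} \overline{cs}_j\Big]\cdot
\overline{l_M \cdot cs_M},$$

so a single scale reduces *exactly* to SSIM. The default is $M = 5$
scales, uniform unit exponents (the canonical per-scale weights are
available as `scale_weights = "wang"`); at 64 px the feasible maximum is
$M = 3$ and `metric_report()` caps the scale count automatically. PSNR is
$10\log_{10}(\mathrm{MAX}^2/\mathrm{MSE})$ with an explicit $+\infty$
sentinel at zero error, serialized as the string `"inf"`. Reports always
renormalize both images to $[0,1]$ first so models trained in $[0,1]$ and
$[-1,1]$ are directly comparable.

Both SSIM and MS-SSIM are verified against brute-force per-window /
explicit-pyramid oracles to $10^{-6}$ in the test suite, and the analytic
MS-SSIM gradient used in training against central finite differences.

## Losses

For the reconstruction models: $L_1$, $L_2$, $L_{MSSSIM} = 1 -
\mathrm{MS\text{-}SSIM}$ (the bounded form that vanishes at identity; the
source text never writes the loss out, and the alternative
$-\mathrm{MS\text{-}SSIM}$ differs only by a constant), and the mixed
losses $\alpha L_{MSSSIM} + (1-\alpha) L_{1/2}$. The mixing weight
$\alpha$ is not stated in the source work; the default 0.84 is the value
conventionally paired with MS-SSIM + $L_1$ mixing, and it is configurable.

For the GAN, the composite generator objective is

$$-\tfrac1n\sum_i D(X_i, Y_i') \;+\; \delta\big[\alpha L_{1/2} +
\beta L_{\mathrm{Perc}} + \gamma L_{\mathrm{Sobel}}\big],
\qquad \delta = 10000,\ \alpha = 1,\ \beta = 10,\ \gamma = 10,$$

with simpler variants (`WL`, `WL1`, `WL2`) obtained by zeroing
coefficients, and the critic minimizes $\bar D_{\text{fake}} -
\bar D_{\text{real}}$. The printed form of the composite objective in the
source literature carries a positive sign on the adversarial term while
the text describes the generator as making the critic score its output as
real; the implementation uses the coherent minimization convention and
documents the discrepancy rather than reproducing it.

* **Sobel loss** — mean absolute difference of the $\pm\{1,2,1\}$
  3×3-stencil gradient maps in both directions, reflect-padded. $L_1$
  comparison on the gradient maps is a choice (the source says only that
  gradient maps are compared); it is the bounded, outlier-robust option.
* **Perceptual loss** — mean squared distance between feature maps under a
  *pluggable* extractor contract. The deployable reference is an
  ImageNet-pretrained deep feature stack; since no pretrained weights ship
  with (or can be downloaded by) this package, the shipped extractors are
  a seeded fixed 3-stage convolution stack (tapped after every stage) and
  the identity extractor, under which the loss provably degenerates to
  pixel $L_2$ — both exercise the contract and keep the loss
  deterministic.
* **Gradient penalty** — $\mathbb{E}\,(\lVert\nabla_{\hat x} D(\hat
  x)\rVert_2 - 1)^2$ on per-sample uniform interpolates of (real, fake)
  critic inputs. Lipschitz control is configurable: `gp` (default,
  $\lambda = 10$), classic weight clipping at 0.01, or none. The critic
  keeps its batch normalization in all modes, matching the published
  architecture even though penalty-based training more commonly avoids
  batch coupling; the penalty's parameter gradients are computed by double
  backpropagation with the activation pattern and batch statistics frozen
  — exact for the piecewise-linear conv/LeakyReLU/dense path, an
  approximation through batch norm (the gradient tests therefore use a
  norm-free critic, and the value itself is exact in all modes).

## Architectures

All three families are parameterized by `depth` and `base_filters` with
the schedule $\min(\text{base}\cdot 2^{\ell-1}, 512)$; exact per-layer
filter counts in the source figures are not fully legible from text, so
the schedule is the documented stand-in, with `depth = 4`,
`base_filters = 64` at paper scale and `depth = 3`, `base_filters = 8` at
test scale.

* **CDAE** — conv3×3 + ReLU + 2×2 max-pool per encoder level; nearest-
  neighbour upsampling + conv in the decoder; no skips; sigmoid output in
  $[0,1]$.
* **U-Net** — as above plus level-wise skip concatenation. An optional
  *backbone* object replaces the encoder (one feature map per level plus a
  bottom map); backbone parameters are frozen during training, which is
  how pretrained-encoder variants are meant to be slotted in. A
  seeded-random backbone ships for exercising the seam.
* **GAN generator** — strided 4×4 convolutions down, transpose
  convolutions up, skip concatenation, tanh output in $[-1,1]$. The
  published pipeline feeds 512×512×3 inputs; grayscale phantoms are
  replicated across channels when a 3-channel spec is used, and the
  test-scale studies use 1 channel.
* **Critic** — stride-2 4×4 convolutions, batch normalization after every
  convolution except the first, LeakyReLU(0.2) activations (the published
  figure fixes only the linear head), flattened to a single linear score
  per image. The critic is *conditioned*: its input is the source
  concatenated with the (real or generated) suppression along channels.

Hidden activations default to ReLU in the reconstruction families and
LeakyReLU(0.2) in the critic — a convention choice where the figures name
only "ReLU or Sigmoid" / "linear". Output activations follow each
pipeline's normalization range. Initialization is He-normal, fully seeded;
identical (spec, seed) gives bit-identical parameters.

## Training

Both regimes use Adam at a fixed initial rate of 0.001. Supervised
training applies reduce-on-plateau to the validation loss — decay 0.5,
patience 5 — and retains the best-validation parameters (no early
stopping; fixed epoch counts are the norm here, and the final parameters
are kept alongside). The validation split, where none is supplied, is a
seeded 10% of the training pairs. Batch size defaults to 8 (the small-
dataset setting; 4 is the large-dataset setting).

Adversarial training alternates `critic_steps_per_gen_step` critic updates
(default 1 — the strict reading of "trained simultaneously"; classic
Wasserstein practice of 5 is a config away) with one generator update,
uses Adam $\beta_1 = 0.5$, $\beta_2 = 0.9$ (the usual choice under a
gradient penalty; the source states Adam only for the reconstruction
models), holds the learning rate fixed (whether reduce-on-plateau was
applied to the GAN is not stated; not applying it is the conservative
default), and logs every loss component per epoch. Checkpoints store spec
+ parameters + history and reproduce forward outputs bit-identically.

## Region-wise evaluation

`region_analysis()` derives a bone mask from $|OR - GT|$ — Otsu's
threshold on the difference image by default (the threshold rule is
unstated in the source; fixed-value and quantile alternatives are exposed
and the threshold used is always reported), no morphological cleanup by
default (a 3×3 opening is a switch) — then splits
$|{\rm prediction} - GT|$ into bone / non-bone MAE. The pixel-count-
weighted identity $n_b\,\mathrm{MAE}_b + n_n\,\mathrm{MAE}_n =
n\,\mathrm{MAE}$ is asserted to $10^{-9}$. Edge error is the mean absolute
difference of Sobel gradient magnitudes restricted to the mask (the
source shows edge-error maps without a formula; this is the
operationalization). "Homogeneous residuals" is operationalized as the
bone/non-bone MAE ratio (`residual_uniformity()`, 1 = perfectly
homogeneous) — this package's construction, stated as such. An
identically-zero difference yields an empty mask with a `no_bone_signal`
flag, not an error. Predictions at another resolution are first aligned
by center-aligned bilinear resampling (`align_to_reference()`), whose
convention is documented precisely so it can be checked against
hand-computed interpolation.

## Numerical and design choices

* Convolutions are im2col + GEMM in C++ (RcppArmadillo); all layer
  gradients, the MS-SSIM/Sobel/perceptual gradients, and the
  double-backprop penalty gradients are validated against central finite
  differences at $10^{-4}$ relative tolerance or better.
* Max-pool ties route the gradient to the first maximum in column-major
  window order (exclusive routing).
* 12-bit raw radiographs are assumed right-aligned in their big-endian
  16-bit words (`left_aligned = TRUE` for the alternative); PNG output is
  8-bit (the installed writer's depth) and 16-bit output goes through
  TIFF.
* All randomness flows through explicit seeds via `withr::with_seed()`;
  no function disturbs the caller's RNG state.

## Study sizes

The shipped studies (test suite and `scripts/acceptance.R`) run on 200
phantom pairs at 64×64 — tiny U-Net (depth 3, 8 base filters, MixL1, 30
epochs), tiny GAN (WL1PS with $\delta,\alpha,\beta,\gamma$ = 10000, 1, 10,
10; 60 epochs), and a WL-versus-WL2 ablation at 12 epochs over five seeds
— sizes chosen so the full study is a single-CPU, minutes-scale
computation. They verify the learning signal (trained models beat the
do-nothing baseline on held-out MS-SSIM and bone-region MAE, and pixel
supervision lifts PSNR over the pure adversarial objective) rather than
any absolute clinical score: headline numbers from full-scale
radiograph studies require the clinical dataset and multi-day GPU
training, and are out of scope by design.

## Known limitations

* The perceptual loss ships without pretrained weights; its deployable
  value depends on plugging in a domain-appropriate extractor.
* Batch norm inside the critic interacts awkwardly with the gradient
  penalty (frozen-statistics approximation in the double-backprop path);
  weight clipping is the cleaner alternative within this architecture.
* The phantom is additive and noise-stationary; real rib shadows are
  multiplicative in attenuation and correlate with anatomy.
* Training is single-threaded CPU; the implementation is written for
  correctness and testability at phantom scale, not for GPU-scale
  throughput.
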
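# ribclear

Bone suppression in chest radiographs as paired image-to-image
regression, implemented and testable end to end on synthetic phantoms.

Rib and clavicle shadows obscure soft tissue in chest radiographs and
complicate reading and computer-aided diagnosis. Given a source
radiograph *X* (bones present) and a registered target *Y* (bones
suppressed), ribclear learns mappings *G(X) ≈ Y* under three paradigms
and compares them under one evaluation framework:

* a **convolutional denoising autoencoder** (ribs as structured
  corruption of the clean soft-tissue signal),
* a **U-Net** with skip connections and a pluggable frozen encoder
  backbone,
* a **conditional Wasserstein GAN** — U-shaped generator with transpose
  convolution upsampling, a critic scoring (source, suppression) pairs,
  and Lipschitz control by gradient penalty or weight clipping.

Training objectives cover pixel losses, the MS-SSIM loss, mixed losses
`α·L_MSSSIM + (1−α)·L_{1/2}`, and the composite generator objective

```
L(G) = −mean D(X, Y′) + δ [ α·L_{1/2} + β·L_Perceptual + γ·L_Sobel ],
        δ = 10000, α = 1, β = 10, γ = 10
```

with the Wasserstein critic loss `mean D(fake) − mean D(real)`.
Evaluation uses MSE, MAE, PSNR `10·log10(MAX²/MSE)`, SSIM and MS-SSIM
(Gaussian-window, dyadic mean-pool pyramid), plus a region-wise analysis
that derives a bone mask from |OR − GT| (Otsu threshold by default) and
splits the reconstruction error into bone / non-bone MAE with
Sobel-gradient edge errors inside the mask.

Everything runs on a deterministic synthetic phantom generator (smooth
soft-tissue background with lung fields, curved additive rib bands with
exact ground-truth masks, nodule blobs, acquisition noise) plus the
standard augmentation operators (rotation ±10°, translation ±5 px,
horizontal flip, zoom, median/max/min filtering, unsharp masking), so no
clinical data or downloads are required. The deep-learning stack
(convolutions, backpropagation, Adam, reduce-on-plateau) is implemented
in the package with RcppArmadillo kernels and validated against finite
differences and brute-force oracles.

## Worked example

```r
library(ribclear)

# 60 phantom pairs, 64x64, with ground-truth rib masks
cfg   <- phantom_config(image_size = 64, rib_count = 6,
                        rib_width_range = c(3, 6), seed = 100)
pairs <- generate_dataset(cfg, 60)
train <- pairs[1:50]; test <- pairs[51:60]

# tiny U-Net, mixed MS-SSIM + L1 loss
unet <- build_unet(model_spec("unet", 64, depth = 3, base_filters = 8,
                              input_channels = 1), seed = 5)
fit  <- train_supervised(unet, train, loss = "MixL1",
                         cfg = train_config(epochs = 10, batch_size = 8,
                                            seed = 2))
preds <- suppress_bones(fit, test)

sp <- ssim_params(scales = 3)
mean(sapply(test,            function(p) ms_ssim(p$source, p$target, sp)))
#> [1] 0.06840482       # do-nothing baseline: prediction = source
mean(sapply(seq_along(test), function(i) ms_ssim(preds[[i]], test[[i]]$target, sp)))
#> [1] 0.787705         # after 10 epochs

rr <- region_analysis(test[[1]]$source, test[[1]]$target, preds[[1]])
rr
#> <region report: mae_bone 0.0972 (n=1499), mae_nonbone 0.09616 (n=2597),
#>  edge_error_bone 0.08059, threshold 0.1177>
region_analysis(test[[1]]$source, test[[1]]$target, test[[1]]$source)$mae_bone
#> [1] 0.2195283        # baseline bone-region error, more than twice the model's
```

The rib overlay destroys local structure, so the baseline MS-SSIM is
very low (0.068); ten epochs of the tiny U-Net already recover most
structure (0.79), and its bone-region MAE (0.097) is well below the
do-nothing baseline (0.220). The Otsu-derived bone mask agrees with the
generator's ground-truth mask (intersection-over-union 0.98 on this
pair). `train_adversarial()` trains the GAN the same way;
`metric_report()`, `compare_models()`, `tidy()`/`glance()`/`autoplot()`
summarize results; `run_pipeline()` executes phantom → train → evaluate
into a run directory, and `inst/cli/ribclear.R` exposes the same steps as
shell subcommands (`phantom`, `augment`, `train`, `suppress`, `metrics`,
`region-analysis`, `run`).

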
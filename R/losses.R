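# Training objectives: pixel losses, MS-SSIM loss, mixed losses, Sobel
# gradient loss, perceptual feature loss, Wasserstein critic loss with
# optional gradient penalty, and the composite generator objective
# adversarial + delta * (alpha * pixel + beta * perceptual + gamma * Sobel).
#
# Every reconstruction loss can also return its analytic gradient with
# respect to the prediction (`grad = TRUE`); these gradients drive training
# and are verified against central finite differences in the test suite.
#
# Sign convention: the critic minimizes mean(d_fake) - mean(d_real) and the
# generator minimizes -mean(d_fake). The printed form of the composite
# objective in the source literature carries the opposite sign on the
# adversarial term while describing the generator as driving critic scores
# up; the coherent minimization convention is used here throughout.

.batchify <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L, 1L))
  if (length(dim(x)) != 4L)
    rc_abort("expected a matrix or an (H, W, C, N) array", "ribclear_dimension_error")
  x
}

#' Pixel-wise loss (L1 / L2)
#'
#' Batch-mean MAE (`kind = "L1"`) or MSE (`kind = "L2"`).
#'
#' @param pred,target Matrices or `(H, W, C, N)` arrays of identical shape.
#' @param kind `"L1"` or `"L2"`.
#' @param grad If `TRUE`, return `list(value, grad)` with the gradient with
#'   respect to `pred`.
#' @return Scalar loss, or a list when `grad = TRUE`.
#' @export
pixel_loss <- function(pred, target, kind = c("L1", "L2"), grad = FALSE) {
  kind <- match.arg(kind)
  check_same_shape(pred, target)
  d <- pred - target
  n <- length(d)
  if (kind == "L2") {
    v <- mean(d^2)
    if (!grad) return(v)
    return(list(value = v, grad = 2 * d / n))
  }
  v <- mean(abs(d))
  if (!grad) return(v)
  list(value = v, grad = sign(d) / n)
}

#' MS-SSIM loss
#'
#' `1 - ms_ssim(pred, target)`: bounded below by 0 at `pred == target`.
#' Accepts single images or batches; batch values are averaged per
#' channel-plane.
#'
#' @inheritParams pixel_loss
#' @param ssim_params An [ssim_params()] object.
#' @return Scalar loss, or `list(value, grad)` when `grad = TRUE`.
#' @export
msssim_loss <- function(pred, target, ssim_params = ribclear::ssim_params(),
                        grad = FALSE) {
  check_same_shape(pred, target)
  if (is.matrix(pred)) {
    if (!grad) return(1 - ms_ssim(pred, target, ssim_params))
    vg <- .ms_ssim_value_grad(pred, target, ssim_params)
    return(list(value = 1 - vg$value, grad = -vg$grad))
  }
  x <- .batchify(pred); y <- .batchify(target)
  d <- dim(x); nplane <- d[3L] * d[4L]
  xs <- x; dim(xs) <- c(d[1L], d[2L], 1L, nplane)
  ys <- y; dim(ys) <- c(d[1L], d[2L], 1L, nplane)
  vg <- .ms_ssim_vg_batch(xs, ys, ssim_params)
  v <- mean(1 - vg$value)
  if (!grad) return(v)
  g <- -vg$grad / nplane
  dim(g) <- d
  list(value = v, grad = g)
}

#' Mixed-loss configuration
#'
#' @param alpha_mix Weight of the MS-SSIM term in `[0, 1]`; the pixel term
#'   gets `1 - alpha_mix`. Default 0.84, the value commonly paired with
#'   MS-SSIM + L1 mixing.
#' @param pixel_kind `"L1"` or `"L2"`.
#' @param ssim_params An [ssim_params()] object.
#' @return A `mixed_loss_config` object.
#' @export
mixed_loss_config <- function(alpha_mix = 0.84, pixel_kind = c("L1", "L2"),
                              ssim_params = ribclear::ssim_params()) {
  check_number(alpha_mix, "alpha_mix", min = 0, max = 1,
               class = "ribclear_argument_error")
  structure(list(alpha_mix = alpha_mix, pixel_kind = match.arg(pixel_kind),
                 ssim_params = ssim_params),
            class = "ribclear_mixed_loss_config")
}

#' Mixed MS-SSIM + pixel loss
#'
#' `alpha_mix * msssim_loss + (1 - alpha_mix) * pixel_loss`. At
#' `alpha_mix = 0` or `1` this reduces exactly to the pure component.
#'
#' @inheritParams pixel_loss
#' @param cfg A [mixed_loss_config()].
#' @return Scalar loss, or `list(value, grad)` when `grad = TRUE`.
#' @export
mixed_loss <- function(pred, target, cfg = mixed_loss_config(), grad = FALSE) {
  a <- cfg$alpha_mix
  if (a == 0) return(pixel_loss(pred, target, cfg$pixel_kind, grad = grad))
  if (a == 1) return(msssim_loss(pred, target, cfg$ssim_params, grad = grad))
  ms <- msssim_loss(pred, target, cfg$ssim_params, grad = grad)
  px <- pixel_loss(pred, target, cfg$pixel_kind, grad = grad)
  if (!grad) return(a * ms + (1 - a) * px)
  list(value = a * ms$value + (1 - a) * px$value,
       grad = a * ms$grad + (1 - a) * px$grad)
}

.sobel_kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3L, 3L)
.sobel_ky <- t(.sobel_kx)

.sobel_maps <- function(m) {
  mp <- pad_reflect(m, 1L)
  list(gx = .filter_valid(mp, .sobel_kx), gy = .filter_valid(mp, .sobel_ky))
}

#' Sobel gradient loss
#'
#' Mean absolute difference between the Sobel-filtered gradient maps of
#' prediction and target, averaged over the horizontal and vertical
#' directions. Reflect padding keeps the maps at image size.
#'
#' @inheritParams pixel_loss
#' @return Scalar loss, or `list(value, grad)` when `grad = TRUE`.
#' @export
sobel_loss <- function(pred, target, grad = FALSE) {
  check_same_shape(pred, target)
  x <- .batchify(pred); y <- .batchify(target)
  d <- dim(x)
  if (d[1L] < 3L || d[2L] < 3L)
    rc_abort("images must be at least 3x3 for the Sobel stencil",
             "ribclear_dimension_error")
  npix <- prod(d)
  tot <- 0
  g <- if (grad) array(0, dim = d) else NULL
  for (n in seq_len(d[4L])) for (c in seq_len(d[3L])) {
    sp <- .sobel_maps(x[, , c, n]); st <- .sobel_maps(y[, , c, n])
    dx <- sp$gx - st$gx; dy <- sp$gy - st$gy
    tot <- tot + sum(abs(dx)) + sum(abs(dy))
    if (grad) {
      gm <- .filter_valid_adj(sign(dx), .sobel_kx, d[1L] + 2L, d[2L] + 2L) +
            .filter_valid_adj(sign(dy), .sobel_ky, d[1L] + 2L, d[2L] + 2L)
      g[, , c, n] <- fold_reflect(gm, 1L, d[1L], d[2L]) / (2 * npix)
    }
  }
  v <- tot / (2 * npix)
  if (!grad) return(v)
  if (is.matrix(pred)) dim(g) <- dim(pred)
  list(value = v, grad = g)
}

# ---- feature extractors -----------------------------------------------------

#' Feature extractors for the perceptual loss
#'
#' A feature extractor is a fixed, deterministic mapping from an image batch
#' to an ordered list of feature maps. `make_random_extractor()` builds a
#' seeded multi-stage convolution stack (3x3 convolutions + LeakyReLU + 2x2
#' max pooling, features tapped after each stage), which exercises the
#' perceptual-loss contract without any pretrained weights;
#' `identity_extractor()` returns the image itself as the single feature map,
#' under which the perceptual loss degenerates to the L2 pixel loss. A
#' pretrained deep extractor can be plugged in through the same contract.
#'
#' @param stages Number of convolution stages.
#' @param base_filters Channels at the first stage (doubled per stage).
#' @param in_ch Expected input channels.
#' @param seed Integer seed for the random weights.
#' @return A `ribclear_extractor` object with fields `in_ch`, `descriptor`
#'   and the internal layer stack.
#' @export
make_random_extractor <- function(stages = 3L, base_filters = 8L, in_ch = 1L,
                                  seed = 1L) {
  layers <- withr::with_seed(seed, {
    ls <- list(); ch <- in_ch
    for (s in seq_len(stages)) {
      f <- as.integer(min(base_filters * 2^(s - 1L), 256L))
      ls[[paste0("s", s, ".conv")]] <- nn_conv(paste0("s", s, ".conv"), ch, f)
      ls[[paste0("s", s, ".act")]] <- nn_act(paste0("s", s, ".act"), "lrelu")
      if (s < stages) ls[[paste0("s", s, ".pool")]] <- nn_pool(paste0("s", s, ".pool"))
      ch <- f
    }
    ls
  })
  taps <- paste0("s", seq_len(stages), ".act")
  structure(list(layers = layers, order = names(layers), taps = taps,
                 in_ch = as.integer(in_ch),
                 descriptor = sprintf("seeded-random-conv(stages=%d,base=%d,seed=%d)",
                                      stages, base_filters, seed)),
            class = "ribclear_extractor")
}

#' @rdname make_random_extractor
#' @export
identity_extractor <- function(in_ch = 1L) {
  structure(list(layers = list(), order = character(), taps = character(),
                 in_ch = as.integer(in_ch), descriptor = "identity"),
            class = "ribclear_extractor")
}

#' Extract feature maps
#' @param extractor A `ribclear_extractor`.
#' @param x Image matrix or `(H, W, C, N)` batch.
#' @return List of feature-map arrays, in stage order.
#' @export
extract_features <- function(extractor, x) {
  x <- .batchify(x)
  if (dim(x)[3L] != extractor$in_ch)
    rc_abort(sprintf("extractor expects %d channels, got %d", extractor$in_ch,
                     dim(x)[3L]), "ribclear_interface_error")
  if (length(extractor$order) == 0L) return(list(x))
  feats <- list()
  for (nm in extractor$order) {
    x <- layer_forward(extractor$layers[[nm]], x)$y
    if (nm %in% extractor$taps) feats[[length(feats) + 1L]] <- x
  }
  feats
}

.extractor_forward_cached <- function(extractor, x) {
  caches <- list(); feats <- list(); tap_pos <- integer()
  for (i in seq_along(extractor$order)) {
    nm <- extractor$order[i]
    r <- layer_forward(extractor$layers[[nm]], x)
    x <- r$y; caches[[nm]] <- r$cache
    if (nm %in% extractor$taps) {
      feats[[length(feats) + 1L]] <- x
      tap_pos <- c(tap_pos, i)
    }
  }
  list(feats = feats, caches = caches, tap_pos = tap_pos)
}

#' Perceptual feature loss
#'
#' Mean over the extractor's feature maps of the mean squared elementwise
#' feature difference (squared Euclidean distance per feature element)
#' between prediction and target. Deterministic for a fixed extractor.
#'
#' @inheritParams pixel_loss
#' @param extractor A `ribclear_extractor` (see [make_random_extractor()]).
#' @return Scalar loss, or `list(value, grad)` when `grad = TRUE`.
#' @export
perceptual_loss <- function(pred, target, extractor, grad = FALSE) {
  check_same_shape(pred, target)
  if (!inherits(extractor, "ribclear_extractor"))
    rc_abort("`extractor` must be a ribclear_extractor", "ribclear_interface_error")
  x <- .batchify(pred); y <- .batchify(target)
  if (dim(x)[3L] != extractor$in_ch)
    rc_abort(sprintf("extractor expects %d channels, got %d", extractor$in_ch,
                     dim(x)[3L]), "ribclear_interface_error")
  if (length(extractor$order) == 0L) {  # identity: degenerates to pixel L2
    return(pixel_loss(x, y, "L2", grad = grad))
  }
  fp <- .extractor_forward_cached(extractor, x)
  ft <- lapply(extract_features(extractor, y), identity)
  k <- length(fp$feats)
  v <- 0
  for (t in seq_len(k)) v <- v + mean((fp$feats[[t]] - ft[[t]])^2)
  v <- v / k
  if (!grad) return(v)
  # backward with gradient injections at the tap outputs
  dy <- NULL
  g <- NULL
  for (i in rev(seq_along(extractor$order))) {
    nm <- extractor$order[i]
    tp <- match(i, fp$tap_pos)
    if (!is.na(tp)) {
      inj <- 2 * (fp$feats[[tp]] - ft[[tp]]) / (length(fp$feats[[tp]]) * k)
      dy <- if (is.null(dy)) inj else dy + inj
    }
    dy <- layer_backward(extractor$layers[[nm]], fp$caches[[nm]], dy)$dx
  }
  if (is.matrix(pred)) dim(dy) <- dim(pred)
  list(value = v, grad = dy)
}

# ---- adversarial losses -----------------------------------------------------

#' Wasserstein critic loss
#'
#' `mean(d_fake) - mean(d_real)`: the quantity the critic minimizes, pushing
#' real scores up and generated scores down. Antisymmetric under swapping
#' its arguments.
#'
#' @param d_real,d_fake Numeric vectors (or 1 x N matrices) of critic scores.
#' @return Scalar loss.
#' @export
critic_loss <- function(d_real, d_fake) {
  if (length(d_real) == 0L || length(d_fake) == 0L)
    rc_abort("score batches must be nonempty", "ribclear_argument_error")
  mean(d_fake) - mean(d_real)
}

#' Gradient penalty for the critic
#'
#' Interpolates between real and generated critic inputs with per-sample
#' uniform weights and penalizes the squared deviation of the critic's
#' input-gradient norm from 1: `mean((||grad D(x_interp)|| - 1)^2)`.
#'
#' With `param_grads = TRUE` the gradient of the penalty with respect to the
#' critic parameters is also returned, computed by double backpropagation
#' with the critic's activation pattern and batch statistics frozen (exact
#' for the piecewise-linear convolution/LeakyReLU/dense path).
#'
#' @param critic A `ribclear_network` with family `gan_critic`.
#' @param real,fake Critic input batches `(H, W, 2*C, N)` — the source image
#'   concatenated with the real / generated suppression along channels.
#' @param seed Integer seed for the interpolation weights.
#' @param param_grads If `TRUE`, also return per-parameter penalty gradients.
#' @return The scalar penalty, or `list(value, grads)` when
#'   `param_grads = TRUE`.
#' @export
gradient_penalty <- function(critic, real, fake, seed = 1L, param_grads = FALSE) {
  if (!inherits(critic, "ribclear_network") || critic$spec$family != "gan_critic")
    rc_abort("`critic` must be a gan_critic network", "ribclear_capability_error")
  check_same_shape(real, fake, "real and fake critic inputs")
  d <- dim(real)
  n <- d[4L]
  u <- withr::with_seed(seed, runif(n))
  xi <- real
  for (i in seq_len(n)) xi[, , , i] <- u[i] * real[, , , i] + (1 - u[i]) * fake[, , , i]
  f <- .net_forward(critic, xi, train = TRUE)
  ones <- matrix(1, 1L, n)
  bk <- .net_backward(critic, f$cache, ones, keep_deltas = param_grads)
  g <- bk$dx
  norms <- sqrt(vapply(seq_len(n), function(i) sum(g[, , , i]^2), numeric(1)))
  value <- mean((norms - 1)^2)
  if (!param_grads) return(value)
  # v = dP/dg, per sample
  v <- g
  for (i in seq_len(n)) {
    coef <- if (norms[i] > 0) 2 * (norms[i] - 1) / (norms[i] * n) else 0
    v[, , , i] <- coef * g[, , , i]
  }
  # linearized forward of v with frozen masks; pair each layer's tangent
  # input with the recorded backward delta at its output
  grads <- list()
  uvec <- v
  for (nm in critic$order) {
    ly <- critic$layers[[nm]]
    pg <- layer_lin_param_grads(ly, f$cache[[nm]], uvec, bk$deltas[[nm]])
    if (!is.null(pg))
      for (pn in names(pg)) grads[[paste0(nm, ".", pn)]] <- pg[[pn]]
    uvec <- layer_linforward(ly, f$cache[[nm]], uvec)
  }
  list(value = value, grads = grads)
}

#' Composite generator loss weights
#'
#' The unified composite objective
#' `-mean(d_fake) + delta * (alpha_pix * pixel + beta_perc * perceptual +
#' gamma_sobel * sobel)`. Setting `beta_perc = 0` and/or `gamma_sobel = 0`
#' recovers the simpler adversarial + pixel variants.
#'
#' @param delta Outer weight of the reconstruction block (default 10000).
#' @param alpha_pix Pixel-term weight (default 1).
#' @param beta_perc Perceptual-term weight (default 10).
#' @param gamma_sobel Sobel-term weight (default 10).
#' @param pixel_kind `"L1"` or `"L2"`.
#' @return A `composite_weights` object.
#' @export
composite_weights <- function(delta = 10000, alpha_pix = 1, beta_perc = 10,
                              gamma_sobel = 10, pixel_kind = c("L1", "L2")) {
  for (f in c("delta", "alpha_pix", "beta_perc", "gamma_sobel"))
    check_number(get(f), f, min = 0, class = "ribclear_argument_error")
  structure(list(delta = delta, alpha_pix = alpha_pix, beta_perc = beta_perc,
                 gamma_sobel = gamma_sobel, pixel_kind = match.arg(pixel_kind)),
            class = "ribclear_composite_weights")
}

#' Composite generator objective
#'
#' @inheritParams pixel_loss
#' @param d_fake Critic scores for the generated pairs.
#' @param weights A [composite_weights()] object.
#' @param extractor Feature extractor; required iff `beta_perc > 0`.
#' @param grad If `TRUE`, also return the gradient of the reconstruction
#'   block with respect to `pred` (the adversarial term's gradient flows
#'   through the critic and is handled by the training loop).
#' @return List with `total` and the named components `adversarial`, `pixel`,
#'   `perceptual`, `sobel`; plus `grad_pred` when `grad = TRUE`.
#' @export
generator_loss <- function(d_fake, pred, target, weights = composite_weights(),
                           extractor = NULL, grad = FALSE) {
  check_same_shape(pred, target)
  if (weights$beta_perc > 0 && is.null(extractor))
    rc_abort("`beta_perc` > 0 requires a feature extractor",
             "ribclear_config_error")
  adv <- -mean(d_fake)
  px <- pixel_loss(pred, target, weights$pixel_kind, grad = grad)
  pc <- if (weights$beta_perc > 0)
    perceptual_loss(pred, target, extractor, grad = grad)
  sb <- if (weights$gamma_sobel > 0) sobel_loss(pred, target, grad = grad)
  val <- function(x) if (is.list(x)) x$value else x %||% 0
  total <- adv + weights$delta * (weights$alpha_pix * val(px) +
                                  weights$beta_perc * val(pc) +
                                  weights$gamma_sobel * val(sb))
  out <- list(total = total, adversarial = adv, pixel = val(px),
              perceptual = val(pc), sobel = val(sb))
  if (grad) {
    gp <- weights$delta * weights$alpha_pix * px$grad
    if (weights$beta_perc > 0) gp <- gp + weights$delta * weights$beta_perc * pc$grad
    if (weights$gamma_sobel > 0) gp <- gp + weights$delta * weights$gamma_sobel * sb$grad
    out$grad_pred <- gp
  }
  out
}

#' Parse a loss shorthand
#'
#' Maps the field's shorthand names to a structured loss configuration:
#' supervised losses `L1`, `L2`, `MSSSIM`, `MixL1`, `MixL2`, and adversarial
#' composites `WL` (pure Wasserstein), `WL1`/`WL2` (+ pixel), `WL1PS`/`WL2PS`
#' (+ pixel + perceptual + Sobel).
#'
#' @param name Loss name string.
#' @param weights Optional list overriding [composite_weights()] /
#'   [mixed_loss_config()] fields.
#' @return A `ribclear_loss_config` list with `kind` (`"supervised"` or
#'   `"adversarial"`) and the component configuration.
#' @export
loss_config <- function(name, weights = list()) {
  name <- toupper(name)
  sup <- c("L1", "L2", "MSSSIM", "MIXL1", "MIXL2")
  adv <- c("WL", "WL1", "WL2", "WL1PS", "WL2PS")
  if (name %in% sup) {
    cfg <- switch(name,
      L1 = list(objective = "pixel", pixel_kind = "L1"),
      L2 = list(objective = "pixel", pixel_kind = "L2"),
      MSSSIM = list(objective = "msssim"),
      MIXL1 = list(objective = "mixed", pixel_kind = "L1"),
      MIXL2 = list(objective = "mixed", pixel_kind = "L2"))
    cfg <- modifyList(cfg, weights)
    return(structure(c(list(kind = "supervised", name = name), cfg),
                     class = "ribclear_loss_config"))
  }
  if (name %in% adv) {
    base <- switch(name,
      WL = composite_weights(alpha_pix = 0, beta_perc = 0, gamma_sobel = 0),
      WL1 = composite_weights(beta_perc = 0, gamma_sobel = 0, pixel_kind = "L1"),
      WL2 = composite_weights(beta_perc = 0, gamma_sobel = 0, pixel_kind = "L2"),
      WL1PS = composite_weights(pixel_kind = "L1"),
      WL2PS = composite_weights(pixel_kind = "L2"))
    base[names(weights)] <- weights
    return(structure(list(kind = "adversarial", name = name, weights = base),
                     class = "ribclear_loss_config"))
  }
  rc_abort(sprintf("unknown loss name '%s'", name), "ribclear_config_error")
}

# Value and prediction-gradient of a supervised loss configuration.
supervised_loss <- function(pred, target, cfg, grad = FALSE,
                            ssim_params = ribclear::ssim_params()) {
  switch(cfg$objective,
    pixel = pixel_loss(pred, target, cfg$pixel_kind, grad = grad),
    msssim = msssim_loss(pred, target, ssim_params, grad = grad),
    mixed = mixed_loss(pred, target,
                       mixed_loss_config(alpha_mix = cfg$alpha_mix %||% 0.84,
                                         pixel_kind = cfg$pixel_kind,
                                         ssim_params = ssim_params),
                       grad = grad),
    rc_abort("unknown supervised objective", "ribclear_config_error"))
}
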
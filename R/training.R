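# Training regimes: supervised (autoencoder / U-Net) and adversarial
# (Wasserstein GAN). Both use Adam; the supervised loop applies
# reduce-on-plateau to the validation loss (decay 0.5, patience 5 by
# default) and retains the best-validation parameters. The adversarial
# loop alternates critic and generator updates, conditions the critic on
# the source image, and enforces the Lipschitz constraint by gradient
# penalty (default), weight clipping, or not at all.

#' Training configuration
#'
#' @param learning_rate Initial Adam step size (default 0.001).
#' @param plateau_decay Multiplicative learning-rate decay on plateau
#'   (default 0.5, must be in (0, 1)).
#' @param plateau_patience Epochs without validation improvement before a
#'   decay (default 5).
#' @param batch_size Minibatch size (default 8).
#' @param epochs Training epochs.
#' @param normalization Declared data range, `c(0, 1)` or `c(-1, 1)`; must
#'   match the pairs' declared `pixel_range`.
#' @param critic_steps_per_gen_step Critic updates per generator update
#'   (default 1, i.e. strictly simultaneous training; classic Wasserstein
#'   practice uses up to 5).
#' @param lipschitz_mode `"gp"` (gradient penalty, default), `"clip"`
#'   (weight clipping) or `"none"`.
#' @param gp_lambda Gradient-penalty weight (default 10).
#' @param clip_value Weight-clip bound (default 0.01).
#' @param val_fraction Fraction of training pairs held out for validation
#'   when no validation set is supplied (default 0.1).
#' @param seed Integer seed governing shuffling, splits and penalty draws.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 0.001, plateau_decay = 0.5,
                         plateau_patience = 5L, batch_size = 8L, epochs = 10L,
                         normalization = c(0, 1),
                         critic_steps_per_gen_step = 1L,
                         lipschitz_mode = c("gp", "clip", "none"),
                         gp_lambda = 10, clip_value = 0.01,
                         val_fraction = 0.1, seed = 1L) {
  check_number(learning_rate, "learning_rate", min = 1e-12)
  if (plateau_decay <= 0 || plateau_decay >= 1)
    rc_abort("`plateau_decay` must be in (0, 1)", "ribclear_config_error")
  check_number(plateau_patience, "plateau_patience", min = 1, integerish = TRUE)
  check_number(batch_size, "batch_size", min = 1, integerish = TRUE)
  check_number(epochs, "epochs", min = 0, integerish = TRUE)
  check_number(critic_steps_per_gen_step, "critic_steps_per_gen_step",
               min = 1, integerish = TRUE)
  structure(list(learning_rate = learning_rate, plateau_decay = plateau_decay,
                 plateau_patience = as.integer(plateau_patience),
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 normalization = as.numeric(normalization),
                 critic_steps_per_gen_step = as.integer(critic_steps_per_gen_step),
                 lipschitz_mode = match.arg(lipschitz_mode),
                 gp_lambda = gp_lambda, clip_value = clip_value,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "ribclear_train_config")
}

#' Reduce-on-plateau decision
#'
#' Returns `current_lr * plateau_decay` iff the most recent
#' `plateau_patience` validation losses contain no improvement over the
#' best value that preceded them; otherwise `current_lr` unchanged.
#'
#' @param val_losses Numeric vector of validation losses, oldest first
#'   (restarted after each decay).
#' @param current_lr Current learning rate (> 0).
#' @param cfg A [train_config()] (only decay and patience are used).
#' @return The new learning rate.
#' @export
plateau_scheduler <- function(val_losses, current_lr, cfg = train_config()) {
  if (current_lr <= 0)
    rc_abort("`current_lr` must be positive", "ribclear_argument_error")
  p <- cfg$plateau_patience
  n <- length(val_losses)
  if (n < p + 1L) return(current_lr)
  best_prev <- min(val_losses[seq_len(n - p)])
  recent <- val_losses[(n - p + 1L):n]
  if (min(recent) >= best_prev) current_lr * cfg$plateau_decay else current_lr
}

.check_pairs_range <- function(pairs, normalization) {
  for (pr in pairs)
    if (!isTRUE(all.equal(pr$pixel_range, normalization)))
      rc_abort(sprintf("pair declares range [%g, %g] but config expects [%g, %g]",
                       pr$pixel_range[1], pr$pixel_range[2],
                       normalization[1], normalization[2]),
               "ribclear_config_error")
  invisible(TRUE)
}

#' Rescale an image pair to a different declared range
#' @param pair An [image_pair()].
#' @param to Target range, `c(0, 1)` or `c(-1, 1)`.
#' @return The rescaled [image_pair()].
#' @export
pair_normalize <- function(pair, to = c(-1, 1)) {
  image_pair(normalize_range(pair$source, pair$pixel_range, to),
             normalize_range(pair$target, pair$pixel_range, to),
             rib_mask = pair$rib_mask, pixel_range = to)
}

.pairs_to_xy <- function(pairs, channels) {
  list(x = as_batch(lapply(pairs, `[[`, "source"), channels),
       y = as_batch(lapply(pairs, `[[`, "target"), channels))
}

.split_val <- function(pairs, frac) {
  n <- length(pairs)
  nv <- max(1L, round(frac * n))
  vi <- sample(n, nv)
  list(train = pairs[-vi], val = pairs[vi])
}

.eval_loss <- function(model, pairs, loss_fun) {
  ch <- model$spec$input_channels
  d <- .pairs_to_xy(pairs, ch)
  pred <- .net_forward(model, d$x, train = FALSE)$out
  loss_fun(pred, d$y)
}

.empty_history <- function(cols) {
  do.call(tibble::tibble, setNames(rep(list(numeric(0)), length(cols)), cols))
}

#' Train a reconstruction model (autoencoder / U-Net)
#'
#' Adam optimization of the configured loss with reduce-on-plateau
#' learning-rate scheduling on the validation loss. The parameters with
#' the best validation loss are retained in the returned model. Fully
#' seeded: identical data, model and config reproduce the history.
#'
#' @param model A `cdae` or `unet` [build_cdae()]/[build_unet()] handle.
#' @param train_pairs List of [image_pair()]s in the configured range.
#' @param val_pairs Optional validation pairs; if `NULL`, a seeded
#'   `val_fraction` split of `train_pairs` is used.
#' @param loss A loss name (`"L1"`, `"L2"`, `"MSSSIM"`, `"MixL1"`,
#'   `"MixL2"`) or a [loss_config()] of kind `"supervised"`.
#' @param cfg A [train_config()].
#' @return A `ribclear_fit`: list with `model` (best-validation parameters),
#'   `final_model`, and `history` (one row per epoch: losses, learning rate,
#'   seconds).
#' @export
train_supervised <- function(model, train_pairs, val_pairs = NULL,
                             loss = "MixL1", cfg = train_config()) {
  if (!model$spec$family %in% c("cdae", "unet"))
    rc_abort("`model` must be a cdae or unet network", "ribclear_config_error")
  if (is.character(loss)) loss <- loss_config(loss)
  if (loss$kind != "supervised")
    rc_abort("supervised training requires a supervised loss", "ribclear_config_error")
  .check_pairs_range(train_pairs, cfg$normalization)
  if (!is.null(val_pairs)) .check_pairs_range(val_pairs, cfg$normalization)
  hist_cols <- c("epoch", "train_loss", "val_loss", "lr", "seconds")
  if (cfg$epochs == 0L)
    return(structure(list(model = model, final_model = model,
                          history = .empty_history(hist_cols)),
                     class = "ribclear_fit"))
  sz <- nrow(train_pairs[[1]]$source)
  sp <- ssim_params(scales = min(5L, .max_scales(sz, 11L)))
  loss_vg <- function(pred, target, grad = FALSE)
    supervised_loss(pred, target, loss, grad = grad, ssim_params = sp)
  withr::with_seed(cfg$seed, {
    if (is.null(val_pairs)) {
      splt <- .split_val(train_pairs, cfg$val_fraction)
      train_pairs <- splt$train; val_pairs <- splt$val
    }
    ch <- model$spec$input_channels
    dtr <- .pairs_to_xy(train_pairs, ch)
    n <- length(train_pairs)
    params <- nn_params(model)
    opt <- adam_init(params)
    lr <- cfg$learning_rate
    best_val <- Inf; best_params <- params; wait <- 0L
    rows <- vector("list", cfg$epochs)
    for (ep in seq_len(cfg$epochs)) {
      t0 <- proc.time()[["elapsed"]]
      ord <- sample(n)
      tl <- 0; nb <- 0L
      for (b0 in seq(1L, n, by = cfg$batch_size)) {
        bi <- ord[b0:min(b0 + cfg$batch_size - 1L, n)]
        xb <- dtr$x[, , , bi, drop = FALSE]
        yb <- dtr$y[, , , bi, drop = FALSE]
        model <- nn_set_params(model, params)
        f <- .net_forward(model, xb, train = TRUE)
        lv <- loss_vg(f$out, yb, grad = TRUE)
        bk <- .net_backward(model, f$cache, lv$grad)
        st <- adam_update(params, bk$grads, opt, lr)
        params <- st$params; opt <- st$state
        tl <- tl + lv$value; nb <- nb + 1L
      }
      model <- nn_set_params(model, params)
      vl <- .eval_loss(model, val_pairs, function(p, y) loss_vg(p, y))
      if (vl < best_val - 1e-12) {
        best_val <- vl; best_params <- params; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$plateau_patience) { lr <- lr * cfg$plateau_decay; wait <- 0L }
      }
      rows[[ep]] <- tibble::tibble(epoch = ep, train_loss = tl / nb,
                                   val_loss = vl, lr = lr,
                                   seconds = proc.time()[["elapsed"]] - t0)
    }
    structure(list(model = nn_set_params(model, best_params),
                   final_model = nn_set_params(model, params),
                   history = dplyr::bind_rows(rows)),
              class = "ribclear_fit")
  })
}

.clip_params <- function(params, bound) {
  lapply(params, function(p) clamp(p, -bound, bound))
}

#' Train the adversarial pair (generator + critic)
#'
#' Alternating Wasserstein updates: `critic_steps_per_gen_step` critic
#' updates per generator update. The critic scores (source, suppression)
#' pairs, real and generated; the generator minimizes the composite
#' objective `-mean(d_fake) + delta * (pixel + perceptual + Sobel)`.
#' Lipschitz control follows `cfg$lipschitz_mode`. Adam uses
#' `beta1 = 0.5, beta2 = 0.9` (the usual choice under a gradient penalty).
#' The learning rate is held fixed; reduce-on-plateau is not applied to
#' adversarial training.
#'
#' @param gen,critic `gan_generator` / `gan_critic` handles.
#' @param train_pairs,val_pairs [image_pair()]s declared in `[-1, 1]`.
#' @param weights A [composite_weights()] object.
#' @param cfg A [train_config()] with `normalization = c(-1, 1)`.
#' @param extractor Feature extractor, required iff `weights$beta_perc > 0`.
#' @return A `ribclear_gan_fit`: list with `gen`, `critic`, and `history`
#'   logging all loss components per epoch.
#' @export
train_adversarial <- function(gen, critic, train_pairs, val_pairs = NULL,
                              weights = composite_weights(),
                              cfg = train_config(normalization = c(-1, 1)),
                              extractor = NULL) {
  if (gen$spec$family != "gan_generator" || critic$spec$family != "gan_critic")
    rc_abort("`gen`/`critic` must be gan_generator and gan_critic networks",
             "ribclear_config_error")
  if (weights$beta_perc > 0 && is.null(extractor))
    rc_abort("`beta_perc` > 0 requires a feature extractor", "ribclear_config_error")
  .check_pairs_range(train_pairs, cfg$normalization)
  if (!is.null(val_pairs)) .check_pairs_range(val_pairs, cfg$normalization)
  hist_cols <- c("epoch", "critic_loss", "grad_penalty", "gen_total", "gen_adv",
                 "gen_pixel", "gen_perceptual", "gen_sobel", "val_mae", "lr",
                 "seconds")
  if (cfg$epochs == 0L)
    return(structure(list(gen = gen, critic = critic,
                          history = .empty_history(hist_cols)),
                     class = "ribclear_gan_fit"))
  withr::with_seed(cfg$seed, {
    if (is.null(val_pairs)) {
      splt <- .split_val(train_pairs, cfg$val_fraction)
      train_pairs <- splt$train; val_pairs <- splt$val
    }
    ch <- gen$spec$input_channels
    dtr <- .pairs_to_xy(train_pairs, ch)
    n <- length(train_pairs)
    gp_active <- cfg$lipschitz_mode == "gp"
    g_params <- nn_params(gen); c_params <- nn_params(critic)
    g_opt <- adam_init(g_params); c_opt <- adam_init(c_params)
    lr <- cfg$learning_rate
    best_val <- Inf; best_g <- g_params
    rows <- vector("list", cfg$epochs)
    next_batch <- local({
      pool <- integer(0)
      function() {
        if (length(pool) < cfg$batch_size) pool <<- c(pool, sample(n))
        out <- pool[seq_len(min(cfg$batch_size, length(pool)))]
        pool <<- pool[-seq_len(length(out))]
        out
      }
    })
    steps_per_epoch <- max(1L, n %/% (cfg$batch_size *
                                      (cfg$critic_steps_per_gen_step + 1L)))
    for (ep in seq_len(cfg$epochs)) {
      t0 <- proc.time()[["elapsed"]]
      acc <- c(critic_loss = 0, grad_penalty = 0, gen_total = 0, gen_adv = 0,
               gen_pixel = 0, gen_perceptual = 0, gen_sobel = 0)
      for (step in seq_len(steps_per_epoch)) {
        for (k in seq_len(cfg$critic_steps_per_gen_step)) {
          bi <- next_batch()
          xb <- dtr$x[, , , bi, drop = FALSE]
          yb <- dtr$y[, , , bi, drop = FALSE]
          gen <- nn_set_params(gen, g_params)
          yhat <- .net_forward(gen, xb, train = TRUE)$out
          real_in <- .concat_ch(xb, yb)
          fake_in <- .concat_ch(xb, yhat)
          critic <- nn_set_params(critic, c_params)
          fr <- .net_forward(critic, real_in, train = TRUE)
          ff <- .net_forward(critic, fake_in, train = TRUE)
          nb <- length(bi)
          gr <- .net_backward(critic, fr$cache, matrix(-1 / nb, 1L, nb))$grads
          gf <- .net_backward(critic, ff$cache, matrix(1 / nb, 1L, nb))$grads
          cg <- grads_add(gr, gf)
          cl <- critic_loss(fr$out, ff$out)
          if (gp_active) {
            gp <- gradient_penalty(critic, real_in, fake_in,
                                   seed = sample.int(2147483646L, 1L),
                                   param_grads = TRUE)
            cg <- grads_add(cg, grads_scale(gp$grads, cfg$gp_lambda))
            acc["grad_penalty"] <- acc["grad_penalty"] + gp$value
          }
          st <- adam_update(c_params, cg, c_opt, lr, beta1 = 0.5, beta2 = 0.9)
          c_params <- st$params; c_opt <- st$state
          if (cfg$lipschitz_mode == "clip")
            c_params <- .clip_params(c_params, cfg$clip_value)
          acc["critic_loss"] <- acc["critic_loss"] + cl
        }
        # generator update
        bi <- next_batch()
        xb <- dtr$x[, , , bi, drop = FALSE]
        yb <- dtr$y[, , , bi, drop = FALSE]
        nb <- length(bi)
        gen <- nn_set_params(gen, g_params)
        fg <- .net_forward(gen, xb, train = TRUE)
        yhat <- fg$out
        critic <- nn_set_params(critic, c_params)
        fake_in <- .concat_ch(xb, yhat)
        fc <- .net_forward(critic, fake_in, train = TRUE)
        gl <- generator_loss(fc$out, yhat, yb, weights, extractor, grad = TRUE)
        adv_bk <- .net_backward(critic, fc$cache, matrix(-1 / nb, 1L, nb))
        dyhat <- gl$grad_pred +
          adv_bk$dx[, , ch + seq_len(ch), , drop = FALSE]
        gbk <- .net_backward(gen, fg$cache, dyhat)
        st <- adam_update(g_params, gbk$grads, g_opt, lr, beta1 = 0.5, beta2 = 0.9)
        g_params <- st$params; g_opt <- st$state
        acc["gen_total"] <- acc["gen_total"] + gl$total
        acc["gen_adv"] <- acc["gen_adv"] + gl$adversarial
        acc["gen_pixel"] <- acc["gen_pixel"] + gl$pixel
        acc["gen_perceptual"] <- acc["gen_perceptual"] + gl$perceptual
        acc["gen_sobel"] <- acc["gen_sobel"] + gl$sobel
      }
      gen <- nn_set_params(gen, g_params)
      vl <- .eval_loss(gen, val_pairs, function(p, y) pixel_loss(p, y, "L1"))
      if (vl < best_val) { best_val <- vl; best_g <- g_params }
      nc <- steps_per_epoch * cfg$critic_steps_per_gen_step
      rows[[ep]] <- tibble::tibble(
        epoch = ep, critic_loss = acc[["critic_loss"]] / nc,
        grad_penalty = acc[["grad_penalty"]] / nc,
        gen_total = acc[["gen_total"]] / steps_per_epoch,
        gen_adv = acc[["gen_adv"]] / steps_per_epoch,
        gen_pixel = acc[["gen_pixel"]] / steps_per_epoch,
        gen_perceptual = acc[["gen_perceptual"]] / steps_per_epoch,
        gen_sobel = acc[["gen_sobel"]] / steps_per_epoch,
        val_mae = vl, lr = lr,
        seconds = proc.time()[["elapsed"]] - t0)
    }
    structure(list(gen = nn_set_params(gen, best_g),
                   critic = nn_set_params(critic, c_params),
                   final_gen = nn_set_params(gen, g_params),
                   history = dplyr::bind_rows(rows)),
              class = "ribclear_gan_fit")
  })
}

#' Apply a trained model to suppress bones
#'
#' Runs the source image(s) through the network, handling channel
#' replication for 3-channel models and averaging multi-channel outputs
#' back to grayscale.
#'
#' @param model A trained `ribclear_network` (or `ribclear_fit`).
#' @param source A source matrix, an [image_pair()], or a list of either.
#' @return A prediction matrix, or a list of them.
#' @export
suppress_bones <- function(model, source) {
  if (inherits(model, "ribclear_fit")) model <- model$model
  if (inherits(model, "ribclear_gan_fit")) model <- model$gen
  one <- function(src) {
    if (inherits(src, "ribclear_image_pair")) src <- src$source
    out <- nn_forward(model, src)
    batch_to_images(out)[[1]]
  }
  if (is.list(source) && !inherits(source, "ribclear_image_pair"))
    lapply(source, one)
  else one(source)
}

# ---- checkpoints ------------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint records the model spec, parameters, initialization seed
#' and (optionally) the training history, so `load_checkpoint()` can
#' rebuild the network and reproduce forward outputs bit-identically.
#'
#' @param model A `ribclear_network`.
#' @param path Checkpoint file path (`.rds`).
#' @param history Optional training-history tibble.
#' @return `save_checkpoint()`: `path` invisibly. `load_checkpoint()`: a
#'   list with `model` and `history`.
#' @export
save_checkpoint <- function(model, path, history = NULL) {
  if (inherits(model, "ribclear_fit")) {
    if (is.null(history)) history <- model$history
    model <- model$model
  }
  saveRDS(list(spec = model$spec, params = nn_params(model), seed = model$seed,
               history = history,
               version = as.character(utils::packageVersion("ribclear"))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param spec Optional [model_spec()]; if supplied, loading errors unless it
#'   matches the stored spec.
#' @export
load_checkpoint <- function(path, spec = NULL) {
  if (!file.exists(path))
    rc_abort(sprintf("checkpoint not found: %s", path), "ribclear_io_error")
  ck <- tryCatch(readRDS(path), error = function(e)
    rc_abort(sprintf("corrupt checkpoint '%s': %s", path, conditionMessage(e)),
             "ribclear_io_error"))
  if (!is.list(ck) || is.null(ck$spec) || is.null(ck$params))
    rc_abort("corrupt checkpoint: missing spec or parameters", "ribclear_io_error")
  if (!is.null(spec)) {
    cmp <- c("family", "input_size", "input_channels", "base_filters", "depth",
             "output_activation", "normalization")
    for (f in cmp)
      if (!identical(spec[[f]], ck$spec[[f]]))
        rc_abort(sprintf("checkpoint spec mismatch on `%s`: stored %s, requested %s",
                         f, format(ck$spec[[f]]), format(spec[[f]])),
                 "ribclear_spec_mismatch_error")
  }
  builder <- switch(ck$spec$family, cdae = build_cdae, unet = build_unet,
                    gan_generator = build_generator, gan_critic = build_critic)
  model <- builder(ck$spec, seed = ck$seed %||% 1L)
  model <- nn_set_params(model, ck$params)
  list(model = model, history = ck$history)
}

#' @export
print.ribclear_fit <- function(x, ...) {
  cat(sprintf("<ribclear fit: %s, %d epochs>\n", x$model$spec$family,
              nrow(x$history)))
  if (nrow(x$history) > 0) print(utils::tail(x$history, 3L))
  invisible(x)
}

#' @export
print.ribclear_gan_fit <- function(x, ...) {
  cat(sprintf("<ribclear GAN fit: %d epochs>\n", nrow(x$history)))
  if (nrow(x$history) > 0) print(utils::tail(x$history, 3L))
  invisible(x)
}

#' Tidy a training history
#' @param x A `ribclear_fit` or `ribclear_gan_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble.
#' @export
tidy.ribclear_fit <- function(x, ...) x$history

#' @rdname tidy.ribclear_fit
#' @export
tidy.ribclear_gan_fit <- function(x, ...) x$history

#' @rdname tidy.ribclear_fit
#' @param object A fit object.
#' @export
autoplot.ribclear_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "series")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", title = "Training history")
}

#' @rdname tidy.ribclear_fit
#' @export
autoplot.ribclear_gan_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history,
                           c("critic_loss", "gen_adv", "gen_pixel", "val_mae"),
                           names_to = "series")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "Adversarial training history")
}
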
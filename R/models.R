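# Model families: convolutional denoising autoencoder, U-Net with a
# pluggable encoder backbone, and the conditional Wasserstein GAN pair
# (generator + critic). All networks are built from the layer toolkit in
# nn-layers.R and are fully seeded.

#' Describe a network architecture
#'
#' A model spec fixes everything needed to build a network deterministically:
#' the family, the input geometry, the filter schedule (`base_filters * 2^level`,
#' capped at 512), the activation of the output layer and the normalization
#' policy. The critic always ends in a linear scalar score; reconstruction
#' families default to a sigmoid output in `[0, 1]` and the GAN generator to a
#' tanh output in `[-1, 1]`, matching each pipeline's normalization range.
#'
#' @param family One of `"cdae"`, `"unet"`, `"gan_generator"`, `"gan_critic"`.
#' @param input_size Image side length in pixels; must be divisible by
#'   `2^depth`.
#' @param input_channels 1 or 3. Defaults to 1 for `cdae`/`unet` and 3 for the
#'   GAN families.
#' @param base_filters Filters in the first level; deeper levels double this,
#'   capped at 512.
#' @param depth Number of down/up-sampling levels.
#' @param output_activation `"sigmoid"`, `"tanh"` or `"linear"`. The critic is
#'   forced to `"linear"`.
#' @param normalization `"none"` or `"batch"`. Only the critic uses batch
#'   normalization by default (after every convolution except the first).
#' @param backbone `NULL`, or a backbone object (see [random_backbone()]) that
#'   replaces the U-Net encoder and supplies one feature map per level.
#' @return A `model_spec` object.
#' @export
model_spec <- function(family = c("cdae", "unet", "gan_generator", "gan_critic"),
                       input_size = 64L, input_channels = NULL,
                       base_filters = NULL, depth = NULL,
                       output_activation = NULL, normalization = NULL,
                       backbone = NULL) {
  family <- match.arg(family)
  depth <- as.integer(depth %||% 4L)
  base_filters <- as.integer(base_filters %||% 64L)
  input_channels <- as.integer(input_channels %||%
    if (family %in% c("gan_generator", "gan_critic")) 3L else 1L)
  output_activation <- output_activation %||% switch(family,
    cdae = "sigmoid", unet = "sigmoid", gan_generator = "tanh",
    gan_critic = "linear")
  normalization <- normalization %||%
    if (family == "gan_critic") "batch" else "none"
  check_number(input_size, "input_size", min = 2, integerish = TRUE,
               class = "ribclear_spec_error")
  check_number(base_filters, "base_filters", min = 1, integerish = TRUE,
               class = "ribclear_spec_error")
  check_number(depth, "depth", min = 1, integerish = TRUE,
               class = "ribclear_spec_error")
  if (!input_channels %in% c(1L, 3L))
    rc_abort("`input_channels` must be 1 or 3", "ribclear_spec_error")
  if (input_size %% 2L^depth != 0L)
    rc_abort(sprintf("`input_size` (%d) must be divisible by 2^depth (%d)",
                     input_size, 2L^depth), "ribclear_spec_error")
  if (family == "gan_critic" && output_activation != "linear")
    rc_abort("the critic's output activation must be linear",
             "ribclear_spec_error")
  if (!output_activation %in% c("sigmoid", "tanh", "linear"))
    rc_abort("unknown `output_activation`", "ribclear_spec_error")
  if (!normalization %in% c("none", "batch"))
    rc_abort("unknown `normalization`", "ribclear_spec_error")
  if (!is.null(backbone) && !inherits(backbone, "ribclear_backbone"))
    rc_abort("`backbone` must be a ribclear_backbone object",
             "ribclear_interface_error")
  structure(list(family = family, input_size = as.integer(input_size),
                 input_channels = input_channels, base_filters = base_filters,
                 depth = depth, output_activation = output_activation,
                 normalization = normalization, backbone = backbone),
            class = "ribclear_model_spec")
}

.filters <- function(spec, level) as.integer(min(spec$base_filters * 2^(level - 1L), 512L))

.out_act <- function(kind) {
  switch(kind, sigmoid = nn_act("head.act", "sigmoid"),
         tanh = nn_act("head.act", "tanh"), linear = NULL)
}

.new_handle <- function(spec, layers, seed, extra = list()) {
  n_params <- sum(vapply(layers_get_params(layers), length, integer(1)))
  structure(c(list(spec = spec, layers = layers, seed = seed,
                   n_params = n_params), extra),
            class = "ribclear_network")
}

#' @export
print.ribclear_network <- function(x, ...) {
  cat(sprintf("<ribclear network: %s, input %dx%dx%d, depth %d, %s parameters>\n",
              x$spec$family, x$spec$input_size, x$spec$input_size,
              x$spec$input_channels, x$spec$depth,
              format(x$n_params, big.mark = ",")))
  invisible(x)
}

# ---- builders ---------------------------------------------------------------

#' Build a convolutional denoising autoencoder
#'
#' Encoder levels apply a 3x3 convolution + ReLU followed by 2x2 max pooling;
#' the decoder mirrors them with nearest-neighbour upsampling. There are no
#' skip connections, so all information passes through the bottleneck.
#'
#' @param spec A [model_spec()] with `family = "cdae"`.
#' @param seed Integer seed for parameter initialization.
#' @return A `ribclear_network` handle.
#' @export
build_cdae <- function(spec, seed = 1L) {
  if (spec$family != "cdae")
    rc_abort("spec family must be 'cdae'", "ribclear_spec_error")
  withr::with_seed(seed, {
    layers <- list(); order <- character()
    ch <- spec$input_channels
    for (l in seq_len(spec$depth)) {
      f <- .filters(spec, l)
      layers[[paste0("enc", l, ".conv")]] <- nn_conv(paste0("enc", l, ".conv"), ch, f)
      layers[[paste0("enc", l, ".act")]] <- nn_act(paste0("enc", l, ".act"), "relu")
      layers[[paste0("enc", l, ".pool")]] <- nn_pool(paste0("enc", l, ".pool"))
      order <- c(order, paste0("enc", l, c(".conv", ".act", ".pool")))
      ch <- f
    }
    fmid <- .filters(spec, spec$depth + 1L)
    layers[["mid.conv"]] <- nn_conv("mid.conv", ch, fmid)
    layers[["mid.act"]] <- nn_act("mid.act", "relu")
    order <- c(order, "mid.conv", "mid.act")
    ch <- fmid
    for (l in rev(seq_len(spec$depth))) {
      f <- .filters(spec, l)
      layers[[paste0("dec", l, ".up")]] <- nn_up(paste0("dec", l, ".up"))
      layers[[paste0("dec", l, ".conv")]] <- nn_conv(paste0("dec", l, ".conv"), ch, f)
      layers[[paste0("dec", l, ".act")]] <- nn_act(paste0("dec", l, ".act"), "relu")
      order <- c(order, paste0("dec", l, c(".up", ".conv", ".act")))
      ch <- f
    }
    layers[["head.conv"]] <- nn_conv("head.conv", ch, spec$input_channels)
    order <- c(order, "head.conv")
    ha <- .out_act(spec$output_activation)
    if (!is.null(ha)) { layers[["head.act"]] <- ha; order <- c(order, "head.act") }
    .new_handle(spec, layers, seed, list(order = order))
  })
}

#' Build a U-Net
#'
#' As [build_cdae()] plus level-wise skip connections: each encoder level's
#' pre-pooling feature map is concatenated onto the matching decoder level.
#' An optional backbone object replaces the encoder and supplies the skip
#' feature maps; backbone parameters are frozen during training.
#'
#' @inheritParams build_cdae
#' @return A `ribclear_network` handle.
#' @export
build_unet <- function(spec, seed = 1L) {
  if (spec$family != "unet")
    rc_abort("spec family must be 'unet'", "ribclear_spec_error")
  bb <- spec$backbone
  if (!is.null(bb) && bb$depth != spec$depth)
    rc_abort(sprintf("backbone supplies %d feature levels but spec depth is %d",
                     bb$depth, spec$depth), "ribclear_interface_error")
  withr::with_seed(seed, {
    layers <- list()
    skip_ch <- integer(spec$depth)
    if (is.null(bb)) {
      ch <- spec$input_channels
      for (l in seq_len(spec$depth)) {
        f <- .filters(spec, l)
        layers[[paste0("enc", l, ".conv")]] <- nn_conv(paste0("enc", l, ".conv"), ch, f)
        layers[[paste0("enc", l, ".act")]] <- nn_act(paste0("enc", l, ".act"), "relu")
        layers[[paste0("enc", l, ".pool")]] <- nn_pool(paste0("enc", l, ".pool"))
        skip_ch[l] <- f
        ch <- f
      }
      bottom_ch <- ch
    } else {
      skip_ch <- bb$channels[seq_len(spec$depth)]
      bottom_ch <- bb$channels[spec$depth + 1L]
    }
    fmid <- .filters(spec, spec$depth + 1L)
    layers[["mid.conv"]] <- nn_conv("mid.conv", bottom_ch, fmid)
    layers[["mid.act"]] <- nn_act("mid.act", "relu")
    ch <- fmid
    for (l in rev(seq_len(spec$depth))) {
      f <- .filters(spec, l)
      layers[[paste0("dec", l, ".up")]] <- nn_up(paste0("dec", l, ".up"))
      layers[[paste0("dec", l, ".upconv")]] <- nn_conv(paste0("dec", l, ".upconv"), ch, f)
      layers[[paste0("dec", l, ".conv")]] <-
        nn_conv(paste0("dec", l, ".conv"), f + skip_ch[l], f)
      layers[[paste0("dec", l, ".act")]] <- nn_act(paste0("dec", l, ".act"), "relu")
      ch <- f
    }
    layers[["head.conv"]] <- nn_conv("head.conv", ch, spec$input_channels)
    ha <- .out_act(spec$output_activation)
    if (!is.null(ha)) layers[["head.act"]] <- ha
    .new_handle(spec, layers, seed, list(skip_ch = skip_ch))
  })
}

#' Build the GAN generator
#'
#' A U-shaped network with strided-convolution downsampling (4x4, stride 2),
#' transpose-convolution upsampling, skip concatenation at every level, and a
#' tanh output in `[-1, 1]`.
#'
#' @inheritParams build_cdae
#' @return A `ribclear_network` handle.
#' @export
build_generator <- function(spec, seed = 1L) {
  if (spec$family != "gan_generator")
    rc_abort("spec family must be 'gan_generator'", "ribclear_spec_error")
  withr::with_seed(seed, {
    layers <- list()
    ch <- spec$input_channels
    for (l in seq_len(spec$depth)) {
      f <- .filters(spec, l)
      layers[[paste0("enc", l, ".conv")]] <-
        nn_conv(paste0("enc", l, ".conv"), ch, f, k = 4L, stride = 2L, pad = 1L)
      layers[[paste0("enc", l, ".act")]] <- nn_act(paste0("enc", l, ".act"), "lrelu")
      ch <- f
    }
    fmid <- .filters(spec, spec$depth + 1L)
    layers[["mid.conv"]] <- nn_conv("mid.conv", ch, fmid)
    layers[["mid.act"]] <- nn_act("mid.act", "lrelu")
    ch <- fmid
    for (l in rev(seq_len(spec$depth))) {
      f <- .filters(spec, l)
      layers[[paste0("dec", l, ".conv")]] <-
        nn_conv(paste0("dec", l, ".conv"), ch + .filters(spec, l), f)
      layers[[paste0("dec", l, ".act")]] <- nn_act(paste0("dec", l, ".act"), "lrelu")
      fnext <- if (l > 1L) .filters(spec, l - 1L) else .filters(spec, 1L)
      layers[[paste0("dec", l, ".tconv")]] <- nn_tconv(paste0("dec", l, ".tconv"), f, fnext)
      ch <- fnext
    }
    layers[["head.conv"]] <- nn_conv("head.conv", ch, spec$input_channels)
    ha <- .out_act(spec$output_activation)
    if (!is.null(ha)) layers[["head.act"]] <- ha
    .new_handle(spec, layers, seed)
  })
}

#' Build the GAN critic
#'
#' A stack of stride-2 convolutions (batch normalization after every
#' convolution except the first) followed by a single linear score per image.
#' The critic is conditioned on the source image: its input is the source and
#' the (real or generated) bone-suppressed image concatenated along channels.
#'
#' @inheritParams build_cdae
#' @return A `ribclear_network` handle.
#' @export
build_critic <- function(spec, seed = 1L) {
  if (spec$family != "gan_critic")
    rc_abort("spec family must be 'gan_critic'", "ribclear_spec_error")
  withr::with_seed(seed, {
    layers <- list(); order <- character()
    ch <- 2L * spec$input_channels
    for (l in seq_len(spec$depth)) {
      f <- .filters(spec, l)
      layers[[paste0("c", l, ".conv")]] <-
        nn_conv(paste0("c", l, ".conv"), ch, f, k = 4L, stride = 2L, pad = 1L)
      order <- c(order, paste0("c", l, ".conv"))
      if (l > 1L && spec$normalization == "batch") {
        layers[[paste0("c", l, ".bn")]] <- nn_bn(paste0("c", l, ".bn"), f)
        order <- c(order, paste0("c", l, ".bn"))
      }
      layers[[paste0("c", l, ".act")]] <- nn_act(paste0("c", l, ".act"), "lrelu")
      order <- c(order, paste0("c", l, ".act"))
      ch <- f
    }
    layers[["flat"]] <- nn_flatten("flat")
    side <- spec$input_size %/% 2L^spec$depth
    layers[["head.dense"]] <- nn_dense("head.dense", ch * side * side, 1L)
    order <- c(order, "flat", "head.dense")
    .new_handle(spec, layers, seed, list(order = order))
  })
}

# ---- forward / backward -----------------------------------------------------

.trace_add <- function(tr, name, y) {
  if (!is.null(tr)) tr$shapes[[length(tr$shapes) + 1L]] <-
      list(name = name, dim = dim(y))
  invisible(NULL)
}

.net_forward <- function(handle, x, train = FALSE, tr = NULL) {
  spec <- handle$spec
  L <- handle$layers
  if (spec$family %in% c("cdae", "gan_critic")) {
    caches <- list()
    for (nm in handle$order) {
      r <- layer_forward(L[[nm]], x, train = train)
      x <- r$y
      caches[[nm]] <- r$cache
      .trace_add(tr, nm, x)
    }
    return(list(out = x, cache = caches))
  }
  if (spec$family == "unet") {
    caches <- list(); skips <- list()
    if (is.null(spec$backbone)) {
      for (l in seq_len(spec$depth)) {
        for (suf in c(".conv", ".act")) {
          nm <- paste0("enc", l, suf)
          r <- layer_forward(L[[nm]], x, train = train)
          x <- r$y; caches[[nm]] <- r$cache
        }
        skips[[l]] <- x
        .trace_add(tr, paste0("enc", l), x)
        nm <- paste0("enc", l, ".pool")
        r <- layer_forward(L[[nm]], x, train = train)
        x <- r$y; caches[[nm]] <- r$cache
      }
    } else {
      bb <- spec$backbone$forward(x)
      if (length(bb$features) != spec$depth)
        rc_abort("backbone returned the wrong number of feature levels",
                 "ribclear_interface_error")
      skips <- bb$features
      x <- bb$bottom
      .trace_add(tr, "backbone.bottom", x)
    }
    for (nm in c("mid.conv", "mid.act")) {
      r <- layer_forward(L[[nm]], x, train = train)
      x <- r$y; caches[[nm]] <- r$cache
    }
    .trace_add(tr, "mid", x)
    split_at <- integer(spec$depth)
    for (l in rev(seq_len(spec$depth))) {
      for (suf in c(".up", ".upconv")) {
        nm <- paste0("dec", l, suf)
        r <- layer_forward(L[[nm]], x, train = train)
        x <- r$y; caches[[nm]] <- r$cache
      }
      split_at[l] <- dim(x)[3L]
      x <- .concat_ch(x, skips[[l]])
      for (suf in c(".conv", ".act")) {
        nm <- paste0("dec", l, suf)
        r <- layer_forward(L[[nm]], x, train = train)
        x <- r$y; caches[[nm]] <- r$cache
      }
      .trace_add(tr, paste0("dec", l), x)
    }
    r <- layer_forward(L[["head.conv"]], x, train = train)
    x <- r$y; caches[["head.conv"]] <- r$cache
    if (!is.null(L[["head.act"]])) {
      r <- layer_forward(L[["head.act"]], x, train = train)
      x <- r$y; caches[["head.act"]] <- r$cache
    }
    .trace_add(tr, "head", x)
    return(list(out = x, cache = list(layers = caches, split_at = split_at)))
  }
  if (spec$family == "gan_generator") {
    caches <- list(); skips <- list()
    for (l in seq_len(spec$depth)) {
      for (suf in c(".conv", ".act")) {
        nm <- paste0("enc", l, suf)
        r <- layer_forward(L[[nm]], x, train = train)
        x <- r$y; caches[[nm]] <- r$cache
      }
      skips[[l]] <- x
      .trace_add(tr, paste0("enc", l), x)
    }
    for (nm in c("mid.conv", "mid.act")) {
      r <- layer_forward(L[[nm]], x, train = train)
      x <- r$y; caches[[nm]] <- r$cache
    }
    .trace_add(tr, "mid", x)
    split_at <- integer(spec$depth)
    for (l in rev(seq_len(spec$depth))) {
      split_at[l] <- dim(x)[3L]
      x <- .concat_ch(x, skips[[l]])
      for (suf in c(".conv", ".act", ".tconv")) {
        nm <- paste0("dec", l, suf)
        r <- layer_forward(L[[nm]], x, train = train)
        x <- r$y; caches[[nm]] <- r$cache
      }
      .trace_add(tr, paste0("dec", l), x)
    }
    r <- layer_forward(L[["head.conv"]], x, train = train)
    x <- r$y; caches[["head.conv"]] <- r$cache
    if (!is.null(L[["head.act"]])) {
      r <- layer_forward(L[["head.act"]], x, train = train)
      x <- r$y; caches[["head.act"]] <- r$cache
    }
    .trace_add(tr, "head", x)
    return(list(out = x, cache = list(layers = caches, split_at = split_at)))
  }
  stop("unknown family")
}

.concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1L], da[2L], da[3L] + db[3L], da[4L]))
  out[, , seq_len(da[3L]), ] <- a
  out[, , da[3L] + seq_len(db[3L]), ] <- b
  out
}

.net_backward <- function(handle, cache, dy, keep_deltas = FALSE) {
  spec <- handle$spec
  L <- handle$layers
  if (spec$family %in% c("cdae", "gan_critic")) {
    grads <- list()
    deltas <- if (keep_deltas) list() else NULL
    for (nm in rev(handle$order)) {
      if (keep_deltas) deltas[[nm]] <- dy
      r <- layer_backward(L[[nm]], cache[[nm]], dy)
      if (!is.null(r$grads))
        for (pn in names(r$grads)) grads[[paste0(nm, ".", pn)]] <- r$grads[[pn]]
      dy <- r$dx
    }
    return(list(grads = grads, dx = dy, deltas = deltas))
  }
  caches <- cache$layers
  grads <- list()
  bwd1 <- function(nm, dy) {
    r <- layer_backward(L[[nm]], caches[[nm]], dy)
    if (!is.null(r$grads))
      for (pn in names(r$grads))
        grads[[paste0(nm, ".", pn)]] <<- r$grads[[pn]]
    r$dx
  }
  if (spec$family == "unet") {
    if (!is.null(L[["head.act"]])) dy <- bwd1("head.act", dy)
    dy <- bwd1("head.conv", dy)
    skip_grads <- vector("list", spec$depth)
    for (l in seq_len(spec$depth)) {
      dy <- bwd1(paste0("dec", l, ".act"), dy)
      dy <- bwd1(paste0("dec", l, ".conv"), dy)
      sa <- cache$split_at[l]
      skip_grads[[l]] <- dy[, , -seq_len(sa), , drop = FALSE]
      dy <- dy[, , seq_len(sa), , drop = FALSE]
      dy <- bwd1(paste0("dec", l, ".upconv"), dy)
      dy <- bwd1(paste0("dec", l, ".up"), dy)
    }
    dy <- bwd1("mid.act", dy)
    dy <- bwd1("mid.conv", dy)
    if (is.null(spec$backbone)) {
      for (l in rev(seq_len(spec$depth))) {
        dy <- bwd1(paste0("enc", l, ".pool"), dy)
        dy <- dy + skip_grads[[l]]
        dy <- bwd1(paste0("enc", l, ".act"), dy)
        dy <- bwd1(paste0("enc", l, ".conv"), dy)
      }
    } else {
      dy <- NULL  # frozen backbone: gradients stop here
    }
    return(list(grads = grads, dx = dy, deltas = NULL))
  }
  if (spec$family == "gan_generator") {
    if (!is.null(L[["head.act"]])) dy <- bwd1("head.act", dy)
    dy <- bwd1("head.conv", dy)
    skip_grads <- vector("list", spec$depth)
    for (l in seq_len(spec$depth)) {
      dy <- bwd1(paste0("dec", l, ".tconv"), dy)
      dy <- bwd1(paste0("dec", l, ".act"), dy)
      dy <- bwd1(paste0("dec", l, ".conv"), dy)
      sa <- cache$split_at[l]
      skip_grads[[l]] <- dy[, , -seq_len(sa), , drop = FALSE]
      dy <- dy[, , seq_len(sa), , drop = FALSE]
    }
    dy <- bwd1("mid.act", dy)
    dy <- bwd1("mid.conv", dy)
    for (l in rev(seq_len(spec$depth))) {
      dy <- dy + skip_grads[[l]]
      dy <- bwd1(paste0("enc", l, ".act"), dy)
      dy <- bwd1(paste0("enc", l, ".conv"), dy)
    }
    return(list(grads = grads, dx = dy, deltas = NULL))
  }
  stop("unknown family")
}

#' Run a network forward
#'
#' @param handle A `ribclear_network`.
#' @param x Input batch array with dim `(H, W, C, N)`, or a single `H x W`
#'   matrix (promoted to a one-image batch, replicated across the network's
#'   input channels).
#' @param train Logical; use batch statistics in normalization layers.
#' @return The output batch array (or scores matrix for the critic).
#' @export
nn_forward <- function(handle, x, train = FALSE) {
  x <- prepare_input(handle, x)
  .net_forward(handle, x, train = train)$out
}

#' @rdname nn_forward
#' @export
prepare_input <- function(handle, x) {
  if (is.matrix(x)) x <- as_batch(list(x), channels = .input_ch(handle))
  if (length(dim(x)) != 4L)
    rc_abort("input must be an (H, W, C, N) array or a matrix",
             "ribclear_dimension_error")
  if (dim(x)[3L] != .input_ch(handle))
    rc_abort(sprintf("input has %d channels but the network expects %d",
                     dim(x)[3L], .input_ch(handle)), "ribclear_dimension_error")
  x
}

.input_ch <- function(handle) {
  if (handle$spec$family == "gan_critic") 2L * handle$spec$input_channels
  else handle$spec$input_channels
}

#' Trace per-layer output shapes
#'
#' Runs a zero input through the network and records the output shape of each
#' stage, for introspection and contract tests.
#'
#' @param handle A `ribclear_network`.
#' @return A tibble with columns `stage` and `h`, `w`, `channels`.
#' @export
nn_shape_trace <- function(handle) {
  x <- array(0, dim = c(handle$spec$input_size, handle$spec$input_size,
                        .input_ch(handle), 1L))
  tr <- new.env(); tr$shapes <- list()
  .net_forward(handle, x, train = FALSE, tr = tr)
  rows <- lapply(tr$shapes, function(s) {
    d <- s$dim %||% c(NA_integer_, NA_integer_, NA_integer_, NA_integer_)
    if (is.null(s$dim)) d <- rep(NA_integer_, 4L)
    tibble::tibble(stage = s$name, h = d[1L], w = d[2L], channels = d[3L])
  })
  dplyr::bind_rows(rows)
}

#' Network parameters as a named list
#' @param handle A `ribclear_network`.
#' @return Named list of parameter arrays.
#' @export
nn_params <- function(handle) layers_get_params(handle$layers)

#' Replace network parameters
#' @param handle A `ribclear_network`.
#' @param params Named list as returned by [nn_params()].
#' @return The updated handle.
#' @export
nn_set_params <- function(handle, params) {
  handle$layers <- layers_set_params(handle$layers, params)
  handle
}

#' A seeded random encoder backbone
#'
#' Implements the backbone contract used by [build_unet()]: a frozen feature
#' extractor that yields one feature map per level (at the pre-pooling
#' resolution of that level) plus a bottom map at the coarsest resolution.
#' Intended for exercising the backbone seam without any pretrained weights.
#'
#' @param depth Number of feature levels.
#' @param base_filters Channels at the first level (doubled per level).
#' @param in_ch Input channels.
#' @param seed Integer seed.
#' @return A `ribclear_backbone` object with fields `depth`, `channels`,
#'   `forward` and `descriptor`.
#' @export
random_backbone <- function(depth = 3L, base_filters = 4L, in_ch = 1L, seed = 1L) {
  layers <- withr::with_seed(seed, {
    ls <- list(); ch <- in_ch
    for (l in seq_len(depth + 1L)) {
      f <- as.integer(min(base_filters * 2^(l - 1L), 512L))
      ls[[paste0("b", l, ".conv")]] <- nn_conv(paste0("b", l, ".conv"), ch, f)
      ls[[paste0("b", l, ".act")]] <- nn_act(paste0("b", l, ".act"), "lrelu")
      ch <- f
    }
    ls
  })
  channels <- vapply(seq_len(depth + 1L),
                     function(l) layers[[paste0("b", l, ".conv")]]$out_ch, integer(1))
  fwd <- function(x) {
    feats <- vector("list", depth)
    for (l in seq_len(depth)) {
      x <- layer_forward(layers[[paste0("b", l, ".conv")]], x)$y
      x <- layer_forward(layers[[paste0("b", l, ".act")]], x)$y
      feats[[l]] <- x
      x <- cpp_maxpool2_fwd(x)$y
    }
    x <- layer_forward(layers[[paste0("b", depth + 1L, ".conv")]], x)$y
    x <- layer_forward(layers[[paste0("b", depth + 1L, ".act")]], x)$y
    list(features = feats, bottom = x)
  }
  structure(list(depth = as.integer(depth), channels = channels, forward = fwd,
                 descriptor = sprintf("seeded-random-conv(depth=%d,base=%d,seed=%d)",
                                      depth, base_filters, seed)),
            class = "ribclear_backbone")
}
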
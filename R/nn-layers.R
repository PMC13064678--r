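# Minimal layer toolkit backing the model families. Each layer is a plain
# list carrying its parameters; forward/backward are explicit so that the
# adversarial losses can differentiate through the critic to its input
# (needed for the gradient penalty) as well as to its parameters.
#
# Array convention: activations are arrays with dim (H, W, C, N); dense
# layers operate on (features, N) matrices.

nn_conv <- function(name, in_ch, out_ch, k = 3L, stride = 1L, pad = NULL) {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  sd <- sqrt(2 / (k * k * in_ch))
  list(type = "conv", name = name,
       w = array(stats::rnorm(k * k * in_ch * out_ch, sd = sd),
                 dim = c(k, k, in_ch, out_ch)),
       b = numeric(out_ch),
       k = k, stride = as.integer(stride), pad = as.integer(pad),
       in_ch = in_ch, out_ch = out_ch)
}

# Transpose (fractionally strided) convolution; weights are stored with
# dim (k, k, out_ch, in_ch) so the forward pass is exactly the adjoint of
# a stride-`stride` convolution mapping out_ch -> in_ch channels.
nn_tconv <- function(name, in_ch, out_ch, k = 4L, stride = 2L, pad = 1L) {
  sd <- sqrt(2 / (k * k * in_ch))
  list(type = "tconv", name = name,
       w = array(stats::rnorm(k * k * out_ch * in_ch, sd = sd),
                 dim = c(k, k, out_ch, in_ch)),
       b = numeric(out_ch),
       k = k, stride = as.integer(stride), pad = as.integer(pad),
       in_ch = in_ch, out_ch = out_ch)
}

nn_bn <- function(name, ch, momentum = 0.9, eps = 1e-5) {
  list(type = "bn", name = name, gamma = rep(1, ch), beta = numeric(ch),
       run_mean = numeric(ch), run_var = rep(1, ch),
       momentum = momentum, eps = eps, ch = ch)
}

nn_act <- function(name, kind = c("relu", "lrelu", "sigmoid", "tanh"), slope = 0.2) {
  list(type = "act", name = name, kind = match.arg(kind), slope = slope)
}

nn_pool <- function(name) list(type = "pool", name = name)
nn_up <- function(name) list(type = "up", name = name)
nn_flatten <- function(name) list(type = "flatten", name = name)

nn_dense <- function(name, in_dim, out_dim) {
  list(type = "dense", name = name,
       w = matrix(stats::rnorm(out_dim * in_dim, sd = sqrt(2 / in_dim)),
                  out_dim, in_dim),
       b = numeric(out_dim), in_dim = in_dim, out_dim = out_dim)
}

.bn_channel_stats <- function(x) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1L, 2L, 4L, 3L)), ncol = d[3L])
  list(mean = colMeans(xm), var = colMeans(xm^2) - colMeans(xm)^2, m = nrow(xm))
}

.per_channel <- function(x, v) {
  # multiply/add a length-C vector along dim 3 of (H,W,C,N)
  d <- dim(x)
  rep(rep(v, each = d[1L] * d[2L]), times = d[4L])
}

layer_forward <- function(layer, x, train = FALSE) {
  switch(layer$type,
    conv = {
      y <- cpp_conv2d_fwd(x, layer$w, layer$b, layer$stride, layer$pad)
      list(y = y, cache = list(x = x))
    },
    tconv = {
      d <- dim(x)
      oh <- (d[1L] - 1L) * layer$stride - 2L * layer$pad + layer$k
      ow <- (d[2L] - 1L) * layer$stride - 2L * layer$pad + layer$k
      y <- cpp_conv2d_bwd_data(x, layer$w, layer$stride, layer$pad, oh, ow)
      y <- y + .per_channel(y, layer$b)
      list(y = y, cache = list(x = x, oh = oh, ow = ow))
    },
    bn = {
      if (train) {
        s <- .bn_channel_stats(x)
        inv_std <- 1 / sqrt(s$var + layer$eps)
        xhat <- (x - .per_channel(x, s$mean)) * .per_channel(x, inv_std)
        y <- xhat * .per_channel(x, layer$gamma) + .per_channel(x, layer$beta)
        list(y = y, cache = list(xhat = xhat, inv_std = inv_std, m = s$m,
                                 batch_mean = s$mean, batch_var = s$var))
      } else {
        inv_std <- 1 / sqrt(layer$run_var + layer$eps)
        xhat <- (x - .per_channel(x, layer$run_mean)) * .per_channel(x, inv_std)
        y <- xhat * .per_channel(x, layer$gamma) + .per_channel(x, layer$beta)
        list(y = y, cache = list(xhat = xhat, inv_std = inv_std, m = NA_real_))
      }
    },
    act = {
      switch(layer$kind,
        relu = { m <- x > 0; list(y = x * m, cache = list(mult = m)) },
        lrelu = {
          mult <- ifelse(x > 0, 1, layer$slope)
          list(y = x * mult, cache = list(mult = mult))
        },
        sigmoid = { y <- 1 / (1 + exp(-x)); list(y = y, cache = list(y = y)) },
        tanh = { y <- tanh(x); list(y = y, cache = list(y = y)) })
    },
    pool = {
      r <- cpp_maxpool2_fwd(x)
      list(y = r$y, cache = list(idx = r$idx, h = dim(x)[1L], w = dim(x)[2L]))
    },
    up = {
      d <- dim(x)
      y <- x[rep(seq_len(d[1L]), each = 2L), rep(seq_len(d[2L]), each = 2L), , ,
             drop = FALSE]
      list(y = y, cache = list(d = d))
    },
    flatten = {
      d <- dim(x)
      y <- x
      dim(y) <- c(prod(d[1:3]), d[4L])
      list(y = y, cache = list(d = d))
    },
    dense = {
      list(y = layer$w %*% x + layer$b, cache = list(x = x))
    },
    stop("unknown layer type: ", layer$type))
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      d <- dim(cache$x)
      dx <- cpp_conv2d_bwd_data(dy, layer$w, layer$stride, layer$pad, d[1L], d[2L])
      pg <- cpp_conv2d_bwd_param(cache$x, dy, layer$k, layer$k, layer$stride, layer$pad)
      list(dx = dx, grads = list(w = pg$dw, b = pg$db))
    },
    tconv = {
      dx <- cpp_conv2d_fwd(dy, layer$w, numeric(dim(layer$w)[4L]),
                           layer$stride, layer$pad)
      pg <- cpp_conv2d_bwd_param(dy, cache$x, layer$k, layer$k, layer$stride, layer$pad)
      db <- colSums(matrix(aperm(dy, c(1L, 2L, 4L, 3L)), ncol = dim(dy)[3L]))
      list(dx = dx, grads = list(w = pg$dw, b = db))
    },
    bn = {
      d <- dim(dy)
      dym <- matrix(aperm(dy, c(1L, 2L, 4L, 3L)), ncol = d[3L])
      xhm <- matrix(aperm(cache$xhat, c(1L, 2L, 4L, 3L)), ncol = d[3L])
      dgamma <- colSums(dym * xhm)
      dbeta <- colSums(dym)
      dxhat <- dy * .per_channel(dy, layer$gamma)
      m <- cache$m
      s1 <- .per_channel(dy, dbeta * layer$gamma)
      s2 <- .per_channel(dy, dgamma * layer$gamma)
      dx <- .per_channel(dy, cache$inv_std) * (dxhat - s1 / m - cache$xhat * s2 / m)
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    act = {
      dx <- switch(layer$kind,
        relu = dy * cache$mult,
        lrelu = dy * cache$mult,
        sigmoid = dy * cache$y * (1 - cache$y),
        tanh = dy * (1 - cache$y^2))
      list(dx = dx, grads = NULL)
    },
    pool = {
      list(dx = cpp_maxpool2_bwd(dy, cache$idx, cache$h, cache$w), grads = NULL)
    },
    up = {
      d <- cache$d
      ri <- seq(1L, 2L * d[1L], by = 2L); ci <- seq(1L, 2L * d[2L], by = 2L)
      dx <- dy[ri, ci, , , drop = FALSE] + dy[ri + 1L, ci, , , drop = FALSE] +
            dy[ri, ci + 1L, , , drop = FALSE] + dy[ri + 1L, ci + 1L, , , drop = FALSE]
      list(dx = dx, grads = NULL)
    },
    flatten = {
      dx <- dy
      dim(dx) <- cache$d
      list(dx = dx, grads = NULL)
    },
    dense = {
      list(dx = crossprod(layer$w, dy),
           grads = list(w = tcrossprod(dy, cache$x), b = rowSums(dy)))
    })
}

# Frozen-linearization forward: propagate a tangent vector v through the
# layer with the activation pattern and batch statistics of `cache` held
# fixed; biases do not enter. Used for double backpropagation in the
# gradient penalty. Only layer types that occur in the critic support it.
layer_linforward <- function(layer, cache, v) {
  switch(layer$type,
    conv = cpp_conv2d_fwd(v, layer$w, numeric(layer$out_ch), layer$stride, layer$pad),
    bn = v * .per_channel(v, layer$gamma * cache$inv_std),
    act = {
      if (!layer$kind %in% c("relu", "lrelu"))
        stop("linearized forward only supports piecewise-linear activations")
      v * cache$mult
    },
    flatten = { d <- dim(v); dim(v) <- c(prod(d[1:3]), d[4L]); v },
    dense = layer$w %*% v,
    stop("linearized forward not supported for layer type: ", layer$type))
}

# Parameter-gradient contribution of the scalar sum(delta_out * J_layer(v_in))
# with the layer's nonlinearity pattern frozen (see gradient_penalty()).
layer_lin_param_grads <- function(layer, cache, v_in, delta_out) {
  switch(layer$type,
    conv = {
      pg <- cpp_conv2d_bwd_param(v_in, delta_out, layer$k, layer$k,
                                 layer$stride, layer$pad)
      list(w = pg$dw, b = numeric(length(layer$b)))
    },
    bn = {
      d <- dim(delta_out)
      prod_m <- matrix(aperm(delta_out * v_in, c(1L, 2L, 4L, 3L)), ncol = d[3L])
      list(gamma = colSums(prod_m) * cache$inv_std, beta = numeric(layer$ch))
    },
    dense = list(w = tcrossprod(delta_out, v_in), b = numeric(length(layer$b))),
    NULL)
}

# ---- sequential helpers -----------------------------------------------------

seq_forward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, train = train)
    x <- r$y
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

# Backward through a layer list. Returns dx, per-layer parameter grads
# (named by layer), and optionally the gradient flowing into each layer's
# output (`deltas`, needed for double backprop).
seq_backward <- function(layers, caches, dy, keep_deltas = FALSE) {
  grads <- list()
  deltas <- if (keep_deltas) vector("list", length(layers)) else NULL
  for (i in rev(seq_along(layers))) {
    if (keep_deltas) deltas[[i]] <- dy
    r <- layer_backward(layers[[i]], caches[[i]], dy)
    if (!is.null(r$grads)) {
      for (pn in names(r$grads))
        grads[[paste0(layers[[i]]$name, ".", pn)]] <- r$grads[[pn]]
    }
    dy <- r$dx
  }
  list(dx = dy, grads = grads, deltas = deltas)
}

# ---- parameter bookkeeping --------------------------------------------------

.param_fields <- c("w", "b", "gamma", "beta")

layers_get_params <- function(layers) {
  out <- list()
  for (ly in layers)
    for (pf in .param_fields)
      if (!is.null(ly[[pf]])) out[[paste0(ly$name, ".", pf)]] <- ly[[pf]]
  out
}

layers_set_params <- function(layers, params) {
  for (i in seq_along(layers))
    for (pf in .param_fields) {
      nm <- paste0(layers[[i]]$name, ".", pf)
      if (!is.null(params[[nm]])) {
        stopifnot(length(params[[nm]]) == length(layers[[i]][[pf]]))
        p <- params[[nm]]
        if (!is.null(dim(layers[[i]][[pf]]))) dim(p) <- dim(layers[[i]][[pf]])
        layers[[i]][[pf]] <- p
      }
    }
  layers
}

grads_add <- function(a, b) {
  for (nm in names(b)) a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  a
}

grads_scale <- function(g, s) lapply(g, function(x) x * s)

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_update <- function(params, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
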
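# Image-quality metrics: MSE, MAE, PSNR, SSIM and MS-SSIM.
#
# SSIM is computed over sliding Gaussian windows (valid positions only);
# MS-SSIM evaluates the contrast and structure terms on a dyadic pyramid
# built by 2x2 mean pooling and takes the luminance term at the coarsest
# scale. The analytic gradient of MS-SSIM (used by the training losses) is
# implemented alongside and verified against finite differences in the
# test suite.

#' SSIM / MS-SSIM parameters
#'
#' @param dynamic_range Maximum possible pixel value `L` (1 for images in
#'   `[0, 1]`).
#' @param window_size Odd side length of the Gaussian window (default 11).
#' @param window_sigma Gaussian standard deviation in pixels (default 1.5).
#' @param scales Number of pyramid scales `M` for MS-SSIM (default 5).
#' @param alpha,beta,gamma Exponents of the luminance, contrast and structure
#'   comparison functions (all default 1, which collapses SSIM to its usual
#'   simplified form).
#' @param k1,k2 Stabilizer factors; `c1 = (k1*L)^2`, `c2 = (k2*L)^2`,
#'   `c3 = c2/2`.
#' @param scale_weights `"uniform"` (all per-scale exponents 1) or `"wang"`
#'   (the five canonical per-scale weights, renormalized to the requested
#'   number of scales).
#' @return An `ssim_params` object with fields `c1`, `c2`, `c3`, the
#'   exponents, `scales`, window settings and `dynamic_range`.
#' @export
ssim_params <- function(dynamic_range = 1, window_size = 11L, window_sigma = 1.5,
                        scales = 5L, alpha = 1, beta = 1, gamma = 1,
                        k1 = 0.01, k2 = 0.03,
                        scale_weights = c("uniform", "wang")) {
  scale_weights <- match.arg(scale_weights)
  check_number(window_size, "window_size", min = 3, integerish = TRUE)
  if (window_size %% 2L == 0L)
    rc_abort("`window_size` must be odd", "ribclear_config_error")
  check_number(scales, "scales", min = 1, integerish = TRUE)
  check_number(dynamic_range, "dynamic_range", min = 1e-12)
  check_number(window_sigma, "window_sigma", min = 1e-12)
  c1 <- (k1 * dynamic_range)^2
  c2 <- (k2 * dynamic_range)^2
  c3 <- c2 / 2
  if (c1 <= 0 || c2 <= 0 || c3 <= 0)
    rc_abort("stabilizers c1..c3 must be positive", "ribclear_config_error")
  w <- if (scale_weights == "wang") {
    ww <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)[seq_len(min(scales, 5L))]
    if (scales > 5L) ww <- c(ww, rep(ww[5L], scales - 5L))
    ww / sum(ww)
  } else rep(1, scales)
  structure(list(c1 = c1, c2 = c2, c3 = c3, alpha = alpha, beta = beta,
                 gamma = gamma, scales = as.integer(scales),
                 window_size = as.integer(window_size),
                 window_sigma = window_sigma, dynamic_range = dynamic_range,
                 scale_weights = scale_weights, per_scale = w),
            class = "ribclear_ssim_params")
}

gaussian_window <- function(size, sigma) {
  r <- seq_len(size) - (size + 1) / 2
  g <- exp(-r^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

.as_plane <- function(m) array(m, dim = c(nrow(m), ncol(m), 1L, 1L))

.filter_valid <- function(m, kern) {
  y <- cpp_conv2d_fwd(.as_plane(m), array(kern, c(nrow(kern), ncol(kern), 1L, 1L)),
                      0, 1L, 0L)
  matrix(y, dim(y)[1L], dim(y)[2L])
}

# adjoint of .filter_valid (scatter a valid-position map back to image size)
.filter_valid_adj <- function(f, kern, h, w) {
  dx <- cpp_conv2d_bwd_data(.as_plane(f), array(kern, c(nrow(kern), ncol(kern), 1L, 1L)),
                            1L, 0L, h, w)
  matrix(dx, h, w)
}

.ssim_maps <- function(x, y, p, kern) {
  mu_x <- .filter_valid(x, kern)
  mu_y <- .filter_valid(y, kern)
  sxx <- .filter_valid(x * x, kern) - mu_x^2
  syy <- .filter_valid(y * y, kern) - mu_y^2
  sxy <- .filter_valid(x * y, kern) - mu_x * mu_y
  list(mu_x = mu_x, mu_y = mu_y, sxx = sxx, syy = syy, sxy = sxy,
       l = (2 * mu_x * mu_y + p$c1) / (mu_x^2 + mu_y^2 + p$c1),
       cs = (2 * sxy + p$c2) / (sxx + syy + p$c2))
}

.check_ssim_input <- function(x, y, p) {
  check_same_shape(x, y)
  if (min(dim(x)) < p$window_size)
    rc_abort(sprintf("image (%dx%d) smaller than the %d-pixel SSIM window",
                     nrow(x), ncol(x), p$window_size), "ribclear_dimension_error")
}

#' Mean squared error
#' @param x,y Numeric arrays of identical shape.
#' @return Nonnegative scalar.
#' @export
mse <- function(x, y) {
  check_same_shape(x, y)
  mean((x - y)^2)
}

#' Mean absolute error
#' @inheritParams mse
#' @return Nonnegative scalar.
#' @export
mae <- function(x, y) {
  check_same_shape(x, y)
  mean(abs(x - y))
}

#' Peak signal-to-noise ratio in decibels
#'
#' `10 * log10(max_value^2 / mse(x, y))`. Identical images yield the
#' `+Inf` sentinel (serialized as the string `"inf"` in reports, never as a
#' finite number).
#'
#' @inheritParams mse
#' @param max_value Maximum possible pixel value (must be positive).
#' @return PSNR in dB, or `Inf` when `mse(x, y) == 0`.
#' @export
psnr <- function(x, y, max_value = 1) {
  if (!is.numeric(max_value) || length(max_value) != 1L || max_value <= 0)
    rc_abort("`max_value` must be a positive scalar", "ribclear_argument_error")
  m <- mse(x, y)
  if (m == 0) return(Inf)
  10 * log10(max_value^2 / m)
}

#' Structural similarity index
#'
#' Mean over sliding Gaussian windows of the product of luminance, contrast
#' and structure comparison terms raised to their exponents; with all
#' exponents 1 this is the familiar simplified SSIM. Symmetric in its two
#' arguments.
#'
#' @param x,y Grayscale image matrices with values in `[0, dynamic_range]`.
#' @param params An [ssim_params()] object.
#' @return Scalar in `[-1, 1]`.
#' @export
ssim <- function(x, y, params = ssim_params()) {
  p <- params
  .check_ssim_input(x, y, p)
  kern <- gaussian_window(p$window_size, p$window_sigma)
  m <- .ssim_maps(x, y, p, kern)
  if (p$alpha == 1 && p$beta == 1 && p$gamma == 1) return(mean(m$l * m$cs))
  sx <- sqrt(pmax(m$sxx, 0)); sy <- sqrt(pmax(m$syy, 0))
  cc <- (2 * sx * sy + p$c2) / (m$sxx + m$syy + p$c2)
  ss <- (m$sxy + p$c3) / (sx * sy + p$c3)
  mean(m$l^p$alpha * cc^p$beta * ss^p$gamma)
}

mean_pool2 <- function(m) {
  h <- nrow(m) %/% 2L; w <- ncol(m) %/% 2L
  m <- m[seq_len(2L * h), seq_len(2L * w), drop = FALSE]
  ri <- seq(1L, 2L * h, by = 2L); ci <- seq(1L, 2L * w, by = 2L)
  (m[ri, ci, drop = FALSE] + m[ri + 1L, ci, drop = FALSE] +
   m[ri, ci + 1L, drop = FALSE] + m[ri + 1L, ci + 1L, drop = FALSE]) / 4
}

# adjoint of mean_pool2
.mean_pool2_adj <- function(g, h, w) {
  out <- matrix(0, h, w)
  hh <- nrow(g); ww <- ncol(g)
  ri <- seq(1L, 2L * hh, by = 2L); ci <- seq(1L, 2L * ww, by = 2L)
  out[ri, ci] <- g / 4; out[ri + 1L, ci] <- g / 4
  out[ri, ci + 1L] <- g / 4; out[ri + 1L, ci + 1L] <- g / 4
  out
}

.max_scales <- function(side, window) max(1L, floor(log2(side / window)) + 1L)

#' Multi-scale structural similarity index
#'
#' The contrast/structure term is averaged at every scale of a dyadic
#' pyramid (2x2 mean pooling between scales) and the luminance term at the
#' coarsest scale; the result is the exponent-weighted product. With
#' `scales = 1` this equals [ssim()] exactly.
#'
#' @inheritParams ssim
#' @return Scalar MS-SSIM value.
#' @export
ms_ssim <- function(x, y, params = ssim_params()) {
  p <- params
  .check_ssim_input(x, y, p)
  M <- p$scales
  if (min(dim(x)) < p$window_size * 2^(M - 1L)) {
    feasible <- .max_scales(min(dim(x)), p$window_size)
    rc_abort(sprintf(
      "image (%dx%d) too small for %d scales with a %d-pixel window; at most %d scales are feasible",
      nrow(x), ncol(x), M, p$window_size, feasible), "ribclear_dimension_error")
  }
  kern <- gaussian_window(p$window_size, p$window_sigma)
  out <- 1
  for (j in seq_len(M)) {
    m <- .ssim_maps(x, y, p, kern)
    if (p$alpha == 1 && p$beta == 1 && p$gamma == 1) {
      cs_map <- m$cs
      l_map <- m$l
    } else {
      sx <- sqrt(pmax(m$sxx, 0)); sy <- sqrt(pmax(m$syy, 0))
      cc <- (2 * sx * sy + p$c2) / (m$sxx + m$syy + p$c2)
      ss <- (m$sxy + p$c3) / (sx * sy + p$c3)
      cs_map <- cc^p$beta * ss^p$gamma
      l_map <- m$l^p$alpha
    }
    wgt <- p$per_scale[j]
    # coarsest scale carries the luminance term pointwise, so a single
    # scale reduces exactly to ssim()
    term <- if (j == M) mean(l_map * cs_map) else mean(cs_map)
    out <- out * (if (term >= 0 || wgt == 1) term^wgt else -abs(term)^wgt)
    if (j < M) { x <- mean_pool2(x); y <- mean_pool2(y) }
  }
  out
}

# ---- batched MS-SSIM gradient ----------------------------------------------
# Planes are stacked as (H, W, 1, P) so the whole batch shares each
# convolution call. Used by the training losses.

.filter_valid_b <- function(x, kern) {
  cpp_conv2d_fwd(x, array(kern, c(nrow(kern), ncol(kern), 1L, 1L)), 0, 1L, 0L)
}

.filter_valid_adj_b <- function(f, kern, h, w) {
  cpp_conv2d_bwd_data(f, array(kern, c(nrow(kern), ncol(kern), 1L, 1L)),
                      1L, 0L, h, w)
}

.mean_pool2_b <- function(x) {
  d <- dim(x)
  ri <- seq(1L, d[1L] - 1L, by = 2L); ci <- seq(1L, d[2L] - 1L, by = 2L)
  (x[ri, ci, , , drop = FALSE] + x[ri + 1L, ci, , , drop = FALSE] +
   x[ri, ci + 1L, , , drop = FALSE] + x[ri + 1L, ci + 1L, , , drop = FALSE]) / 4
}

.mean_pool2_adj_b <- function(g, h, w) {
  d <- dim(g)
  out <- array(0, c(h, w, 1L, d[4L]))
  ri <- seq(1L, 2L * d[1L], by = 2L); ci <- seq(1L, 2L * d[2L], by = 2L)
  out[ri, ci, , ] <- g / 4; out[ri + 1L, ci, , ] <- g / 4
  out[ri, ci + 1L, , ] <- g / 4; out[ri + 1L, ci + 1L, , ] <- g / 4
  out
}

.per_plane <- function(x, v) {
  # multiply a length-P vector along dim 4 of (H, W, 1, P)
  d <- dim(x)
  x * rep(v, each = d[1L] * d[2L])
}

.plane_means <- function(x) {
  d <- dim(x)
  colMeans(matrix(x, d[1L] * d[2L], d[4L]))
}

# Per-plane MS-SSIM values and gradients with respect to x; x and y are
# (H, W, 1, P) stacks. Requires unit exponents and uniform scale weights
# (the configuration the training losses use).
.ms_ssim_vg_batch <- function(x, y, p) {
  if (!(p$alpha == 1 && p$beta == 1 && p$gamma == 1 &&
        p$scale_weights == "uniform"))
    rc_abort("the MS-SSIM gradient requires unit exponents and uniform scale weights",
             "ribclear_config_error")
  M <- p$scales
  if (min(dim(x)[1:2]) < p$window_size * 2^(M - 1L))
    rc_abort("image too small for the requested number of scales",
             "ribclear_dimension_error")
  kern <- gaussian_window(p$window_size, p$window_sigma)
  P <- dim(x)[4L]
  xs <- vector("list", M); ys <- vector("list", M)
  xs[[1L]] <- x; ys[[1L]] <- y
  for (j in seq_len(M - 1L)) {
    xs[[j + 1L]] <- .mean_pool2_b(xs[[j]])
    ys[[j + 1L]] <- .mean_pool2_b(ys[[j]])
  }
  maps <- vector("list", M)
  cs_bar <- matrix(0, M, P)
  for (j in seq_len(M)) {
    mu_x <- .filter_valid_b(xs[[j]], kern)
    mu_y <- .filter_valid_b(ys[[j]], kern)
    sxx <- .filter_valid_b(xs[[j]] * xs[[j]], kern) - mu_x^2
    syy <- .filter_valid_b(ys[[j]] * ys[[j]], kern) - mu_y^2
    sxy <- .filter_valid_b(xs[[j]] * ys[[j]], kern) - mu_x * mu_y
    l <- (2 * mu_x * mu_y + p$c1) / (mu_x^2 + mu_y^2 + p$c1)
    cs <- (2 * sxy + p$c2) / (sxx + syy + p$c2)
    maps[[j]] <- list(mu_x = mu_x, mu_y = mu_y, sxx = sxx, syy = syy,
                      sxy = sxy, l = l, cs = cs)
    cs_bar[j, ] <- .plane_means(cs)
  }
  lcs_bar <- .plane_means(maps[[M]]$l * maps[[M]]$cs)
  prod_cs <- if (M > 1L) apply(cs_bar[seq_len(M - 1L), , drop = FALSE], 2, prod)
             else rep(1, P)
  value <- prod_cs * lcs_bar
  grads <- vector("list", M)
  for (j in seq_len(M)) {
    m <- maps[[j]]
    xj <- xs[[j]]; yj <- ys[[j]]
    npos <- prod(dim(m$cs)[1:2])
    B2 <- m$sxx + m$syy + p$c2
    dcs_dsxy <- 2 / B2
    dcs_dsxx <- -m$cs / B2
    if (j < M) {
      others <- setdiff(seq_len(M - 1L), j)
      coef <- (if (length(others)) apply(cs_bar[others, , drop = FALSE], 2, prod)
               else rep(1, P)) * lcs_bar
      F1 <- .per_plane(dcs_dsxx, coef / npos)
      F2 <- .per_plane(dcs_dsxy, coef / npos)
    } else {
      coef <- prod_cs
      F1 <- .per_plane(m$l * dcs_dsxx, coef / npos)
      F2 <- .per_plane(m$l * dcs_dsxy, coef / npos)
    }
    h <- dim(xj)[1L]; w <- dim(xj)[2L]
    g <- 2 * xj * .filter_valid_adj_b(F1, kern, h, w) -
         2 * .filter_valid_adj_b(F1 * m$mu_x, kern, h, w) +
         yj * .filter_valid_adj_b(F2, kern, h, w) -
         .filter_valid_adj_b(F2 * m$mu_y, kern, h, w)
    if (j == M) {
      A1 <- 2 * m$mu_x * m$mu_y + p$c1
      B1 <- m$mu_x^2 + m$mu_y^2 + p$c1
      dl_dmux <- (2 * m$mu_y * B1 - 2 * m$mu_x * A1) / B1^2
      g <- g + .filter_valid_adj_b(.per_plane(m$cs * dl_dmux, coef / npos),
                                   kern, h, w)
    }
    grads[[j]] <- g
  }
  total <- grads[[M]]
  for (j in rev(seq_len(M - 1L))) {
    total <- .mean_pool2_adj_b(total, dim(xs[[j]])[1L], dim(xs[[j]])[2L])
    total <- total + grads[[j]]
  }
  list(value = value, grad = total)
}

# single-image convenience wrapper
.ms_ssim_value_grad <- function(x, y, params = ssim_params()) {
  p <- params
  .check_ssim_input(x, y, p)
  vg <- .ms_ssim_vg_batch(array(x, c(dim(x), 1L, 1L)),
                          array(y, c(dim(y), 1L, 1L)), p)
  list(value = vg$value[1L], grad = matrix(vg$grad, nrow(x), ncol(x)))
}

#' Per-image and aggregate quality metrics
#'
#' Computes MSE, MAE, PSNR, SSIM and MS-SSIM for each prediction against its
#' pair's target, plus aggregate means and standard deviations. Both images
#' are renormalized to `[0, 1]` (from the pair's declared pixel range) before
#' metric computation so that models trained in different ranges are
#' comparable; `max_value = 1` throughout.
#'
#' @param pairs List of [image_pair()] objects.
#' @param predictions List of predicted bone-suppressed images (matrices),
#'   shape-matched to the targets.
#' @param params [ssim_params()]; the scale count is capped at what the image
#'   size supports.
#' @return A `ribclear_metric_report` with a `per_image` tibble and an
#'   `aggregate` tibble; see [tidy.ribclear_metric_report()].
#' @export
metric_report <- function(pairs, predictions, params = ssim_params()) {
  if (length(pairs) == 0L)
    rc_abort("`pairs` must contain at least one image pair", "ribclear_argument_error")
  if (length(pairs) != length(predictions))
    rc_abort("`pairs` and `predictions` must have equal length", "ribclear_argument_error")
  rows <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    tgt <- normalize_range(pr$target, from = pr$pixel_range, to = c(0, 1))
    pred <- predictions[[i]]
    check_same_shape(pred, tgt, "prediction and target")
    pred <- normalize_range(pred, from = pr$pixel_range, to = c(0, 1))
    pcl <- params
    feasible <- .max_scales(min(dim(tgt)), params$window_size)
    if (params$scales > feasible)
      pcl <- modifyList(params, list(scales = feasible))
    class(pcl) <- class(params)
    rows[[i]] <- tibble::tibble(
      image = i,
      mse = mse(pred, tgt), mae = mae(pred, tgt),
      psnr_db = psnr(pred, tgt, max_value = 1),
      ssim = ssim(pred, tgt, pcl), ms_ssim = ms_ssim(pred, tgt, pcl))
  }
  per_image <- dplyr::bind_rows(rows)
  agg <- tidyr::pivot_longer(per_image, -"image", names_to = "metric")
  agg <- dplyr::summarise(dplyr::group_by(agg, .data$metric),
                          mean = mean(.data$value), sd = stats::sd(.data$value),
                          .groups = "drop")
  structure(list(per_image = per_image, aggregate = agg, n = length(pairs)),
            class = "ribclear_metric_report")
}

#' @export
print.ribclear_metric_report <- function(x, ...) {
  cat(sprintf("<metric report over %d images>\n", x$n))
  print(x$aggregate)
  invisible(x)
}

#' @rdname metric_report
#' @param x A `ribclear_metric_report`.
#' @param ... Unused.
#' @export
tidy.ribclear_metric_report <- function(x, ...) x$per_image

#' @rdname metric_report
#' @export
glance.ribclear_metric_report <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$aggregate, names_from = "metric",
                             values_from = c("mean", "sd"))
  dplyr::bind_cols(wide, tibble::tibble(n = x$n))
}

#' @rdname metric_report
#' @param object A `ribclear_metric_report`.
#' @export
autoplot.ribclear_metric_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_image, -"image", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL, title = "Reconstruction quality per image")
}
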
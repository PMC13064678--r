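# Independent oracles and small fixtures shared across the test files.
# The oracles deliberately re-derive every quantity from first principles
# (literal window loops, naive convolutions, finite differences) so they
# share no code path with the implementation they check.

rcns <- asNamespace("ribclear")

seeded_image <- function(n, m = n, seed = 1, lo = 0, hi = 1) {
  withr::with_seed(seed, matrix(runif(n * m, lo, hi), n, m))
}

tiny_phantom_cfg <- function(seed = 1, size = 64, ...) {
  phantom_config(image_size = size, rib_count = 6, rib_intensity = 0.25,
                 rib_width_range = c(3, 6), nodule_count = 2,
                 noise_sigma = 0.01, seed = seed, ...)
}

# --- literal SSIM / MS-SSIM oracles -----------------------------------------

oracle_gauss <- function(size, sigma) {
  r <- seq_len(size) - (size + 1) / 2
  g <- exp(-r^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

oracle_ssim_stats <- function(x, y, p) {
  k <- oracle_gauss(p$window_size, p$window_sigma)
  ws <- p$window_size
  H <- nrow(x); W <- ncol(x)
  np <- (H - ws + 1) * (W - ws + 1)
  cs <- numeric(np); l <- numeric(np); idx <- 1
  for (j in seq_len(W - ws + 1)) for (i in seq_len(H - ws + 1)) {
    wx <- x[i:(i + ws - 1), j:(j + ws - 1)]
    wy <- y[i:(i + ws - 1), j:(j + ws - 1)]
    mx <- sum(k * wx); my <- sum(k * wy)
    sxx <- sum(k * wx^2) - mx^2
    syy <- sum(k * wy^2) - my^2
    sxy <- sum(k * wx * wy) - mx * my
    l[idx] <- (2 * mx * my + p$c1) / (mx^2 + my^2 + p$c1)
    cs[idx] <- (2 * sxy + p$c2) / (sxx + syy + p$c2)
    idx <- idx + 1
  }
  list(l = l, cs = cs)
}

oracle_ssim <- function(x, y, p) {
  s <- oracle_ssim_stats(x, y, p)
  mean(s$l * s$cs)
}

oracle_pool <- function(m) {
  h <- nrow(m) %/% 2; w <- ncol(m) %/% 2
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    out[i, j] <- mean(m[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j)])
  out
}

# explicit pyramid: product of mean-cs terms, coarsest scale contributes
# the mean of the full per-window SSIM map
oracle_msssim <- function(x, y, p) {
  out <- 1
  for (j in seq_len(p$scales)) {
    s <- oracle_ssim_stats(x, y, p)
    out <- out * if (j == p$scales) mean(s$l * s$cs) else mean(s$cs)
    if (j < p$scales) { x <- oracle_pool(x); y <- oracle_pool(y) }
  }
  out
}

# --- naive convolution (for Sobel / extractor / layer oracles) --------------

oracle_conv_valid <- function(m, kern) {
  kh <- nrow(kern); kw <- ncol(kern)
  H <- nrow(m) - kh + 1; W <- ncol(m) - kw + 1
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W))
    out[i, j] <- sum(m[i:(i + kh - 1), j:(j + kw - 1)] * kern)
  out
}

oracle_pad_reflect <- function(m, p) {
  n <- nrow(m); k <- ncol(m)
  ri <- c(rev(seq_len(p) + 1), seq_len(n), n - seq_len(p))
  ci <- c(rev(seq_len(p) + 1), seq_len(k), k - seq_len(p))
  m[ri, ci]
}

# --- finite differences ------------------------------------------------------

fd_grad <- function(f, x, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    (f(x1) - f(x2)) / (2 * eps)
  }, numeric(1))
}

expect_fd_match <- function(f, x, grad, n = 8, tol = 1e-4, seed = 1,
                            eps = 1e-6) {
  idx <- withr::with_seed(seed, sample(length(x), n))
  fd <- fd_grad(f, x, idx, eps = eps)
  an <- grad[idx]
  expect_lt(max(abs(fd - an) / pmax(1, abs(fd))), tol)
}
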
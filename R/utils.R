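# Shared validation and array helpers.

rc_abort <- function(msg, class, ...) {
  rlang::abort(msg, class = c(class, "ribclear_error"), ...)
}

check_number <- function(x, field, min = -Inf, max = Inf, integerish = FALSE,
                         class = "ribclear_config_error") {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    rc_abort(sprintf("`%s` must be a single number", field), class)
  if (integerish && x != round(x))
    rc_abort(sprintf("`%s` must be an integer", field), class)
  if (x < min || x > max)
    rc_abort(sprintf("`%s` must be in [%s, %s], got %s", field,
                     format(min), format(max), format(x)), class)
  invisible(x)
}

check_same_shape <- function(x, y, what = "images") {
  if (!identical(dim(x), dim(y)))
    rc_abort(sprintf("%s must share dimensions (got %s vs %s)", what,
                     paste(dim(x), collapse = "x"), paste(dim(y), collapse = "x")),
             "ribclear_dimension_error")
  invisible(TRUE)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Reflect-pad a matrix by p pixels on every side (edge rows mirrored,
# edge pixel not duplicated when possible).
pad_reflect <- function(m, p) {
  n <- nrow(m); k <- ncol(m)
  ri <- c(rev(seq_len(min(p, n - 1L)) + 1L), seq_len(n),
          n - seq_len(min(p, n - 1L)))
  ci <- c(rev(seq_len(min(p, k - 1L)) + 1L), seq_len(k),
          k - seq_len(min(p, k - 1L)))
  if (length(ri) < n + 2L * p || length(ci) < k + 2L * p)
    rc_abort("image too small to reflect-pad this far", "ribclear_dimension_error")
  m[ri, ci, drop = FALSE]
}

# Adjoint of pad_reflect: fold gradients from padded cells back onto the
# interior cells they were mirrored from.
fold_reflect <- function(dm, p, n, k) {
  ri <- c(rev(seq_len(p) + 1L), seq_len(n), n - seq_len(p))
  ci <- c(rev(seq_len(p) + 1L), seq_len(k), k - seq_len(p))
  out <- matrix(0, n, k)
  for (i in seq_along(ri))
    for (j in seq_along(ci))
      out[ri[i], ci[j]] <- out[ri[i], ci[j]] + dm[i, j]
  out
}

# Stack a list of matrices (H x W) into an (H, W, C, N) batch array.
as_batch <- function(images, channels = 1L) {
  h <- nrow(images[[1L]]); w <- ncol(images[[1L]])
  n <- length(images)
  x <- array(0, dim = c(h, w, channels, n))
  for (i in seq_len(n)) {
    m <- images[[i]]
    for (c in seq_len(channels)) x[, , c, i] <- m
  }
  x
}

# Average the channels of an (H, W, C, N) batch back to a list of matrices.
batch_to_images <- function(x) {
  n <- dim(x)[4L]
  lapply(seq_len(n), function(i) {
    if (dim(x)[3L] == 1L) x[, , 1L, i] else apply(x[, , , i, drop = FALSE], c(1, 2), mean)
  })
}
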
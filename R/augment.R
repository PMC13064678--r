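# Augmentation operators: affine transformations (rotation within +/-10
# degrees, translation within +/-5 pixels per axis, horizontal flipping,
# zooming) and intensity filters (median, maximum and minimum filtering,
# unsharp masking). Geometric operators are applied with identical
# parameters to source, target and rib mask (nearest-neighbour for the
# mask); intensity operators apply to source and target only. Edges are
# handled by reflect-padding before the geometric transform and
# center-cropping back to the original size.

.aug_kinds <- c("rotate", "translate", "hflip", "zoom",
                "median_filter", "max_filter", "min_filter", "unsharp_mask")

#' An augmentation operator
#'
#' @param kind One of `rotate`, `translate`, `hflip`, `zoom`,
#'   `median_filter`, `max_filter`, `min_filter`, `unsharp_mask`.
#' @param magnitude Kind-specific parameter: degrees in `[-10, 10]` for
#'   `rotate`; an integer pair in `[-5, 5]` for `translate`; a positive
#'   factor for `zoom`; an odd window size (default 3) for the rank filters;
#'   `c(amount, sigma)` (default `c(1, 1)`) for `unsharp_mask`; ignored for
#'   `hflip`. `NULL` defers the draw to application time (seeded).
#' @return An `augment_op` object.
#' @export
augment_op <- function(kind, magnitude = NULL) {
  if (!kind %in% .aug_kinds)
    rc_abort(sprintf("unknown augmentation kind '%s'", kind),
             "ribclear_validation_error")
  if (!is.null(magnitude)) .validate_magnitude(kind, magnitude)
  structure(list(kind = kind, magnitude = magnitude), class = "ribclear_augment_op")
}

.validate_magnitude <- function(kind, m) {
  bad <- function(msg) rc_abort(msg, "ribclear_validation_error")
  switch(kind,
    rotate = if (!is.numeric(m) || length(m) != 1L || abs(m) > 10)
      bad("rotation magnitude must be in [-10, 10] degrees"),
    translate = if (!is.numeric(m) || length(m) != 2L || any(abs(m) > 5))
      bad("translation magnitude must be a pair in [-5, 5] pixels"),
    zoom = if (!is.numeric(m) || length(m) != 1L || m <= 0)
      bad("zoom factor must be positive"),
    median_filter = ,
    max_filter = ,
    min_filter = if (!is.numeric(m) || length(m) != 1L || m < 3 || m %% 2 != 1)
      bad("filter window must be an odd integer >= 3"),
    unsharp_mask = if (!is.numeric(m) || length(m) != 2L || m[2] <= 0)
      bad("unsharp magnitude must be c(amount, sigma) with sigma > 0"),
    hflip = invisible(NULL))
  invisible(NULL)
}

.draw_magnitude <- function(kind) {
  switch(kind,
    rotate = runif(1, -10, 10),
    translate = sample(-5:5, 2L, replace = TRUE),
    zoom = runif(1, 0.9, 1.1),
    median_filter = 3,
    max_filter = 3,
    min_filter = 3,
    unsharp_mask = c(1, 1),
    hflip = NULL)
}

.geom_pad <- function(s) as.integer(ceiling(0.25 * s)) + 6L

.center_crop <- function(m, s) {
  off <- (dim(m) - s) %/% 2L
  m[off[1] + seq_len(s), off[2] + seq_len(s), drop = FALSE]
}

# apply one geometric op to a single matrix; `nearest` for masks
.apply_geom <- function(m, kind, mag, nearest = FALSE) {
  s <- nrow(m)
  filt <- if (nearest) "none" else "bilinear"
  switch(kind,
    hflip = m[, rev(seq_len(ncol(m))), drop = FALSE],
    translate = {
      p <- max(abs(mag)) + 1L
      mp <- pad_reflect(m, p)
      mp[(seq_len(s)) + p - mag[2], (seq_len(s)) + p - mag[1], drop = FALSE]
    },
    rotate = {
      p <- .geom_pad(s)
      mp <- pad_reflect(m, p)
      rp <- EBImage::rotate(EBImage::Image(mp), mag, filter = filt,
                            output.dim = dim(mp), bg.col = 0)
      .center_crop(EBImage::imageData(rp), s)
    },
    zoom = {
      p <- .geom_pad(s)
      mp <- pad_reflect(m, p)
      zs <- max(4L, as.integer(round(nrow(mp) * mag)))
      rp <- EBImage::resize(EBImage::Image(mp), w = zs, h = zs, filter = filt)
      rp <- EBImage::imageData(rp)
      if (nrow(rp) < s) rp <- pad_reflect(rp, ceiling((s - nrow(rp)) / 2) + 1L)
      .center_crop(rp, s)
    },
    stop("not a geometric op"))
}

# intensity ops operate on [0, 1] matrices
.apply_intensity <- function(m, kind, mag) {
  switch(kind,
    median_filter = EBImage::imageData(
      EBImage::medianFilter(EBImage::Image(clamp(m, 0, 1)), (mag - 1) / 2)),
    max_filter = EBImage::imageData(
      EBImage::dilate(EBImage::Image(m), EBImage::makeBrush(mag, "box"))),
    min_filter = EBImage::imageData(
      EBImage::erode(EBImage::Image(m), EBImage::makeBrush(mag, "box"))),
    unsharp_mask = {
      blur <- EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = mag[2]))
      clamp(m + mag[1] * (m - blur), 0, 1)
    },
    stop("not an intensity op"))
}

.is_geom <- function(kind) kind %in% c("rotate", "translate", "hflip", "zoom")

#' Augment an image pair
#'
#' Applies a sequence of [augment_op()]s. Geometric operators transform
#' source, target and rib mask with identical parameters (nearest-neighbour
#' resampling for the mask); intensity operators are applied identically to
#' source and target and leave the mask unchanged. Output dimensions always
#' equal input dimensions; values are clipped to the pair's declared range.
#'
#' @param pair An [image_pair()].
#' @param ops Nonempty list of [augment_op()]s. Operators created without a
#'   magnitude draw one (seeded) at application time.
#' @param seed Integer seed for deferred magnitude draws.
#' @return The augmented [image_pair()].
#' @export
augment_pair <- function(pair, ops, seed = 1L) {
  if (!inherits(pair, "ribclear_image_pair"))
    rc_abort("`pair` must be an image_pair", "ribclear_validation_error")
  if (length(ops) == 0L)
    rc_abort("`ops` must be nonempty", "ribclear_validation_error")
  if (inherits(ops, "ribclear_augment_op")) ops <- list(ops)
  withr::with_seed(seed, {
    src <- pair$source; tgt <- pair$target; msk <- pair$rib_mask
    lo <- pair$pixel_range[1]; hi <- pair$pixel_range[2]
    for (op in ops) {
      mag <- op$magnitude %||% .draw_magnitude(op$kind)
      .validate_magnitude(op$kind, mag)
      if (.is_geom(op$kind)) {
        src <- .apply_geom(src, op$kind, mag)
        tgt <- .apply_geom(tgt, op$kind, mag)
        if (!is.null(msk))
          msk <- .apply_geom(msk + 0, op$kind, mag, nearest = TRUE) > 0.5
      } else {
        u <- function(m) {
          m01 <- normalize_range(m, from = c(lo, hi), to = c(0, 1))
          out <- .apply_intensity(m01, op$kind, mag)
          normalize_range(out, from = c(0, 1), to = c(lo, hi))
        }
        src <- u(src); tgt <- u(tgt)
      }
      src <- clamp(src, lo, hi); tgt <- clamp(tgt, lo, hi)
    }
    image_pair(src, tgt, rib_mask = msk, pixel_range = pair$pixel_range)
  })
}

#' Default augmentation catalog
#'
#' One operator of each supported kind, magnitudes drawn at application
#' time within their valid ranges.
#'
#' @return List of [augment_op()]s.
#' @export
default_augment_catalog <- function() lapply(.aug_kinds, augment_op)

#' Expand a dataset by augmentation
#'
#' Produces `multiplier` copies of each pair: the first copy is the
#' unaugmented original, the rest are augmented with 1-3 operators drawn
#' from the catalog. All draws are reproducible from `seed`. An optional
#' `max_total` truncates the expanded collection.
#'
#' @param pairs Nonempty list of [image_pair()]s.
#' @param ops_catalog List of candidate [augment_op()]s.
#' @param multiplier Copies per input pair (>= 1).
#' @param seed Integer seed.
#' @param max_total Optional cap on the output length.
#' @return List of [image_pair()]s of length
#'   `min(length(pairs) * multiplier, max_total)`.
#' @export
expand_dataset <- function(pairs, ops_catalog = default_augment_catalog(),
                           multiplier = 2L, seed = 1L, max_total = NULL) {
  if (length(pairs) == 0L)
    rc_abort("`pairs` must be nonempty", "ribclear_argument_error")
  check_number(multiplier, "multiplier", min = 1, integerish = TRUE,
               class = "ribclear_argument_error")
  out <- vector("list", length(pairs) * multiplier)
  idx <- 1L
  for (i in seq_along(pairs)) {
    out[[idx]] <- pairs[[i]]; idx <- idx + 1L
    for (j in seq_len(multiplier - 1L)) {
      sub_seed <- (seed + 7919L * i + 104729L * j) %% .Machine$integer.max
      picks <- withr::with_seed(sub_seed, {
        k <- sample(seq_len(min(3L, length(ops_catalog))), 1L)
        sample(seq_along(ops_catalog), k, replace = FALSE)
      })
      out[[idx]] <- augment_pair(pairs[[i]], ops_catalog[picks],
                                 seed = sub_seed + 1L)
      idx <- idx + 1L
    }
  }
  if (!is.null(max_total) && length(out) > max_total) out <- out[seq_len(max_total)]
  out
}
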
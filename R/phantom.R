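# Synthetic chest phantoms: paired bone-present / bone-suppressed images
# with ground-truth rib masks. The bone-suppressed target is a smooth
# soft-tissue background (low-frequency cosine field with two darker
# elliptical lung fields), optional nodule blobs and acquisition noise;
# the source adds curved additive rib bands on top. Ribs act as structured
# corruption of the clean signal, which is what the suppression models
# must learn to remove.

#' Phantom configuration
#'
#' All intensity parameters are in normalized `[0, 1]` units. The rib
#' overlay profile falls smoothly to half its amplitude exactly at half the
#' rib width, so the ground-truth mask (overlay above half-amplitude) is the
#' geometric band of each rib.
#'
#' @param image_size Pixels per side (square), at least 16.
#' @param rib_count Number of rib bands (>= 0).
#' @param rib_intensity Additive amplitude of the rib overlay.
#' @param rib_width_range Length-2 range of rib widths in pixels.
#' @param rib_curvature Arc height of the rib centerline as a fraction of
#'   the image side.
#' @param nodule_count Number of Gaussian nodule blobs (present in both
#'   images).
#' @param nodule_amplitude Peak amplitude of a nodule.
#' @param background_smoothness Maximum spatial frequency of the background
#'   field in cycles per image side (smaller = smoother).
#' @param noise_sigma Gaussian acquisition-noise standard deviation.
#' @param seed Integer seed; the pair is a pure function of the config.
#' @return A `phantom_config` object.
#' @export
phantom_config <- function(image_size = 128L, rib_count = 8L,
                           rib_intensity = 0.25, rib_width_range = c(4, 8),
                           rib_curvature = 0.08, nodule_count = 2L,
                           nodule_amplitude = 0.12,
                           background_smoothness = 3, noise_sigma = 0.01,
                           seed = 1L) {
  check_number(image_size, "image_size", min = 16, integerish = TRUE)
  check_number(rib_count, "rib_count", min = 0, integerish = TRUE)
  check_number(rib_intensity, "rib_intensity", min = 0, max = 1)
  check_number(nodule_amplitude, "nodule_amplitude", min = 0, max = 1)
  check_number(nodule_count, "nodule_count", min = 0, integerish = TRUE)
  check_number(noise_sigma, "noise_sigma", min = 0)
  check_number(rib_curvature, "rib_curvature", min = 0)
  check_number(background_smoothness, "background_smoothness", min = 0.5)
  check_number(seed, "seed", integerish = TRUE)
  if (length(rib_width_range) != 2L || any(rib_width_range <= 0) ||
      rib_width_range[1] > rib_width_range[2])
    rc_abort("`rib_width_range` must be an increasing pair of positive widths",
             "ribclear_config_error")
  structure(list(image_size = as.integer(image_size),
                 rib_count = as.integer(rib_count),
                 rib_intensity = rib_intensity,
                 rib_width_range = rib_width_range,
                 rib_curvature = rib_curvature,
                 nodule_count = as.integer(nodule_count),
                 nodule_amplitude = nodule_amplitude,
                 background_smoothness = background_smoothness,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "ribclear_phantom_config")
}

#' A registered source/target image pair
#'
#' @param source Image with bone structures present.
#' @param target The same scene with bones suppressed.
#' @param rib_mask Optional logical matrix marking rib pixels.
#' @param pixel_range Declared value range, `c(0, 1)` or `c(-1, 1)`.
#' @return An `image_pair` object.
#' @export
image_pair <- function(source, target, rib_mask = NULL, pixel_range = c(0, 1)) {
  check_same_shape(source, target, "source and target")
  if (!is.null(rib_mask)) {
    check_same_shape(source, rib_mask, "source and rib_mask")
    if (!is.logical(rib_mask))
      rc_abort("`rib_mask` must be strictly logical", "ribclear_config_error")
  }
  if (!identical(as.numeric(pixel_range), c(0, 1)) &&
      !identical(as.numeric(pixel_range), c(-1, 1)))
    rc_abort("`pixel_range` must be c(0, 1) or c(-1, 1)", "ribclear_config_error")
  rng <- range(source, target)
  if (rng[1] < pixel_range[1] - 1e-9 || rng[2] > pixel_range[2] + 1e-9)
    rc_abort("pixel values fall outside the declared range", "ribclear_config_error")
  structure(list(source = source, target = target, rib_mask = rib_mask,
                 pixel_range = as.numeric(pixel_range)),
            class = "ribclear_image_pair")
}

#' @export
print.ribclear_image_pair <- function(x, ...) {
  cat(sprintf("<image pair %dx%d, range [%g, %g], rib mask: %s>\n",
              nrow(x$source), ncol(x$source), x$pixel_range[1], x$pixel_range[2],
              if (is.null(x$rib_mask)) "none"
              else sprintf("%d px", sum(x$rib_mask))))
  invisible(x)
}

.phantom_background <- function(s, smooth) {
  # low-frequency cosine field
  xx <- matrix(seq(0, 1, length.out = s), s, s, byrow = TRUE)
  yy <- matrix(seq(0, 1, length.out = s), s, s)
  bg <- matrix(0, s, s)
  for (k in 1:6) {
    fx <- runif(1, 0.2, smooth); fy <- runif(1, 0.2, smooth)
    ph <- runif(2, 0, 2 * pi)
    bg <- bg + (1 / k) * cos(2 * pi * (fx * xx) + ph[1]) *
                         cos(2 * pi * (fy * yy) + ph[2])
  }
  bg <- (bg - mean(bg)) / max(abs(bg - mean(bg)))
  bg <- 0.55 + 0.12 * bg
  # two darker elliptical lung fields
  for (cx in c(0.32, 0.68)) {
    e <- ((xx - cx) / 0.17)^2 + ((yy - 0.47) / 0.30)^2
    bg <- bg - 0.13 / (1 + exp((e - 1) * 6))
  }
  bg
}

.phantom_ribs <- function(s, cfg) {
  overlay <- matrix(0, s, s)
  if (cfg$rib_count == 0L) return(list(overlay = overlay, mask = overlay > 0))
  xx <- seq_len(s)
  rowp <- matrix(seq_len(s), s, s)  # row index per cell
  for (r in seq_len(cfg$rib_count)) {
    y0 <- s * (0.12 + 0.76 * (r - 0.5) / cfg$rib_count) + runif(1, -0.02, 0.02) * s
    arc <- cfg$rib_curvature * s * runif(1, 0.6, 1.4)
    slope <- runif(1, -0.05, 0.05)
    w <- runif(1, cfg$rib_width_range[1], cfg$rib_width_range[2])
    yc <- y0 + arc * ((xx - s / 2) / s)^2 * 4 + slope * (xx - s / 2)
    dist <- abs(sweep(rowp, 2, yc))   # |row - centerline| per column
    prof <- cfg$rib_intensity * exp(-log(2) * (2 * dist / w)^4)
    overlay <- pmax(overlay, prof)
  }
  list(overlay = overlay, mask = overlay > 0.5 * cfg$rib_intensity)
}

#' Generate one phantom pair
#'
#' The target is `background (+ nodules) + noise`, clipped to `[0, 1]`; the
#' source is `clip(target + rib overlay)`. The rib mask marks pixels where
#' the overlay exceeds half its amplitude, so for positive rib intensity the
#' source-target difference outside the mask stays below half-amplitude by
#' construction. Fully determined by `config` (including its seed).
#'
#' @param config A [phantom_config()].
#' @return An [image_pair()] with ground-truth `rib_mask`.
#' @export
generate_phantom_pair <- function(config) {
  if (!inherits(config, "ribclear_phantom_config"))
    rc_abort("`config` must be a phantom_config", "ribclear_config_error")
  s <- config$image_size
  withr::with_seed(config$seed, {
    bg <- .phantom_background(s, config$background_smoothness)
    if (config$nodule_count > 0L) {
      xx <- matrix(seq_len(s), s, s, byrow = TRUE)
      yy <- matrix(seq_len(s), s, s)
      for (k in seq_len(config$nodule_count)) {
        cx <- runif(1, 0.2, 0.8) * s; cy <- runif(1, 0.25, 0.75) * s
        sig <- runif(1, 0.02, 0.05) * s
        bg <- bg + config$nodule_amplitude *
          exp(-((xx - cx)^2 + (yy - cy)^2) / (2 * sig^2))
      }
    }
    if (config$noise_sigma > 0)
      bg <- bg + matrix(rnorm(s * s, sd = config$noise_sigma), s, s)
    target <- clamp(bg, 0, 1)
    ribs <- .phantom_ribs(s, config)
    source <- clamp(target + ribs$overlay, 0, 1)
    image_pair(source, target, rib_mask = ribs$mask)
  })
}

#' Generate an ordered collection of phantom pairs
#'
#' Pair `i` (1-based) is generated with seed `config$seed + i - 1`, so the
#' collection is reproducible and extendable.
#'
#' @param config A [phantom_config()].
#' @param n_pairs Number of pairs (>= 1).
#' @return List of [image_pair()] objects.
#' @export
generate_dataset <- function(config, n_pairs) {
  check_number(n_pairs, "n_pairs", min = 1, integerish = TRUE,
               class = "ribclear_argument_error")
  lapply(seq_len(n_pairs) - 1L, function(i) {
    ci <- config
    ci$seed <- config$seed + i
    generate_phantom_pair(ci)
  })
}
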
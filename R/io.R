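# Image and raw-format I/O plus range normalization.

#' Read a grayscale image into the unit interval
#'
#' Supports 8/16-bit grayscale PNG and TIFF. Multi-channel files are
#' averaged to one channel. PNG values arrive pre-scaled by the reader;
#' TIFF values are scaled by `1/(2^depth - 1)` using the file's declared
#' bit depth.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @param expected_bit_depth Optional; for TIFF, error if the file's bit
#'   depth differs.
#' @return Image matrix with values in `[0, 1]`.
#' @export
read_image <- function(path, expected_bit_depth = NULL) {
  if (!file.exists(path))
    rc_abort(sprintf("file not found: %s", path), "ribclear_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    info <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bits <- attr(info, "bits.per.sample") %||% 8L
    if (!is.null(expected_bit_depth) && bits != expected_bit_depth)
      rc_abort(sprintf("expected %d-bit TIFF, file is %d-bit",
                       expected_bit_depth, bits), "ribclear_format_error")
    img <- info / (2^bits - 1)
  } else {
    rc_abort(sprintf("unsupported image format '.%s' (use PNG or TIFF)", ext),
             "ribclear_format_error")
  }
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  img
}

#' Write a grayscale image
#'
#' TIFF supports 8 or 16 bits per sample; PNG is written at 8 bits (the
#' installed PNG writer's depth).
#'
#' @param image Matrix with values in `[0, 1]`.
#' @param path Output path (`.png`, `.tif`, `.tiff`).
#' @param bit_depth 8 or 16 (TIFF only).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bit_depth = 16L) {
  ext <- tolower(tools::file_ext(path))
  image <- clamp(image, 0, 1)
  if (ext == "png") {
    png::writePNG(image, path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!bit_depth %in% c(8L, 16L))
      rc_abort("`bit_depth` must be 8 or 16", "ribclear_format_error")
    tiff::writeTIFF(image, path, bits.per.sample = bit_depth)
  } else {
    rc_abort(sprintf("unsupported image format '.%s'", ext),
             "ribclear_format_error")
  }
  invisible(path)
}

#' Read a headerless big-endian raw radiograph
#'
#' The classic digitized-radiograph interchange layout: 2048 x 2048 pixels
#' stored as headerless big-endian 16-bit words holding 12-bit samples
#' (0.175 mm pixel spacing in the originals). Values are scaled by
#' `1/(2^12 - 1)`. Samples are assumed right-aligned in the 16-bit words;
#' set `left_aligned = TRUE` for the alternative packing.
#'
#' @param path File path; size must be exactly `width * height * 2` bytes.
#' @param width,height Image dimensions (default 2048 x 2048).
#' @param left_aligned If `TRUE`, samples occupy the high 12 bits.
#' @return Image matrix in `[0, 1]`, `height` rows by `width` columns,
#'   row-major pixel order.
#' @export
read_jsrt_raw <- function(path, width = 2048L, height = 2048L,
                          left_aligned = FALSE) {
  if (!file.exists(path))
    rc_abort(sprintf("file not found: %s", path), "ribclear_io_error")
  expected <- as.numeric(width) * height * 2
  actual <- file.size(path)
  if (actual != expected)
    rc_abort(sprintf("raw file size mismatch: expected %.0f bytes (%dx%dx2), got %.0f",
                     expected, width, height, actual), "ribclear_format_error")
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, what = "integer", n = width * height, size = 2L,
               signed = FALSE, endian = "big")
  if (left_aligned) v <- v %/% 16L
  matrix(v / 4095, nrow = height, ncol = width, byrow = TRUE)
}

#' @rdname read_jsrt_raw
#' @param image Matrix in `[0, 1]` to write as 12-bit big-endian raw.
#' @export
write_jsrt_raw <- function(image, path, left_aligned = FALSE) {
  v <- as.integer(round(clamp(image, 0, 1) * 4095))
  if (left_aligned) v <- v * 16L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(t(matrix(v, nrow(image), ncol(image)))),
           con, size = 2L, endian = "big")
  invisible(path)
}

#' Affine range normalization
#'
#' Maps `from[1] -> to[1]` and `from[2] -> to[2]` linearly; composing with
#' the inverse mapping is the identity to machine precision.
#'
#' @param image Numeric array.
#' @param from,to Length-2 numeric ranges with distinct endpoints.
#' @return Rescaled array.
#' @export
normalize_range <- function(image, from = c(0, 1), to = c(-1, 1)) {
  if (length(from) != 2L || length(to) != 2L || from[2] == from[1] ||
      to[2] == to[1])
    rc_abort("`from` and `to` must be length-2 ranges with distinct endpoints",
             "ribclear_argument_error")
  (image - from[1]) / (from[2] - from[1]) * (to[2] - to[1]) + to[1]
}
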
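#' Construct a fluorescence channel image
#'
#' A `channel_image` wraps one grayscale fluorescence channel as a numeric
#' matrix in arbitrary intensity units, together with its nominal bit depth
#' and (optionally) the physical pixel size. All pipeline stages use the
#' `(row, col)` convention with 0-based coordinates and pixel centers at
#' integer positions.
#'
#' @param pixels Numeric matrix of non-negative, finite intensities.
#' @param bit_depth Integer nominal bit depth (8 or 16 for TIFF I/O).
#' @param pixel_size Optional physical pixel size in micrometres per pixel.
#'
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, bit_depth = 16L, pixel_size = NULL) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (!all(is.finite(pixels))) {
    stop("channel_image: pixel intensities must be finite", call. = FALSE)
  }
  if (any(pixels < 0)) {
    stop("channel_image: pixel intensities must be non-negative", call. = FALSE)
  }
  structure(
    list(pixels = pixels, bit_depth = as.integer(bit_depth),
         pixel_size = pixel_size),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %d x %d px, %d-bit, range [%.6g, %.6g]\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.channel_image <- function(x) dim(x$pixels)

as_pixels <- function(image) {
  if (inherits(image, "channel_image")) image$pixels else as.matrix(image)
}

#' Read a grayscale TIFF channel
#'
#' Accepts single-plane 8- or 16-bit grayscale TIFF files and preserves the
#' stored integer intensities exactly. Multi-sample (RGB/RGBA) images are
#' rejected: the pipeline operates on one fluorescence channel per file.
#'
#' @param path Path to the TIFF file.
#' @return A [channel_image()].
#' @export
read_channel_tiff <- function(path) {
  if (!file.exists(path)) {
    stop("read_channel_tiff: no such file: ", path, call. = FALSE)
  }
  raw <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
  bits_attr <- attr(raw, "bits.per.sample")
  attributes(raw) <- list(dim = dim(raw))
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3] > 1L) {
      stop("read_channel_tiff: unsupported multi-channel (RGB) TIFF; ",
           "expected single-sample grayscale: ", path, call. = FALSE)
    }
    raw <- raw[, , 1L]
  }
  bits <- bits_attr
  if (is.null(bits)) bits <- if (max(raw) > 255) 16L else 8L
  channel_image(raw, bit_depth = as.integer(bits))
}

#' Write a channel image as grayscale TIFF
#'
#' Intensities are rounded to integers and stored at the image's bit depth;
#' values outside the representable range raise an error rather than being
#' clipped silently.
#'
#' @param image A [channel_image()] (or plain matrix).
#' @param path Output path.
#' @param bit_depth 8 or 16.
#' @return `path`, invisibly.
#' @export
write_channel_tiff <- function(image, path, bit_depth = 16L) {
  px <- round(as_pixels(image))
  maxval <- 2^bit_depth - 1
  if (max(px) > maxval) {
    stop("write_channel_tiff: intensities exceed ", bit_depth,
         "-bit range; rescale before writing", call. = FALSE)
  }
  tiff::writeTIFF(px / maxval, path, bits.per.sample = as.integer(bit_depth))
  invisible(path)
}
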
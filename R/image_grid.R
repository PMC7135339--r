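#' Image raster container
#'
#' A light wrapper around a numeric matrix of non-negative fluorescence
#' intensities, carrying its bit depth. All filters in the package operate
#' on `image_grid` objects (plain matrices are coerced with `bit_depth =
#' "float"`).
#'
#' @param pixels numeric matrix, all values finite and >= 0.
#' @param bit_depth one of `8`, `16` or `"float"`. Integer depths bound the
#'   admissible intensity range (255 / 65535).
#' @return An `image_grid` object.
#' @export
image_grid <- function(pixels, bit_depth = "float") {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  bit_depth <- as.character(bit_depth)
  if (!bit_depth %in% c("8", "16", "float")) {
    stop("bit_depth must be 8, 16 or \"float\"")
  }
  if (!all(is.finite(pixels))) stop("all intensities must be finite")
  if (any(pixels < 0)) stop("all intensities must be >= 0")
  if (bit_depth == "8" && any(pixels > 255)) stop("8-bit values must be <= 255")
  if (bit_depth == "16" && any(pixels > 65535)) {
    stop("16-bit values must be <= 65535")
  }
  structure(list(pixels = pixels, bit_depth = bit_depth),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid %d x %d, %s-bit, range [%g, %g]>\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.image_grid <- function(x) dim(x$pixels)

as_image_grid <- function(x, bit_depth = "float") {
  if (inherits(x, "image_grid")) x else image_grid(x, bit_depth)
}

check_min_shape <- function(img, n = 3L) {
  if (any(dim(img$pixels) < n)) {
    stop(sprintf("image must be at least %dx%d for neighborhood operations",
                 n, n))
  }
}

#' Convert an image to 8-bit by a linear min-max map
#'
#' Maps the intensity range `[lo, hi]` linearly onto `[0, 255]` with
#' round-half-up. By default `lo`/`hi` are the image minimum and maximum,
#' which makes the downstream mask invariant under affine intensity
#' rescaling; explicit display limits may be supplied instead. A constant
#' image maps to all zeros.
#'
#' @param img an [image_grid()] (or matrix).
#' @param lo,hi optional explicit range limits; values outside are clipped.
#' @return An 8-bit `image_grid`.
#' @export
convert_to_8bit <- function(img, lo = NULL, hi = NULL) {
  img <- as_image_grid(img)
  px <- img$pixels
  if (is.null(lo)) lo <- min(px)
  if (is.null(hi)) hi <- max(px)
  if (hi <= lo) {
    out <- matrix(0, nrow(px), ncol(px))
  } else {
    out <- floor(255 * (pmin(pmax(px, lo), hi) - lo) / (hi - lo) + 0.5)
  }
  image_grid(out, 8)
}

#' 256-bin intensity histogram of an 8-bit image
#'
#' @param img an 8-bit [image_grid()].
#' @return Integer vector of 256 counts; bin `i + 1` holds gray level `i`.
#' @export
intensity_histogram <- function(img) {
  img <- as_image_grid(img)
  px <- img$pixels
  if (any(px != floor(px)) || any(px > 255)) {
    stop("intensity_histogram expects integer gray levels in 0..255")
  }
  counts <- tabulate(as.integer(px) + 1L, nbins = 256L)
  stopifnot(sum(counts) == length(px))
  counts
}

#' Rescale an arbitrary raster to 8-bit gray levels
#'
#' Min-max linear rescale to `[0, 255]`, round-half-up; used to requantize
#' the floating-point tubeness response before IsoData thresholding.
#'
#' @param x numeric matrix.
#' @return An 8-bit `image_grid`.
#' @export
rescale_to_8bit <- function(x) {
  if (inherits(x, "image_grid")) x <- x$pixels
  convert_to_8bit(image_grid(pmax(x, 0), "float"))
}
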
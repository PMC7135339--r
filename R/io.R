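#' Read a grayscale TIFF as an image grid
#'
#' Single-plane 8- or 16-bit grayscale TIFF; multi-page files are
#' returned as a list of independent images. Pixel values are kept on
#' their native integer scale.
#'
#' @param path file path.
#' @return An [image_grid()] (or list of them for multi-page files).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read image: %s", path))
  raw <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                  error = function(e) {
                    stop(sprintf("malformed TIFF %s: %s", path,
                                 conditionMessage(e)))
                  })
  one <- function(m) {
    if (length(dim(m)) == 3) {
      if (dim(m)[3] != 1) stop("only single-channel grayscale supported")
      m <- m[, , 1]
    }
    depth <- attr(m, "bits.per.sample")
    if (is.null(depth)) depth <- if (max(m) > 255) 16 else 8
    if (!depth %in% c(8, 16)) stop("bit depth must be 8 or 16")
    image_grid(m, depth)
  }
  imgs <- lapply(raw, one)
  if (length(imgs) == 1) imgs[[1]] else imgs
}

#' Write an image grid to a grayscale TIFF
#'
#' Round-trips bit depth and pixel values exactly for 8- and 16-bit
#' images.
#'
#' @param img an [image_grid()] with integer bit depth.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  img <- as_image_grid(img)
  depth <- switch(img$bit_depth, "8" = 8L, "16" = 16L,
                  stop("write_image supports 8- and 16-bit images"))
  top <- if (depth == 8L) 255 else 65535
  tiff::writeTIFF(img$pixels / top, path, bits.per.sample = depth)
  invisible(path)
}

#' Write a segmentation mask as an 8-bit TIFF plus a component CSV
#'
#' The mask raster is written 0/255; the companion CSV lists per-label
#' area and centroid (0-based row/col pixel coordinates).
#'
#' @param mask a [seg_mask()].
#' @param path output TIFF path; the CSV is written next to it with a
#'   `.csv` extension.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "seg_mask"))
  write_image(image_grid(ifelse(mask$values, 255, 0), 8), path)
  write.csv(component_table(mask), sub("\\.tiff?$", ".csv", path),
            row.names = FALSE)
  invisible(path)
}

#' Read/write measurement tables
#'
#' Thin CSV wrappers that preserve missing cells and column order.
#'
#' @param path file path.
#' @return `read_table()` returns a data frame.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read table: %s", path))
  read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_table
#' @param x data frame to write.
#' @export
write_table <- function(x, path) {
  write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}
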
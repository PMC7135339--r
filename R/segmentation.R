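#' Segmentation mask container
#'
#' Pairs a boolean foreground raster with an integer label raster
#' (0 = background, components numbered `1..n` contiguously) and the
#' per-label pixel areas.
#'
#' @param labels integer matrix of component labels.
#' @return A `seg_mask` object with elements `values` (logical matrix),
#'   `labels` (integer matrix) and `areas` (named integer vector).
#' @export
seg_mask <- function(labels) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  n <- max(labels, 0L)
  areas <- if (n > 0) tabulate(labels[labels > 0L], nbins = n) else integer(0)
  if (n > 0 && any(areas == 0L)) stop("labels must be contiguous 1..n")
  if (n > 0) names(areas) <- as.character(seq_len(n))
  structure(list(values = labels > 0L, labels = labels,
                 areas = as.integer(areas)),
            class = "seg_mask")
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask %d x %d, %d components, %d foreground px>\n",
              nrow(x$values), ncol(x$values), length(x$areas),
              sum(x$values)))
  invisible(x)
}

#' Label connected components of a binary mask
#'
#' @param mask logical matrix (or a `seg_mask`, whose boolean raster is
#'   relabeled).
#' @param connectivity 4 or 8 (default 8, the usual particle-analysis
#'   behavior).
#' @return A [seg_mask()] with labels `1..n` and per-label areas.
#' @export
label_components <- function(mask, connectivity = 8) {
  if (inherits(mask, "seg_mask")) mask <- mask$values
  mask <- as.matrix(mask)
  if (!is.logical(mask)) mask <- mask > 0
  stopifnot(connectivity %in% c(4, 8))
  seg_mask(cpp_label_components(mask, as.integer(connectivity)))
}

#' Remove components smaller than a minimum pixel area
#'
#' Components with area strictly below `min_px` are removed (an area of
#' exactly `min_px` survives); survivors are relabeled contiguously in
#' their original order.
#'
#' @param mask a [seg_mask()].
#' @param min_px minimum area in pixels (default 10).
#' @return A filtered `seg_mask`.
#' @export
filter_small_particles <- function(mask, min_px = 10) {
  stopifnot(inherits(mask, "seg_mask"))
  keep <- which(mask$areas >= min_px)
  remap <- integer(length(mask$areas))
  remap[keep] <- seq_along(keep)
  lab <- mask$labels
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  seg_mask(lab)
}

#' Drop named components from a mask
#'
#' Machine-readable stand-in for the manual removal of unwanted objects:
#' the listed label ids are cleared and the rest relabeled contiguously.
#'
#' @param mask a [seg_mask()].
#' @param exclusions integer vector of label ids to remove.
#' @return A `seg_mask` without the excluded components.
#' @export
exclude_components <- function(mask, exclusions) {
  stopifnot(inherits(mask, "seg_mask"))
  if (length(exclusions) == 0) return(mask)
  keep <- setdiff(seq_along(mask$areas), as.integer(exclusions))
  remap <- integer(length(mask$areas))
  remap[keep] <- seq_along(keep)
  lab <- mask$labels
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  seg_mask(lab)
}

#' Mean intensity inside and outside a mask
#'
#' Computed on the raw (unfiltered) image: the masked mean is the
#' foreground readout and the mean outside the mask defines the
#' background.
#'
#' @param img an [image_grid()] or matrix.
#' @param mask a [seg_mask()] or logical matrix of the same shape.
#' @return List with `mean_inside`, `mean_outside` (NA with a flag if the
#'   mask covers the whole image) and `foreground_area`.
#' @export
masked_stats <- function(img, mask) {
  img <- as_image_grid(img)
  m <- if (inherits(mask, "seg_mask")) mask$values else as.matrix(mask) > 0
  if (!all(dim(m) == dim(img$pixels))) stop("mask and image shapes differ")
  n_in <- sum(m)
  if (n_in == 0) stop_wormupr("empty_mask", "mask has no foreground pixels")
  full <- n_in == length(m)
  list(
    mean_inside = mean(img$pixels[m]),
    mean_outside = if (full) NA_real_ else mean(img$pixels[!m]),
    foreground_area = n_in,
    full_mask = full
  )
}

#' Per-component areas and centroids
#'
#' @param mask a [seg_mask()].
#' @return Data frame with `label`, `area`, `centroid_row`, `centroid_col`
#'   (0-based pixel coordinates).
#' @export
component_table <- function(mask) {
  stopifnot(inherits(mask, "seg_mask"))
  n <- length(mask$areas)
  if (n == 0) {
    return(data.frame(label = integer(0), area = integer(0),
                      centroid_row = numeric(0), centroid_col = numeric(0)))
  }
  idx <- which(mask$labels > 0L, arr.ind = TRUE)
  lab <- mask$labels[mask$labels > 0L]
  data.frame(
    label = seq_len(n),
    area = mask$areas,
    centroid_row = as.numeric(tapply(idx[, 1] - 1, lab, mean)),
    centroid_col = as.numeric(tapply(idx[, 2] - 1, lab, mean)),
    row.names = NULL
  )
}
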
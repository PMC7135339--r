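#' Segment whole animals in a reporter image
#'
#' Triangle auto-threshold on the 8-bit histogram, foreground taken as the
#' bright side, followed by the minimum-size particle filter and removal
#' of explicitly excluded component labels (the reproducible stand-in for
#' manual clean-up).
#'
#' @param img an [image_grid()] or matrix (any bit depth; converted to
#'   8-bit for thresholding).
#' @param min_px minimum particle area in pixels (default 10).
#' @param exclusions optional integer labels to drop after filtering.
#' @param connectivity 4 or 8 (default 8).
#' @return A [seg_mask()] of the animals.
#' @export
segment_animals <- function(img, min_px = 10, exclusions = NULL,
                            connectivity = 8) {
  img8 <- convert_to_8bit(img)
  thr <- triangle_threshold(intensity_histogram(img8))
  mask <- label_components(img8$pixels > thr, connectivity)
  mask <- filter_small_particles(mask, min_px)
  if (!is.null(exclusions)) mask <- exclude_components(mask, exclusions)
  mask
}

#' Quantify a reporter image under its animal mask
#'
#' Mean fluorescence intensity is measured on the raw image under the
#' mask; the mean outside the mask is reported as the background.
#'
#' @param img raw [image_grid()] or matrix.
#' @param mask a [seg_mask()] from [segment_animals()].
#' @param image_id,group identifiers carried into the measurement row.
#' @return One-row data frame: `image_id`, `group`, `mean_inside`,
#'   `background`, `n_animals_est`, `foreground_area`.
#' @export
quantify_reporter <- function(img, mask, image_id = NA_character_,
                              group = NA_character_) {
  st <- masked_stats(img, mask)
  data.frame(
    image_id = image_id,
    group = group,
    mean_inside = st$mean_inside,
    background = st$mean_outside,
    n_animals_est = length(mask$areas),
    foreground_area = st$foreground_area,
    stringsAsFactors = FALSE
  )
}

#' Baseline-and-scale group normalization of reporter measurements
#'
#' Subtracts the mean of the wild-type control group and divides by the
#' span to the stressed-mutant control group:
#' `normalized = (x - mean(wt)) / (mean(mutant) - mean(wt))`.
#' The wild-type control group then averages 0 and the mutant control
#' group averages 1. Optionally the per-image background is subtracted
#' from `mean_inside` first (off by default: the group normalization
#' already removes a shared baseline).
#'
#' @param measurements data frame with columns `group` and `mean_inside`
#'   (e.g. rows from [quantify_reporter()]).
#' @param wt_control_label,mutant_control_label the two reference groups.
#' @param value_col column to normalize (default `"mean_inside"`).
#' @param subtract_background if `TRUE`, use
#'   `mean_inside - background` as the raw value.
#' @return The input with a `normalized` column added.
#' @export
normalize_groups <- function(measurements, wt_control_label,
                             mutant_control_label,
                             value_col = "mean_inside",
                             subtract_background = FALSE) {
  stopifnot(wt_control_label != mutant_control_label)
  x <- measurements[[value_col]]
  if (subtract_background) x <- x - measurements$background
  wt <- x[measurements$group == wt_control_label]
  mut <- x[measurements$group == mutant_control_label]
  if (length(wt) < 1 || length(mut) < 1) {
    stop_wormupr("insufficient_data",
                 "both normalization reference groups need measurements")
  }
  denom <- mean(mut) - mean(wt)
  if (denom <= 0) {
    stop_wormupr("normalization_error",
                 "mutant control group does not exceed the wild-type baseline")
  }
  measurements$normalized <- (x - mean(wt)) / denom
  measurements
}

#' Scale normalization to a single control group
#'
#' `normalized = x / mean(control group)`.
#'
#' @inheritParams normalize_groups
#' @param control_label group whose mean becomes 1.
#' @return The input with a `normalized` column added.
#' @export
normalize_to_control <- function(measurements, control_label,
                                 value_col = "mean_inside") {
  x <- measurements[[value_col]]
  ctrl <- x[measurements$group == control_label]
  if (length(ctrl) < 1) {
    stop_wormupr("insufficient_data", "control group has no measurements")
  }
  m <- mean(ctrl)
  if (m <= 0) {
    stop_wormupr("normalization_error", "control group mean is not positive")
  }
  measurements$normalized <- x / m
  measurements
}

#' Percent suppression of a normalized treatment group
#'
#' On the scale where the stressed control averages 1, suppression is
#' `100 * (1 - mean(normalized treatment group))`; a fully suppressed
#' group (normalized mean 0) reads 100%.
#'
#' @param normalized_values normalized measurements of one group.
#' @return Percent suppression (can be negative for enhancement).
#' @export
percent_suppression <- function(normalized_values) {
  100 * (1 - mean(normalized_values))
}
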
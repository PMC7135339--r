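#' Tubeness-pipeline configuration
#'
#' Parameters of the mitochondrial segmentation workflow, with the
#' published defaults: Gaussian scale 1.0 px, rolling-ball radius 15 px,
#' minimum filter radius 1, mean filter radius 2, 10-px particle cutoff.
#'
#' @param sigma Gaussian scale in pixels.
#' @param ball_radius rolling-ball radius in pixels.
#' @param min_filter_radius,mean_filter_radius rank/mean filter radii.
#' @param min_particle_px minimum particle area in pixels.
#' @param connectivity 4 or 8.
#' @return A `tubeness_config` list.
#' @export
tubeness_config <- function(sigma = 1.0, ball_radius = 15,
                            min_filter_radius = 1, mean_filter_radius = 2,
                            min_particle_px = 10, connectivity = 8) {
  stopifnot(sigma > 0, ball_radius > 0, min_filter_radius > 0,
            mean_filter_radius > 0, min_particle_px > 0,
            min_particle_px == floor(min_particle_px))
  structure(list(sigma = sigma, ball_radius = ball_radius,
                 min_filter_radius = min_filter_radius,
                 mean_filter_radius = mean_filter_radius,
                 min_particle_px = as.integer(min_particle_px),
                 connectivity = connectivity),
            class = "tubeness_config")
}

#' Segment mitochondria by the tubeness workflow
#'
#' Applies, in order: 8-bit conversion, rolling-ball background
#' subtraction (keeping the subtracted image), minimum filter, mean
#' filter, tubeness at the configured scale, min-max requantization to
#' 8-bit, IsoData thresholding (foreground above the threshold) and
#' removal of sub-threshold particles.
#'
#' @param img raw [image_grid()] or matrix.
#' @param cfg a [tubeness_config()].
#' @return A [seg_mask()] of mitochondrial structures.
#' @export
segment_mitochondria <- function(img, cfg = tubeness_config()) {
  img8 <- convert_to_8bit(img)
  sub <- rolling_ball_background(img8, cfg$ball_radius)$subtracted
  flt <- minimum_filter(sub, cfg$min_filter_radius)
  flt <- mean_filter(flt, cfg$mean_filter_radius)
  tub <- tubeness(flt, cfg$sigma)
  tub8 <- rescale_to_8bit(tub)
  thr <- isodata_threshold(intensity_histogram(tub8))
  mask <- label_components(tub8$pixels > thr, cfg$connectivity)
  filter_small_particles(mask, cfg$min_particle_px)
}

#' TMRE intensity per mitochondrial area
#'
#' Mean of the raw (unprocessed) intensities under the mitochondrial
#' mask — the membrane-potential proxy — together with the mask area.
#'
#' @param raw raw [image_grid()] or matrix from the same field of view.
#' @param mask a [seg_mask()] from [segment_mitochondria()].
#' @param image_id,group identifiers carried into the measurement row.
#' @return One-row data frame: `image_id`, `group`, `intensity_per_area`,
#'   `mito_area_px`, `n_components`.
#' @export
tmre_intensity <- function(raw, mask, image_id = NA_character_,
                           group = NA_character_) {
  st <- masked_stats(raw, mask)
  data.frame(
    image_id = image_id,
    group = group,
    intensity_per_area = st$mean_inside,
    mito_area_px = st$foreground_area,
    n_components = length(mask$areas),
    stringsAsFactors = FALSE
  )
}

#' Normalize TMRE measurements to a control group
#'
#' Scale normalization (control-group mean becomes 1) on the
#' intensity-per-area values.
#'
#' @param measurements data frame with `group` and `intensity_per_area`.
#' @param control_label reference group.
#' @return The input with a `normalized` column added.
#' @export
normalize_tmre <- function(measurements, control_label) {
  normalize_to_control(measurements, control_label,
                       value_col = "intensity_per_area")
}
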
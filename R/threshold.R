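#' Triangle automatic threshold
#'
#' Geometric threshold selection: draw the line from the histogram peak to
#' the far end of the occupied range and return the gray level maximizing
#' the perpendicular distance from the histogram to that line. If the peak
#' lies in the upper half of the occupied range the histogram is mirrored
#' first and the result mirrored back. Ties resolve to the first (lowest)
#' bin achieving the maximum.
#'
#' @param counts integer vector of 256 histogram counts (bin `i+1` = gray
#'   level `i`), e.g. from [intensity_histogram()]. Shorter vectors are
#'   treated as levels `0..length-1`.
#' @return Integer gray level within the occupied range.
#' @export
triangle_threshold <- function(counts) {
  counts <- as.numeric(counts)
  occ <- which(counts > 0) - 1L
  if (length(occ) < 2L) {
    stop_wormupr("degenerate_histogram",
                 "triangle threshold needs at least two populated bins")
  }
  n <- length(counts)
  lo <- min(occ); hi <- max(occ)
  peak <- which.max(counts) - 1L
  mirrored <- (peak - lo) > (hi - peak)
  if (mirrored) {
    counts <- rev(counts)
    lo2 <- (n - 1L) - hi; hi2 <- (n - 1L) - lo
    lo <- lo2; hi <- hi2
    peak <- which.max(counts) - 1L
  }
  # peak now on the left; the far tail is the highest occupied bin
  hp <- counts[peak + 1L]
  hq <- counts[hi + 1L]
  b <- peak:hi
  num <- abs((hi - peak) * (hp - counts[b + 1L]) - (peak - b) * (hq - hp))
  t <- b[which.max(num)]
  if (mirrored) t <- (n - 1L) - t
  as.integer(t)
}

#' IsoData (intermeans) automatic threshold
#'
#' Classic Ridler-Calvard iteration: starting at the overall mean gray
#' level, replace the threshold with the average of the mean at-or-below
#' and the mean above it, until a fixed point (in integer gray levels) is
#' reached.
#'
#' @inheritParams triangle_threshold
#' @return Integer gray level within the occupied range.
#' @export
isodata_threshold <- function(counts) {
  counts <- as.numeric(counts)
  occ <- which(counts > 0) - 1L
  if (length(occ) < 2L) {
    stop_wormupr("degenerate_histogram",
                 "isodata threshold needs at least two populated bins")
  }
  levels <- seq_along(counts) - 1L
  wmean <- function(idx) sum(levels[idx] * counts[idx]) / sum(counts[idx])
  t <- floor(sum(levels * counts) / sum(counts) + 0.5)
  t <- min(max(t, min(occ)), max(occ) - 1L)
  seen <- integer(0)
  repeat {
    below <- levels <= t & counts > 0
    above <- levels > t & counts > 0
    if (!any(above)) { t <- max(occ) - 1L; break }
    if (!any(below)) { t <- min(occ); next }
    tn <- floor((wmean(below) + wmean(above)) / 2 + 0.5)
    tn <- min(max(tn, min(occ)), max(occ) - 1L)
    if (tn == t) break
    if (tn %in% seen) { t <- min(t, tn); break }  # 2-cycle guard
    seen <- c(seen, t)
    t <- tn
  }
  as.integer(t)
}
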
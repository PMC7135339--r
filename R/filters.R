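#' Neighborhood offsets for rank and mean filters
#'
#' Two discrete-disk conventions are supported. `"rank"` reproduces the
#' common GUI rank-filter kernel (offsets with `dx^2 + dy^2 <= r^2 + 1`),
#' which gives the full 3x3 square at radius 1. `"disk"` keeps pixel
#' centers strictly within the radius (`dx^2 + dy^2 <= r^2`). `"square"`
#' is the `(2r+1)^2` box.
#'
#' @param radius neighborhood radius in pixels, >= 1.
#' @param shape one of `"rank"`, `"disk"`, `"square"`.
#' @return Data frame of integer offsets `dy`, `dx`.
#' @export
neighborhood_offsets <- function(radius, shape = c("rank", "disk", "square")) {
  shape <- match.arg(shape)
  stopifnot(radius >= 1)
  r <- floor(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  keep <- switch(shape,
    rank   = g$dy^2 + g$dx^2 <= radius^2 + 1,
    disk   = g$dy^2 + g$dx^2 <= radius^2,
    square = rep(TRUE, nrow(g))
  )
  g[keep, , drop = FALSE]
}

#' Minimum (erosion) filter
#'
#' Replaces each pixel with the smallest value in its neighborhood
#' (3x3 square at radius 1, disk-approximating kernel at larger radii).
#' Borders are handled by edge replication.
#'
#' @param img an [image_grid()] or matrix.
#' @param radius neighborhood radius in pixels, >= 1.
#' @return An `image_grid` with the same bit depth.
#' @export
minimum_filter <- function(img, radius = 1) {
  img <- as_image_grid(img)
  check_min_shape(img)
  off <- neighborhood_offsets(radius, "rank")
  out <- cpp_min_filter(img$pixels, as.integer(off$dy), as.integer(off$dx))
  image_grid(out, img$bit_depth)
}

#' Mean filter
#'
#' Replaces each pixel with the arithmetic mean of its circular
#' neighborhood (pixel centers within `radius`); edge replication at
#' borders. A square kernel is available via `shape`.
#'
#' @inheritParams minimum_filter
#' @param shape `"disk"` (default) or `"square"`.
#' @return An `image_grid` (float).
#' @export
mean_filter <- function(img, radius = 2, shape = c("disk", "square")) {
  shape <- match.arg(shape)
  img <- as_image_grid(img)
  check_min_shape(img)
  off <- neighborhood_offsets(radius, shape)
  out <- cpp_mean_filter(img$pixels, as.integer(off$dy), as.integer(off$dx))
  image_grid(out, "float")
}

ball_element <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g <- g[g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
  g$h <- sqrt(radius^2 - g$dy^2 - g$dx^2)
  g
}

#' Rolling-ball background estimation and subtraction
#'
#' Estimates the smooth background as the grayscale opening of the image
#' by a ball (spherical cap) structuring element of the given radius —
#' erosion followed by dilation with the ball's height profile — then
#' subtracts it, clipping at zero. The background never exceeds the image.
#'
#' @param img an [image_grid()] or matrix.
#' @param radius ball radius in pixels (default 15, the mitochondrial
#'   workflow's setting).
#' @return List with `background` and `subtracted`, both `image_grid`s.
#' @export
rolling_ball_background <- function(img, radius = 15) {
  img <- as_image_grid(img)
  check_min_shape(img)
  stopifnot(radius >= 1)
  if (radius > min(dim(img$pixels)) / 2) {
    warning("ball radius exceeds half the image extent; background may be trivial")
  }
  el <- ball_element(radius)
  er <- cpp_erode_nonflat(img$pixels, as.integer(el$dy), as.integer(el$dx),
                          el$h)
  bg <- cpp_dilate_nonflat(er, as.integer(el$dy), as.integer(el$dx), el$h)
  bg <- pmin(bg, img$pixels)  # opening is anti-extensive; guard rounding
  sub <- pmax(img$pixels - bg, 0)
  list(background = image_grid(bg, "float"),
       subtracted = image_grid(sub, "float"))
}

gaussian_kernels <- function(sigma) {
  r <- max(2L, as.integer(ceiling(4 * sigma)))
  x <- -r:r
  g0 <- exp(-x^2 / (2 * sigma^2))
  z <- sum(g0)
  g2 <- ((x^2 - sigma^2) / sigma^4) * g0 / z
  list(
    g  = g0 / z,
    g1 = (-x / sigma^2) * g0 / z,
    g2 = g2 - mean(g2)  # exact zero sum: constants produce zero response
  )
}

#' Tubeness: Hessian-eigenvalue ridge enhancement
#'
#' Smooths the image with Gaussian-derivative kernels at scale `sigma`,
#' forms the per-pixel 2x2 Hessian, and scores each pixel with
#' `sigma^2 * |lambda2|` where `lambda2` is the larger-magnitude
#' eigenvalue, kept only where negative (bright line on dark background);
#' elsewhere the response is zero.
#'
#' @param img an [image_grid()] or matrix.
#' @param sigma Gaussian scale in pixels (default 1.0).
#' @return Non-negative float matrix of tubeness scores.
#' @export
tubeness <- function(img, sigma = 1.0) {
  img <- as_image_grid(img)
  check_min_shape(img)
  stopifnot(sigma > 0)
  k <- gaussian_kernels(sigma)
  # the Hessian is offset-invariant; centering makes that exact in
  # floating point (a constant image yields an exactly zero response)
  px <- img$pixels - mean(img$pixels)
  lxx <- cpp_sep_conv(px, k$g2, k$g)
  lyy <- cpp_sep_conv(px, k$g, k$g2)
  lxy <- cpp_sep_conv(px, k$g1, k$g1)
  half_tr <- (lxx + lyy) / 2
  s <- sqrt(((lxx - lyy) / 2)^2 + lxy^2)
  la <- half_tr + s
  lb <- half_tr - s
  l2 <- ifelse(abs(la) >= abs(lb), la, lb)
  out <- ifelse(l2 < 0, sigma^2 * (-l2), 0)
  out
}
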
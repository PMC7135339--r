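# Brute-force reference implementations, independent of the package's
# compiled paths: shift-and-reduce over explicit offsets on a
# replicate-padded matrix, naive per-bin geometry for the thresholds,
# and an R flood fill for labeling.

pad_replicate <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c(rep(1, r), seq_len(nr), rep(nr, r))
  ci <- c(rep(1, r), seq_len(nc), rep(nc, r))
  m[ri, ci, drop = FALSE]
}

# reduce over offsets: fun is pmin / pmax / `+`
oracle_shift_reduce <- function(img, off, fun, init, heights = NULL) {
  r <- max(abs(off$dy), abs(off$dx))
  p <- pad_replicate(img, r)
  nr <- nrow(img); nc <- ncol(img)
  acc <- matrix(init, nr, nc)
  for (k in seq_len(nrow(off))) {
    s <- p[r + off$dy[k] + seq_len(nr), r + off$dx[k] + seq_len(nc),
           drop = FALSE]
    if (!is.null(heights)) s <- s + heights[k]
    acc <- fun(acc, s)
  }
  acc
}

oracle_min_filter <- function(img, off) {
  oracle_shift_reduce(img, off, pmin, Inf)
}

oracle_mean_filter <- function(img, off) {
  oracle_shift_reduce(img, off, `+`, 0) / nrow(off)
}

oracle_opening <- function(img, radius) {
  r <- floor(radius)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dy^2 + off$dx^2 <= radius^2, , drop = FALSE]
  h <- sqrt(radius^2 - off$dy^2 - off$dx^2)
  er <- oracle_shift_reduce(img, off, pmin, Inf, heights = -h)
  # dilation mirrors the offsets; the ball is symmetric
  oracle_shift_reduce(er, off, pmax, -Inf, heights = h)
}

oracle_masked_stats <- function(img, mask) {
  s_in <- 0; n_in <- 0; s_out <- 0; n_out <- 0
  for (i in seq_len(nrow(img))) {
    for (j in seq_len(ncol(img))) {
      if (mask[i, j]) { s_in <- s_in + img[i, j]; n_in <- n_in + 1 }
      else { s_out <- s_out + img[i, j]; n_out <- n_out + 1 }
    }
  }
  list(mean_inside = s_in / n_in, mean_outside = s_out / n_out)
}

oracle_label_count <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  nb <- if (connectivity == 8) {
    cbind(dy = c(-1, -1, -1, 0, 0, 1, 1, 1),
          dx = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dy = c(-1, 0, 0, 1), dx = c(0, -1, 1, 0))
  }
  count <- 0
  for (i0 in seq_len(nr)) for (j0 in seq_len(nc)) {
    if (!mask[i0, j0] || seen[i0, j0]) next
    count <- count + 1
    stack <- list(c(i0, j0)); seen[i0, j0] <- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(nb))) {
        ii <- p[1] + nb[k, 1]; jj <- p[2] + nb[k, 2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc &&
              mask[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          stack[[length(stack) + 1]] <- c(ii, jj)
        }
      }
    }
  }
  count
}

oracle_triangle <- function(counts) {
  occ <- which(counts > 0) - 1
  lo <- min(occ); hi <- max(occ); peak <- which.max(counts) - 1
  n <- length(counts)
  mirrored <- (peak - lo) > (hi - peak)
  if (mirrored) {
    counts <- rev(counts); peak <- which.max(counts) - 1
    tmp <- (n - 1) - hi; hi <- (n - 1) - lo; lo <- tmp
  }
  hp <- counts[peak + 1]; hq <- counts[hi + 1]
  d <- vapply(peak:hi, function(b) {
    abs((hi - peak) * (hp - counts[b + 1]) - (peak - b) * (hq - hp)) /
      sqrt((hi - peak)^2 + (hq - hp)^2)
  }, 1.0)
  t <- (peak:hi)[which.max(d)]
  if (mirrored) t <- (n - 1) - t
  t
}

oracle_isodata <- function(counts) {
  lev <- seq_along(counts) - 1
  occ <- lev[counts > 0]
  t <- floor(sum(lev * counts) / sum(counts) + 0.5)
  t <- min(max(t, min(occ)), max(occ) - 1)
  for (it in 1:1000) {
    below <- lev <= t & counts > 0
    above <- lev > t & counts > 0
    if (!any(above)) { t <- max(occ) - 1; break }
    if (!any(below)) { t <- min(occ); next }
    m0 <- sum(lev[below] * counts[below]) / sum(counts[below])
    m1 <- sum(lev[above] * counts[above]) / sum(counts[above])
    tn <- floor((m0 + m1) / 2 + 0.5)
    tn <- min(max(tn, min(occ)), max(occ) - 1)
    if (tn == t) break
    t <- tn
  }
  t
}

random_histogram <- function() {
  h <- rpois(256, rgamma(256, 0.5, 0.01))
  while (sum(h > 0) < 2) h <- rpois(256, rgamma(256, 0.5, 0.01))
  h
}

mask_iou <- function(a, b) sum(a & b) / sum(a | b)

random_test_image <- function(nr = 32, nc = 32, top = 1000) {
  matrix(runif(nr * nc, 0, top), nr, nc)
}
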
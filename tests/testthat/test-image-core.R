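test_that("8-bit conversion is a rounded linear min-max map", {
  # mid-gray of a full-range 16-bit image
  img <- image_grid(matrix(c(0, 32768, 65535, 100), 2, 2), 16)
  out <- convert_to_8bit(img)
  expect_equal(out$pixels[2, 1], floor(255 * 32768 / 65535 + 0.5))
  expect_equal(out$pixels[1, 1], 0)
  expect_equal(out$pixels[1, 2], 255)
  # constant image maps to zero
  expect_true(all(convert_to_8bit(matrix(500, 4, 4))$pixels == 0))
  # two-valued image maps to the endpoints
  two <- convert_to_8bit(matrix(c(100, 300), 2, 2))
  expect_setequal(unique(as.vector(two$pixels)), c(0, 255))
  # explicit display range clips
  clip <- convert_to_8bit(matrix(c(0, 50, 100, 200), 2, 2),
                          lo = 50, hi = 100)
  expect_equal(as.vector(clip$pixels), c(0, 0, 255, 255))
})

test_that("rolling-ball background is the grayscale opening by a ball", {
  # a constant image is its own background
  rb <- rolling_ball_background(matrix(7, 16, 16), 5)
  expect_equal(rb$background$pixels, matrix(7, 16, 16))
  expect_true(all(rb$subtracted$pixels == 0))
  # an isolated spike is recovered by the subtraction (the discrete ball
  # sags by the sampled cap height at the nearest offset, < 0.2%)
  img <- matrix(10, 31, 31); img[16, 16] <- 110
  rb <- rolling_ball_background(img, 5)
  expect_equal(rb$subtracted$pixels[16, 16], 100, tolerance = 0.002)
  expect_equal(sum(rb$subtracted$pixels > 0.5), 1)
  expect_equal(rb$subtracted$pixels, pmax(img - oracle_opening(img, 5), 0),
               tolerance = 1e-12)
  # a linear ramp is invariant under opening away from the replicated
  # borders, and deviates by well under 10% of range overall
  ramp <- matrix(rep(seq(0, 50, length.out = 64), each = 64), 64, 64)
  rb <- rolling_ball_background(ramp, 15)
  expect_lt(max(abs(rb$subtracted$pixels[, 16:49])), 0.05 * 50)
  expect_lt(max(abs(rb$subtracted$pixels)), 0.10 * 50)
  # exhaustive oracle agreement + anti-extensivity on random images
  set.seed(101)
  for (i in 1:8) {
    img <- random_test_image(24, 24)
    radius <- sample(2:6, 1)
    rb <- rolling_ball_background(img, radius)
    expect_equal(rb$background$pixels, oracle_opening(img, radius),
                 tolerance = 1e-12)
    expect_true(all(rb$background$pixels <= img + 1e-9))
    expect_true(all(rb$subtracted$pixels >= 0))
  }
})

test_that("opening is idempotent: re-opening the background changes nothing", {
  set.seed(202)
  for (i in 1:5) {
    img <- random_test_image(24, 24)
    bg <- rolling_ball_background(img, 4)$background
    bg2 <- rolling_ball_background(bg, 4)$background
    expect_equal(bg2$pixels, bg$pixels, tolerance = 1e-9)
  }
})

test_that("minimum filter takes the neighborhood minimum with edge replication", {
  expect_equal(minimum_filter(matrix(3, 5, 5), 1)$pixels, matrix(3, 5, 5))
  # an isolated bright pixel is erased
  img <- matrix(0, 7, 7); img[4, 4] <- 9
  expect_true(all(minimum_filter(img, 1)$pixels == 0))
  # explicit 5x5 grid against the exhaustive oracle (radius 1 = 3x3)
  set.seed(7)
  g <- matrix(sample(0:20, 25, replace = TRUE), 5, 5)
  off <- expand.grid(dy = -1:1, dx = -1:1)
  expect_equal(minimum_filter(g, 1)$pixels, oracle_min_filter(g, off))
  # larger radii against the same kernel definition
  for (r in 2:3) {
    img <- random_test_image(16, 16)
    off <- neighborhood_offsets(r, "rank")
    expect_equal(minimum_filter(img, r)$pixels, oracle_min_filter(img, off))
  }
})

test_that("mean filter averages the disk neighborhood and conserves interior mass", {
  expect_equal(mean_filter(matrix(3, 9, 9), 2)$pixels, matrix(3, 9, 9))
  set.seed(8)
  g <- matrix(sample(0:20, 25, replace = TRUE), 5, 5)
  off <- neighborhood_offsets(1, "disk")
  expect_equal(mean_filter(g, 1)$pixels, oracle_mean_filter(g, off))
  img <- random_test_image(40, 40)
  out <- mean_filter(img, 2)$pixels
  interior <- 5:36
  expect_equal(mean(out[interior, interior]), mean(img[interior, interior]),
               tolerance = 0.01)
  off2 <- neighborhood_offsets(2, "disk")
  expect_equal(mean_filter(img, 2)$pixels, oracle_mean_filter(img, off2))
})

test_that("tubeness responds to ridges, is non-negative and rotation-equivariant", {
  expect_true(all(tubeness(matrix(5, 16, 16)) == 0))
  # a 1-px line out-scores an equal-amplitude disk at its center
  line <- matrix(0, 21, 21); line[11, ] <- 100
  disk <- matrix(0, 21, 21)
  for (i in 1:21) for (j in 1:21) {
    if ((i - 11)^2 + (j - 11)^2 <= 25) disk[i, j] <- 100
  }
  expect_gt(tubeness(line, 1)[11, 11], tubeness(disk, 1)[11, 11])
  # 90-degree rotation equivariance
  set.seed(33)
  img <- random_test_image(20, 20)
  rot <- t(img)[, rev(seq_len(20))]  # counter-clockwise is fine too
  t1 <- tubeness(img, 1)
  t2 <- tubeness(rot, 1)
  expect_equal(t2, t(t1)[, rev(seq_len(20))], tolerance = 1e-12)
  expect_true(all(t1 >= 0))
})

test_that("planted filaments out-score equal-amplitude blobs at sigma 1", {
  set.seed(44)
  wins <- 0
  for (rep in 1:100) {
    fil <- matrix(0, 40, 40)
    r0 <- sample(10:30, 1)
    fil[r0, 5:35] <- 100
    blob <- matrix(0, 40, 40)
    c0 <- sample(15:25, 2)
    for (i in 1:40) for (j in 1:40) {
      if ((i - c0[1])^2 + (j - c0[2])^2 <= 25) blob[i, j] <- 100
    }
    if (max(tubeness(fil, 1)) > max(tubeness(blob, 1))) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("triangle threshold maximizes peak-to-tail distance and handles mirroring", {
  expect_error(triangle_threshold(c(0, 0, 5, 0)),
               class = "wormupr_degenerate_histogram")
  # toy 8-bin histogram vs exhaustive geometric oracle
  h8 <- c(1, 20, 8, 4, 2, 1, 1, 3)
  expect_equal(triangle_threshold(h8), oracle_triangle(h8))
  # two well-separated modes: threshold strictly between them
  set.seed(55)
  x <- round(c(rnorm(4000, 60, 8), rnorm(2000, 180, 8)))
  h <- tabulate(pmin(pmax(x, 0), 255) + 1, 256)
  thr <- triangle_threshold(h)
  expect_gt(thr, 60); expect_lt(thr, 180)
  # brute-force agreement and count-scale invariance on random histograms
  for (i in 1:200) {
    h <- random_histogram()
    t0 <- triangle_threshold(h)
    expect_identical(t0, as.integer(oracle_triangle(h)))
    expect_identical(triangle_threshold(h * 7L), t0)
    occ <- which(h > 0) - 1
    expect_gte(t0, min(occ)); expect_lte(t0, max(occ))
  }
})

test_that("isodata threshold is the intermeans fixed point", {
  h <- integer(256); h[10 + 1] <- 50; h[20 + 1] <- 50
  expect_equal(isodata_threshold(h), 15L)
  # translation equivariance
  h2 <- integer(256); h2[60 + 1] <- 50; h2[70 + 1] <- 50
  expect_equal(isodata_threshold(h2), 65L)
  expect_error(isodata_threshold(c(9, 0, 0)),
               class = "wormupr_degenerate_histogram")
  set.seed(66)
  for (i in 1:200) {
    h <- random_histogram()
    t0 <- isodata_threshold(h)
    expect_identical(t0, as.integer(oracle_isodata(h)))
    occ <- which(h > 0) - 1
    expect_gte(t0, min(occ)); expect_lte(t0, max(occ))
  }
})

test_that("component labeling respects connectivity and matches flood fill", {
  empty <- label_components(matrix(FALSE, 5, 5))
  expect_length(empty$areas, 0)
  # two diagonally touching pixels
  diag2 <- matrix(FALSE, 4, 4); diag2[2, 2] <- TRUE; diag2[3, 3] <- TRUE
  expect_length(label_components(diag2, 8)$areas, 1)
  expect_length(label_components(diag2, 4)$areas, 2)
  set.seed(77)
  for (i in 1:10) {
    m <- matrix(runif(400) < 0.35, 20, 20)
    for (conn in c(4, 8)) {
      lab <- label_components(m, conn)
      expect_equal(length(lab$areas), oracle_label_count(m, conn))
      expect_equal(sum(lab$areas), sum(m))
      expect_identical(lab$labels > 0L, m)
    }
  }
})

test_that("particle filtering keeps areas >= min_px and conserves area", {
  m <- matrix(FALSE, 20, 20)
  m[1:2, 1:5] <- TRUE          # area 10
  m[10, 1:3] <- TRUE           # area 3
  m[15:19, 10:17] <- TRUE      # area 40
  lab <- label_components(m, 8)
  filt <- filter_small_particles(lab, 10)
  expect_length(filt$areas, 2)
  expect_setequal(filt$areas, c(10L, 40L))  # exactly-10 survives
  expect_equal(sum(filt$areas) + 3L, sum(lab$areas))
  # everything below the cutoff yields an empty mask
  all_small <- filter_small_particles(lab, 100)
  expect_length(all_small$areas, 0)
  expect_false(any(all_small$values))
})

test_that("masked statistics equal the exhaustive pixel loop", {
  # uniform image: inside and outside agree
  m <- matrix(FALSE, 4, 4); m[2, 2] <- TRUE
  st <- masked_stats(matrix(5, 4, 4), m)
  expect_equal(st$mean_inside, 5); expect_equal(st$mean_outside, 5)
  expect_equal(st$foreground_area, 1)
  # 3x3 grid with a bright center
  g <- matrix(0, 3, 3); g[2, 2] <- 9
  cm <- matrix(FALSE, 3, 3); cm[2, 2] <- TRUE
  st <- masked_stats(g, cm)
  expect_equal(st$mean_inside, 9); expect_equal(st$mean_outside, 0)
  # random image + mask vs loop oracle
  set.seed(88)
  for (i in 1:10) {
    img <- random_test_image(12, 12)
    mk <- matrix(runif(144) < 0.4, 12, 12)
    if (!any(mk) || all(mk)) next
    st <- masked_stats(img, mk)
    or <- oracle_masked_stats(img, mk)
    expect_equal(st$mean_inside, or$mean_inside)
    expect_equal(st$mean_outside, or$mean_outside)
  }
  expect_error(masked_stats(g, matrix(FALSE, 3, 3)),
               class = "wormupr_empty_mask")
  full <- masked_stats(g, matrix(TRUE, 3, 3))
  expect_true(full$full_mask); expect_true(is.na(full$mean_outside))
})
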
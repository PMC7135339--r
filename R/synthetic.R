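# Seeded generators emulating the study's inputs: whole-animal reporter
# micrographs, mitochondrial TMRE fields, LC-MS lipid feature tables and
# single-worm Ct tables — each with exact ground truth.

# Poisson shot noise (counts = gain * signal) plus Gaussian read noise,
# the simplest model reproducing fluorescence-microscopy variance scaling.
apply_camera_noise <- function(px, poisson_gain = NULL, read_sd = 0,
                               bit_depth = 16) {
  if (!is.null(poisson_gain) && poisson_gain > 0) {
    px[] <- rpois(length(px), poisson_gain * px) / poisson_gain
  }
  if (read_sd > 0) px <- px + rnorm(length(px), 0, read_sd)
  top <- if (identical(as.character(bit_depth), "8")) 255 else 65535
  px <- pmin(pmax(round(px), 0), top)
  px
}

smooth_background_field <- function(nr, nc, level, texture = 0.05) {
  if (texture <= 0) return(matrix(level, nr, nc))
  rows <- matrix(seq_len(nr) / nr, nr, nc)
  cols <- matrix(rep(seq_len(nc) / nc, each = nr), nr, nc)
  f <- matrix(0, nr, nc)
  for (i in 1:3) {
    f <- f + cos(2 * pi * (runif(1, 0.5, 2) * rows +
                             runif(1, 0.5, 2) * cols + runif(1)))
  }
  level * (1 + texture * f / 3)
}

stamp_disks <- function(mask, pts_r, pts_c, radius) {
  nr <- nrow(mask); nc <- ncol(mask)
  r <- ceiling(radius)
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dy^2 + off$dx^2 <= radius^2, , drop = FALSE]
  for (k in seq_along(pts_r)) {
    ii <- pmin(pmax(round(pts_r[k]) + off$dy, 1), nr)
    jj <- pmin(pmax(round(pts_c[k]) + off$dx, 1), nc)
    mask[cbind(ii, jj)] <- TRUE
  }
  mask
}

bezier_points <- function(p0, p1, p2, n = 200) {
  t <- seq(0, 1, length.out = n)
  list(r = (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1],
       c = (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2])
}

#' Generate a synthetic whole-animal reporter image
#'
#' Elongated worm-shaped objects (Bezier tubes) on a gently textured
#' autofluorescent background, with optional Poisson + Gaussian camera
#' noise applied last. The ground-truth mask and the exact per-object
#' mean intensities of the noise-free image are returned.
#'
#' @param seed integer RNG seed.
#' @param n_worms number of animals (default 5).
#' @param size image side in pixels (default 512).
#' @param background mean background level (arbitrary units).
#' @param amplitudes in-worm intensity per animal (recycled); must exceed
#'   the background or the spec is rejected as infeasible.
#' @param worm_width tube width in pixels.
#' @param texture relative amplitude of the background texture.
#' @param poisson_gain Poisson gain (counts per intensity unit); `NULL`
#'   disables shot noise.
#' @param read_sd Gaussian read-noise SD; 0 disables.
#' @param max_tries placement retries per worm before a packing error.
#' @return List with `image` (16-bit [image_grid()]), `truth` (a
#'   [seg_mask()] of the worms), `object_means` (exact noise-free
#'   per-object means) and `noise_free` (matrix).
#' @export
gen_worm_image <- function(seed, n_worms = 5, size = 512,
                           background = 300, amplitudes = 3000,
                           worm_width = 9, texture = 0.05,
                           poisson_gain = 0.2, read_sd = 20,
                           max_tries = 60) {
  set.seed(seed)
  if (any(amplitudes <= background)) {
    stop_wormupr("infeasible_spec",
                 "worm amplitude must exceed the background level")
  }
  amplitudes <- rep_len(amplitudes, n_worms)
  bg <- smooth_background_field(size, size, background, texture)
  noise_free <- bg
  labels <- matrix(0L, size, size)
  half_w <- worm_width / 2
  len <- size * 0.35
  for (w in seq_len(n_worms)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      p0 <- c(runif(1, half_w + 2, size - half_w - 2),
              runif(1, half_w + 2, size - half_w - 2))
      ang <- runif(1, 0, 2 * pi)
      p2 <- p0 + len * c(sin(ang), cos(ang))
      mid <- (p0 + p2) / 2 +
        runif(2, -0.15, 0.15) * len  # gentle body curvature
      if (any(p2 < half_w + 2) || any(p2 > size - half_w - 2)) next
      bz <- bezier_points(p0, mid, p2, n = ceiling(len * 2))
      cand <- stamp_disks(matrix(FALSE, size, size), bz$r, bz$c, half_w)
      if (any(labels[cand] != 0L)) next
      labels[cand] <- w
      noise_free[cand] <- amplitudes[w]
      placed <- TRUE
      break
    }
    if (!placed) {
      stop_wormupr("packing_error",
                   "could not place worm without overlap; reduce n_worms")
    }
  }
  truth <- seg_mask(labels)
  object_means <- vapply(seq_len(n_worms),
                         function(w) mean(noise_free[labels == w]), 1.0)
  px <- apply_camera_noise(noise_free, poisson_gain, read_sd, 16)
  list(image = image_grid(px, 16), truth = truth,
       object_means = object_means, noise_free = noise_free)
}

#' Generate a synthetic mitochondrial TMRE field
#'
#' `"tubular"` morphology draws long low-curvature filaments 2-4 px
#' wide; `"fragmented"` draws ellipses of 10-60 px area. In-structure
#' intensity is `potential_scale * amplitude` (the membrane-potential
#' proxy); the exact in-structure mean of the noise-free image is
#' returned with the ground-truth mask.
#'
#' @param seed integer RNG seed.
#' @param morphology `"tubular"` or `"fragmented"`.
#' @param size image side in pixels (default 512).
#' @param background mean background level.
#' @param amplitude full-potential in-structure intensity.
#' @param potential_scale membrane-potential scale factor (1 = control;
#'   the fusion-mutant condition plants 0.37).
#' @param n_structures filament / fragment count; defaults scale with
#'   morphology so total structure area is comparable.
#' @param poisson_gain,read_sd camera noise (as [gen_worm_image()]).
#' @return List with `image`, `truth`, `true_mean` (exact in-structure
#'   mean before noise) and `noise_free`.
#' @export
gen_mito_image <- function(seed, morphology = c("tubular", "fragmented"),
                           size = 512, background = 50, amplitude = 2000,
                           potential_scale = 1.0,
                           n_structures = NULL,
                           poisson_gain = 0.2, read_sd = 5) {
  morphology <- match.arg(morphology)
  set.seed(seed)
  inside <- potential_scale * amplitude
  if (inside <= background) {
    stop_wormupr("infeasible_spec",
                 "in-structure intensity must exceed the background")
  }
  scale_fac <- size / 256
  if (is.null(n_structures)) {
    n_structures <- if (morphology == "tubular") {
      max(4, round(6 * scale_fac))
    } else {
      max(20, round(45 * scale_fac^2))
    }
  }
  mask <- matrix(FALSE, size, size)
  if (morphology == "tubular") {
    for (s in seq_len(n_structures)) {
      r <- runif(1, 10, size - 10); c <- runif(1, 10, size - 10)
      theta <- runif(1, 0, 2 * pi)
      steps <- round(runif(1, 0.4, 0.8) * size)
      rr <- numeric(steps); cc <- numeric(steps)
      for (k in seq_len(steps)) {
        theta <- theta + rnorm(1, 0, 0.06)  # low curvature
        r <- min(max(r + sin(theta), 3), size - 2)
        c <- min(max(c + cos(theta), 3), size - 2)
        rr[k] <- r; cc[k] <- c
      }
      mask <- stamp_disks(mask, rr, cc, runif(1, 1.0, 1.9))
    }
  } else {
    for (s in seq_len(n_structures)) {
      area <- runif(1, 10, 60)
      ecc <- runif(1, 1, 2.5)
      b <- sqrt(area / (pi * ecc)); a <- ecc * b
      phi <- runif(1, 0, pi)
      cr <- runif(1, a + 2, size - a - 2)
      cc0 <- runif(1, a + 2, size - a - 2)
      r0 <- ceiling(a)
      g <- expand.grid(dy = -r0:r0, dx = -r0:r0)
      u <- g$dy * cos(phi) + g$dx * sin(phi)
      v <- -g$dy * sin(phi) + g$dx * cos(phi)
      g <- g[(u / a)^2 + (v / b)^2 <= 1, , drop = FALSE]
      ii <- pmin(pmax(round(cr) + g$dy, 1), size)
      jj <- pmin(pmax(round(cc0) + g$dx, 1), size)
      mask[cbind(ii, jj)] <- TRUE
    }
  }
  noise_free <- matrix(background, size, size)
  noise_free[mask] <- inside
  truth <- label_components(mask, 8)
  true_mean <- mean(noise_free[mask])
  px <- apply_camera_noise(noise_free, poisson_gain, read_sd, 16)
  list(image = image_grid(px, 16), truth = truth, true_mean = true_mean,
       noise_free = noise_free)
}

#' Generate a synthetic lipid feature table
#'
#' Lognormal baseline feature intensities with planted per-feature fold
#' changes between a reference and a mutant group, multiplicative drift
#' over injection order, and pooled QC samples injected every
#' `qc_every`-th biological sample (plus a leading QC). Optionally the
#' features are annotated as triacylglycerol sum compositions with a
#' planted landscape: short-chain species (carbons < 48) down 2-fold,
#' long unsaturated species (carbons >= 54 and double bonds >= 3) up
#' 2-fold.
#'
#' @param seed integer RNG seed.
#' @param n_features number of features (default 500).
#' @param groups group labels; the first is the reference.
#' @param n_per_group biological replicates per group (default 5).
#' @param cv within-group biological coefficient of variation.
#' @param qc_cv analytic CV of the pooled QC injections.
#' @param drift_fold multiplicative drift reached at the last injection
#'   (1 = no drift; 2 plants a linear 2x drift).
#' @param qc_every a pooled QC is injected before every block of this
#'   many samples (default 10).
#' @param fold_changes optional per-feature fold change (mutant over
#'   reference); overrides the landscape plant.
#' @param tg_landscape if `TRUE`, annotate features as TG sum
#'   compositions and plant the two-cluster landscape above.
#' @param missing_qc_frac fraction of features blanked in one QC (to
#'   exercise the presence rule).
#' @return List with `table` (a [lipid_table()]), `annotations` (or
#'   `NULL`) and `truth` (fold changes, drift curve, planted direction).
#' @export
gen_lipid_table <- function(seed, n_features = 500,
                            groups = c("wt", "fzo1"), n_per_group = 5,
                            cv = 0.1, qc_cv = 0.02, drift_fold = 1,
                            qc_every = 10, fold_changes = NULL,
                            tg_landscape = FALSE,
                            missing_qc_frac = 0) {
  set.seed(seed)
  n_groups <- length(groups)
  n_bio <- n_groups * n_per_group
  annotations <- NULL
  if (tg_landscape) {
    carbons <- sample(seq(40, 60, by = 2), n_features, replace = TRUE)
    dbs <- sample(0:8, n_features, replace = TRUE)
    name <- sprintf("TG %d:%d", carbons, dbs)
    annotations <- data.frame(
      feature_id = paste0("F", seq_len(n_features)),
      name = name,
      match_score_fwd = runif(n_features, 0.76, 1),
      match_score_rev = runif(n_features, 0.76, 1),
      stringsAsFactors = FALSE
    )
    if (is.null(fold_changes)) {
      fold_changes <- rep(1, n_features)
      fold_changes[carbons < 48] <- 0.5
      fold_changes[carbons >= 54 & dbs >= 3] <- 2
    }
  }
  if (is.null(fold_changes)) fold_changes <- rep(1, n_features)
  fold_changes <- rep_len(fold_changes, n_features)

  base <- rlnorm(n_features, meanlog = log(1e5), sdlog = 1)
  sdlog <- sqrt(log(1 + cv^2))
  group_mean <- outer(base, rep(1, n_groups))
  group_mean[, groups != groups[1]] <-
    group_mean[, groups != groups[1], drop = FALSE] * fold_changes

  # injection schedule: a QC leads every block of qc_every samples,
  # and one closes the run
  bio_order_groups <- sample(rep(groups, each = n_per_group))
  kind <- character(0)
  bio_left <- n_bio
  i <- 0
  while (bio_left > 0) {
    kind <- c(kind, "QC", rep("bio", min(qc_every, bio_left)))
    bio_left <- bio_left - qc_every
  }
  kind <- c(kind, "QC")
  n_qc <- sum(kind == "QC")
  n_total <- length(kind)
  sample_meta <- data.frame(
    sample = ifelse(kind == "QC",
                    paste0("QC", cumsum(kind == "QC")),
                    NA_character_),
    group = ifelse(kind == "QC", "QC", NA_character_),
    is_qc = kind == "QC",
    injection_order = seq_len(n_total),
    protein_ug = NA_real_,
    stringsAsFactors = FALSE
  )
  bio_idx <- which(!sample_meta$is_qc)
  sample_meta$group[bio_idx] <- bio_order_groups
  sample_meta$sample[bio_idx] <-
    paste0(bio_order_groups, "_",
           stats::ave(seq_along(bio_idx), bio_order_groups,
                      FUN = seq_along))
  sample_meta$protein_ug[bio_idx] <- runif(n_bio, 40, 60)

  drift <- 1 + (drift_fold - 1) *
    (sample_meta$injection_order - 1) / (n_total - 1)
  pooled <- rowMeans(group_mean)  # the pooled-aliquot QC composition
  x <- matrix(NA_real_, n_features, n_total)
  for (j in seq_len(n_total)) {
    if (sample_meta$is_qc[j]) {
      x[, j] <- pooled * exp(rnorm(n_features, 0, sqrt(log(1 + qc_cv^2)))) *
        drift[j]
    } else {
      g <- match(sample_meta$group[j], groups)
      x[, j] <- group_mean[, g] * exp(rnorm(n_features, -sdlog^2 / 2, sdlog)) *
        drift[j] * sample_meta$protein_ug[j] / 50
    }
  }
  rownames(x) <- paste0("F", seq_len(n_features))
  if (missing_qc_frac > 0) {
    hit <- sample(n_features, round(missing_qc_frac * n_features))
    x[hit, sample(which(sample_meta$is_qc), 1)] <- NA_real_
  }
  truth <- list(
    fold_changes = fold_changes,
    drift = drift,
    planted_direction = ifelse(fold_changes > 1, "up",
                               ifelse(fold_changes < 1, "down",
                                      "unchanged"))
  )
  list(table = lipid_table(x, sample_meta, annotations),
       annotations = annotations, truth = truth)
}

#' Generate a synthetic single-worm Ct table
#'
#' Per-gene lognormal expression with planted coefficients of variation;
#' Ct values are a gene-specific baseline minus log2 expression, and the
#' housekeeping genes are nearly invariant. Random well failures can be
#' planted via `fail_rate`.
#'
#' @param seed integer RNG seed.
#' @param planted_cv named numeric vector: target genes and their
#'   biological CVs.
#' @param n_worms individuals per genotype (default 36, the assay's
#'   chip capacity).
#' @param housekeeping names of the stable reference genes.
#' @param hk_cv residual CV of the housekeeping genes.
#' @param fail_rate per-well probability of a failed PCR.
#' @return List with `table` (a [ct_table()]) and `truth` (planted CVs).
#' @export
gen_ct_table <- function(seed,
                         planted_cv = c(`hsp-1` = 0.1, `ttr-45` = 0.4,
                                        `nlp-29` = 1.0),
                         n_worms = 36,
                         housekeeping = c("cdc-42", "ire-1", "pmp-3"),
                         hk_cv = 0.01, fail_rate = 0) {
  set.seed(seed)
  genes <- c(names(planted_cv), housekeeping)
  cvs <- c(planted_cv, rep(hk_cv, length(housekeeping)))
  baseline <- runif(length(genes), 18, 28)
  ct <- matrix(NA_real_, length(genes), n_worms,
               dimnames = list(genes, paste0("worm", seq_len(n_worms))))
  for (g in seq_along(genes)) {
    sdlog <- sqrt(log(1 + cvs[g]^2))
    expr <- rlnorm(n_worms, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    ct[g, ] <- baseline[g] - log2(expr)
  }
  flags <- matrix("pass", nrow(ct), ncol(ct), dimnames = dimnames(ct))
  if (fail_rate > 0) {
    bad <- runif(length(ct)) < fail_rate
    flags[bad] <- "failed_pcr"
  }
  list(table = ct_table(ct, housekeeping, flags),
       truth = list(planted_cv = planted_cv))
}
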
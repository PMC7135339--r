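# Pre-registered synthetic experiments mirroring the study's designs.
# Each runs a full pipeline on generated data and returns the quantities
# the analyses report; the drivers under analysis/, the test suite and
# the acceptance script all call these.

#' Reporter suppression recovery experiment
#'
#' Simulates three groups of whole-animal reporter images — wild type on
#' control RNAi, stressed mutant on control RNAi, and a treated mutant
#' whose in-worm intensity is planted at `1 - suppression/100` of the
#' mutant-control span — then runs segmentation, quantification and
#' group normalization, and reports the recovered percent suppression.
#'
#' @param seed integer RNG seed.
#' @param n_per_group images per group (default 20, one image standing
#'   for one 15-20 animal quantification).
#' @param size image side in pixels.
#' @param suppression planted suppression in percent (default 40).
#' @param n_worms animals per image.
#' @return List with `recovered_pct`, `planted_pct` and the measurement
#'   table.
#' @export
reporter_suppression_experiment <- function(seed, n_per_group = 20,
                                            size = 192, suppression = 40,
                                            n_worms = 4) {
  amp_wt <- 1200; amp_mut <- 3000
  amp_treat <- amp_wt + (1 - suppression / 100) * (amp_mut - amp_wt)
  amps <- c(wt_control = amp_wt, mutant_control = amp_mut,
            treatment = amp_treat)
  rows <- list()
  for (g in seq_along(amps)) {
    for (i in seq_len(n_per_group)) {
      w <- gen_worm_image(seed = seed + 7919L * g + i, n_worms = n_worms,
                          size = size, amplitudes = amps[[g]],
                          worm_width = 7)
      m <- segment_animals(w$image)
      rows[[length(rows) + 1L]] <-
        quantify_reporter(w$image, m,
                          image_id = sprintf("%s_%02d", names(amps)[g], i),
                          group = names(amps)[g])
    }
  }
  meas <- do.call(rbind, rows)
  meas <- normalize_groups(meas, "wt_control", "mutant_control")
  rec <- percent_suppression(meas$normalized[meas$group == "treatment"])
  list(recovered_pct = rec, planted_pct = suppression,
       measurements = meas)
}

#' TMRE membrane-potential ratio recovery experiment
#'
#' Simulates a tubular control group at full membrane potential and a
#' fragmented mutant group whose in-structure intensity is scaled by
#' `potential_scale` (0.37 mirrors the reduced potential of the fusion
#' mutant), runs the tubeness segmentation workflow on every image and
#' reports the ratio of group mean intensity-per-area.
#'
#' @param seed integer RNG seed.
#' @param n_per_group images per group (default 12).
#' @param size image side in pixels.
#' @param potential_scale planted mutant/control intensity ratio.
#' @return List with `recovered_ratio`, `planted_ratio` and the
#'   measurement table.
#' @export
tmre_ratio_experiment <- function(seed, n_per_group = 12, size = 256,
                                  potential_scale = 0.37) {
  rows <- list()
  for (i in seq_len(n_per_group)) {
    ctl <- gen_mito_image(seed = seed + i, size = size,
                          morphology = "tubular", potential_scale = 1.0)
    mut <- gen_mito_image(seed = seed + 5000L + i, size = size,
                          morphology = "fragmented",
                          potential_scale = potential_scale)
    for (g in list(list(d = ctl, lab = "control"),
                   list(d = mut, lab = "mutant"))) {
      mk <- segment_mitochondria(g$d$image)
      rows[[length(rows) + 1L]] <-
        tmre_intensity(g$d$image, mk,
                       image_id = sprintf("%s_%02d", g$lab, i),
                       group = g$lab)
    }
  }
  meas <- do.call(rbind, rows)
  ratio <- mean(meas$intensity_per_area[meas$group == "mutant"]) /
    mean(meas$intensity_per_area[meas$group == "control"])
  list(recovered_ratio = ratio, planted_ratio = potential_scale,
       measurements = meas)
}

#' Family-wise error calibration of the gated many-group procedure
#'
#' All-null Gaussian design: `n_groups` groups of `n` observations from
#' the same normal distribution, run through
#' [compare_many_to_control()]; the family-wise error is the fraction of
#' simulations with any many-to-one p-value below `alpha`.
#'
#' @param seed integer RNG seed.
#' @param n_sims number of simulated datasets (default 2000).
#' @param n_groups,n design (default 5 groups of 15).
#' @param alpha nominal level.
#' @return List with `fwer`, `n_sims` and the branch frequencies.
#' @export
fwer_calibration <- function(seed, n_sims = 2000, n_groups = 5, n = 15,
                             alpha = 0.05) {
  set.seed(seed)
  labs <- c("control", paste0("g", seq_len(n_groups - 1)))
  hits <- logical(n_sims)
  branch <- character(n_sims)
  for (s in seq_len(n_sims)) {
    gr <- stats::setNames(lapply(seq_len(n_groups), function(i) rnorm(n)),
                          labs)
    res <- compare_many_to_control(gr, "control", alpha = alpha)
    hits[s] <- any(res$decisions$p_value < alpha)
    branch[s] <- res$test_name
  }
  list(fwer = mean(hits), n_sims = n_sims,
       branch_freq = table(branch) / n_sims)
}

#' Lipidomics landscape recovery experiment
#'
#' Generates a feature table with the planted two-cluster
#' triacylglycerol landscape (short-chain species down 2-fold, long
#' unsaturated species up 2-fold), runs QC filtering, protein
#' normalization, per-feature Welch tests and the sum-composition
#' landscape, and scores cell-call accuracy against the plant.
#'
#' @param seed integer RNG seed.
#' @param n_features features (default 500).
#' @param n_per_group biological replicates (default 5).
#' @param cv within-group CV (default 0.1).
#' @return List with `cell_accuracy`, the classified landscape, the
#'   differential results and the generated data.
#' @export
lipid_landscape_experiment <- function(seed, n_features = 500,
                                       n_per_group = 5, cv = 0.1) {
  gen <- gen_lipid_table(seed, n_features = n_features,
                         groups = c("wt", "fzo1"),
                         n_per_group = n_per_group, cv = cv,
                         tg_landscape = TRUE)
  tab <- qc_presence_rsd_filter(gen$table, rsd_max = 30)
  tab <- protein_normalize(tab)
  res <- welch_differential(tab, "fzo1", "wt")
  land <- classify_landscape_cells(tg_landscape(res, gen$annotations))
  planted_call <- ifelse(land$carbons < 48, "down",
                         ifelse(land$carbons >= 54 & land$double_bonds >= 3,
                                "up", "unchanged"))
  list(cell_accuracy = mean(land$call == planted_call),
       landscape = land, results = res, generated = gen)
}

#' QC drift-correction experiment
#'
#' Plants a linear 2x intensity drift across a long injection sequence
#' and reports per-feature QC RSD before and after the drift
#' normalization.
#'
#' @param seed integer RNG seed.
#' @param n_features features (default 200).
#' @param n_per_group biological replicates per group across 2 groups
#'   (default 20, giving the run a 5-QC anchor sequence).
#' @param drift_fold drift reached at the end of the run (default 2).
#' @return List with `rsd_pre`, `rsd_post` (per-feature vectors) and
#'   their medians.
#' @export
lipid_drift_experiment <- function(seed, n_features = 200,
                                   n_per_group = 20, drift_fold = 2) {
  gen <- gen_lipid_table(seed, n_features = n_features,
                         groups = c("wt", "fzo1"),
                         n_per_group = n_per_group,
                         drift_fold = drift_fold)
  qc_rsd <- function(tab) {
    qc <- tab$intensities[, tab$sample_meta$is_qc, drop = FALSE]
    100 * apply(qc, 1, sd) / rowMeans(qc)
  }
  pre <- qc_rsd(gen$table)
  post <- qc_rsd(qc_drift_normalize(gen$table))
  list(rsd_pre = pre, rsd_post = post,
       median_pre = median(pre), median_post = median(post))
}

#' Single-worm variability ladder recovery experiment
#'
#' Repeatedly generates 36-worm Ct tables with the planted CV ladder
#' (0.1 / 0.4 / 1.0), recovers per-gene expression CVs through the
#' delta-Ct pipeline, and reports the mean recovered CVs and the
#' fraction of runs ranking the ladder correctly.
#'
#' @param seed integer RNG seed.
#' @param n_runs number of generated tables (default 200).
#' @param planted_cv named CV ladder.
#' @return List with `mean_recovered`, `planted`, `order_correct_frac`.
#' @export
qpcr_ladder_experiment <- function(seed, n_runs = 200,
                                   planted_cv = c(`hsp-1` = 0.1,
                                                  `ttr-45` = 0.4,
                                                  `nlp-29` = 1.0)) {
  genes <- names(planted_cv)
  rec <- matrix(NA_real_, length(genes), n_runs,
                dimnames = list(genes, NULL))
  for (r in seq_len(n_runs)) {
    g <- gen_ct_table(seed = seed + r, planted_cv = planted_cv)
    ex <- relative_expression(clean_ct(g$table))
    for (gene in genes) {
      rec[gene, r] <- expression_cv(ex[gene, ], gene, "wt")$cv
    }
  }
  ord <- order(planted_cv)
  correct <- mean(apply(rec, 2, function(x) !is.unsorted(x[ord])))
  list(mean_recovered = rowMeans(rec), planted = planted_cv,
       order_correct_frac = correct, recovered = rec)
}
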
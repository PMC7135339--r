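make_toy_table <- function(x, groups, is_qc, protein = NULL,
                           feature_meta = NULL) {
  n <- length(groups)
  if (is.null(protein)) protein <- ifelse(is_qc, NA_real_, 50)
  lipid_table(x, data.frame(
    sample = paste0("s", seq_len(n)), group = groups, is_qc = is_qc,
    injection_order = seq_len(n), protein_ug = protein
  ), feature_meta)
}

test_that("QC presence and RSD filtering follows the strict 30% rule", {
  x <- rbind(
    good    = c(8, 10, 12, 5, 6),     # QC RSD 20%
    absent  = c(8, NA, 12, 5, 6),     # missing in one QC
    flat    = c(10, 10, 10, 5, 6),    # RSD 0
    noisy   = c(2, 10, 18, 5, 6)      # RSD 80%
  )
  tab <- make_toy_table(x, groups = c("QC", "QC", "QC", "wt", "wt"),
                        is_qc = c(TRUE, TRUE, TRUE, FALSE, FALSE))
  out <- qc_presence_rsd_filter(tab, 30)
  expect_setequal(rownames(out$intensities), c("good", "flat"))
  expect_equal(unname(attr(out, "qc_rsd")["good"]), 20)
  # fewer than two QCs is not a usable QC design
  tab1 <- make_toy_table(x[, c(1, 4, 5)], groups = c("QC", "wt", "wt"),
                         is_qc = c(TRUE, FALSE, FALSE))
  expect_error(qc_presence_rsd_filter(tab1), class = "wormupr_insufficient_qc")
})

test_that("protein normalization divides biological samples only", {
  x <- rbind(f1 = c(100, 10, 20), f2 = c(50, 8, 16))
  tab <- make_toy_table(x, groups = c("QC", "wt", "wt"),
                        is_qc = c(TRUE, FALSE, FALSE),
                        protein = c(NA, 2, 4))
  out <- protein_normalize(tab)
  expect_equal(unname(out$intensities["f1", ]), c(100, 5, 5))
  expect_equal(unname(out$intensities["f2", ]), c(50, 4, 4))
  # equal protein leaves between-sample ratios unchanged
  tab2 <- make_toy_table(x, groups = c("QC", "wt", "wt"),
                         is_qc = c(TRUE, FALSE, FALSE),
                         protein = c(NA, 5, 5))
  out2 <- protein_normalize(tab2)
  expect_equal(unname(out2$intensities["f1", 2] / out2$intensities["f1", 3]),
               unname(x["f1", 2] / x["f1", 3]))
})

test_that("drift normalization flattens a planted trend and spares flat runs", {
  # flat QCs: table unchanged within numerical noise
  gen <- gen_lipid_table(seed = 51, n_features = 40, n_per_group = 20,
                         drift_fold = 1, qc_cv = 0)
  out <- qc_drift_normalize(gen$table)
  expect_equal(out$intensities, gen$table$intensities, tolerance = 1e-6)
  # planted linear 2x drift: QC RSD drops from > 25% to < 5%
  exp <- lipid_drift_experiment(seed = 52, n_features = 50)
  expect_gt(exp$median_pre, 25)
  expect_lt(exp$median_post, 5)
  expect_true(all(exp$rsd_post <= exp$rsd_pre + 1e-9))
})

test_that("two-QC toy run falls back to the median-ratio correction", {
  x <- rbind(f1 = c(100, 110, 120, 200))
  tab <- make_toy_table(x, groups = c("QC", "wt", "wt", "QC"),
                        is_qc = c(TRUE, FALSE, FALSE, TRUE))
  expect_message(out <- qc_drift_normalize(tab), "fewer than 4 QC")
  # feature level is aligned to the grand QC median (150 here)
  expect_equal(median(out$intensities[1, c(1, 4)]), 150)
})

test_that("per-feature Welch testing calls planted fold changes", {
  # identical groups: unchanged with p = 1
  x <- rbind(f1 = c(5, 6, 7, 5, 6, 7))
  tab <- make_toy_table(x, groups = rep(c("wt", "mut"), each = 3),
                        is_qc = rep(FALSE, 6))
  res <- welch_differential(tab, "mut", "wt")
  expect_equal(res$p_value, 1)
  expect_equal(res$direction, "unchanged")
  # planted 2-fold features at CV 10%, n = 5: high power; nulls near alpha
  gen <- gen_lipid_table(seed = 53, n_features = 400, n_per_group = 5,
                         cv = 0.1,
                         fold_changes = rep(c(2, 1), each = 200))
  res <- welch_differential(protein_normalize(gen$table), "fzo1", "wt")
  power <- mean(res$direction[1:200] == "up")
  expect_gte(power, 0.9)
  fpr <- mean(res$direction[201:400] != "unchanged")
  expect_lt(fpr, 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
  # insufficient observations are flagged, not fatal
  x2 <- rbind(f1 = c(5, NA, NA, 7, 8, 9))
  tab2 <- make_toy_table(x2, groups = rep(c("wt", "mut"), each = 3),
                         is_qc = rep(FALSE, 6))
  expect_equal(welch_differential(tab2, "mut", "wt")$direction,
               "insufficient")
})

test_that("annotation score filter applies a strict > 0.75 cut", {
  ann <- data.frame(feature_id = c("a", "b", "c"),
                    match_score_fwd = c(0.8, 0.75, 0.9),
                    match_score_rev = c(0.9, 0.9, 0.74))
  out <- annotation_score_filter(ann)
  expect_equal(out$feature_id, "a")  # 0.75 exactly is dropped
})

test_that("sum-composition parsing extracts class, carbons and double bonds", {
  p <- parse_sum_composition(c("TG 52:3", "TG 40:0", "PC 34:1"))
  expect_equal(p$lipid_class, c("TG", "TG", "PC"))
  expect_equal(p$carbons, c(52L, 40L, 34L))
  expect_equal(p$double_bonds, c(3L, 0L, 1L))
  expect_error(parse_sum_composition("TG52.3"),
               class = "wormupr_parse_error")
})

test_that("the TG landscape counts isomers per cell and recovers the planted split", {
  res <- data.frame(feature_id = c("a", "b", "c"),
                    log2_fc = c(1, 1, -1), p_value = c(0.01, 0.2, 0.01),
                    fdr = NA, direction = c("up", "unchanged", "down"))
  ann <- data.frame(feature_id = c("a", "b", "c"),
                    name = c("TG 52:3", "TG 52:3", "TG 44:1"))
  land <- tg_landscape(res, ann)
  expect_equal(nrow(land), 2)
  cell <- land[land$carbons == 52, ]
  expect_equal(cell$n_isomers, 2); expect_equal(cell$n_up, 1)
  # empty input gives an empty landscape
  expect_equal(nrow(tg_landscape(res[0, ], ann)), 0)
  # full planted landscape recovered (change cells exactly)
  exp <- lipid_landscape_experiment(seed = 54, n_features = 400)
  land <- exp$landscape
  planted <- ifelse(land$carbons < 48, "down",
                    ifelse(land$carbons >= 54 & land$double_bonds >= 3,
                           "up", "unchanged"))
  changed <- planted != "unchanged"
  expect_true(all(land$call[changed] == planted[changed]))
  expect_gte(exp$cell_accuracy, 0.9)
})

test_that("class totals sum annotated features per biological sample", {
  x <- rbind(f1 = c(9, 1, 2, 3), f2 = c(9, 10, 20, 30),
             f3 = c(9, 100, 200, 300))
  tab <- make_toy_table(x, groups = c("QC", "wt", "wt", "mut"),
                        is_qc = c(TRUE, FALSE, FALSE, FALSE))
  ann <- data.frame(feature_id = c("f1", "f2", "f3"),
                    name = c("TG 50:2", "TG 52:3", "PC 34:1"))
  tot <- class_total(tab, ann, "TG")
  expect_equal(tot$total, c(11, 22, 33))
  # a single annotated feature totals to its own row
  tot1 <- class_total(tab, ann[2, , drop = FALSE], "TG")
  expect_equal(tot1$total, c(10, 20, 30))
})

test_that("set overlaps partition the union", {
  ov <- set_overlaps(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
  expect_equal(ov$count[ov$region == "A"], 1)
  expect_equal(ov$count[ov$region == "B"], 1)
  expect_equal(ov$count[ov$region == "A&B"], 2)
  dis <- set_overlaps(list(A = c("a"), B = c("b")))
  expect_equal(dis$count[dis$region == "A&B"], 0)
  set.seed(55)
  for (i in 1:50) {
    sets <- list(A = sample(letters, 8), B = sample(letters, 10),
                 C = sample(letters, 5))
    ov <- set_overlaps(sets)
    expect_equal(sum(ov$count), length(unique(unlist(sets))))
    # brute-force membership oracle per region
    u <- unique(unlist(sets))
    inA <- u %in% sets$A; inB <- u %in% sets$B; inC <- u %in% sets$C
    expect_equal(ov$count[ov$region == "A&B&C"], sum(inA & inB & inC))
    expect_equal(ov$count[ov$region == "A"], sum(inA & !inB & !inC))
  }
  expect_error(set_overlaps(list(A = "a")), "2 or 3")
})

test_that("QC filtering commutes with protein normalization on the surviving set", {
  gen <- gen_lipid_table(seed = 56, n_features = 120, missing_qc_frac = 0.1,
                         cv = 0.4, qc_cv = 0.25)
  a <- qc_presence_rsd_filter(protein_normalize(gen$table), 30)
  b <- protein_normalize(qc_presence_rsd_filter(gen$table, 30))
  expect_setequal(rownames(a$intensities), rownames(b$intensities))
})
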
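toy_ct <- function() {
  ct <- rbind(`hsp-6` = c(20, 21), `cdc-42` = c(22, 23),
              `pmp-3` = c(24, 23))
  colnames(ct) <- c("w1", "w2")
  ct_table(ct, housekeeping = c("cdc-42", "pmp-3"))
}

test_that("well clean-up drops failed worms and blanks flagged wells", {
  ct <- rbind(g1 = c(20, 21, 22), g2 = c(25, 26, 27))
  colnames(ct) <- paste0("w", 1:3)
  flags <- matrix("pass", 2, 3, dimnames = dimnames(ct))
  flags[, 3] <- "failed_pcr"           # worm 3: everything failed
  flags["g2", 1] <- "wrong_melt_peak"  # one bad melt curve
  tab <- ct_table(ct, housekeeping = "g1", well_flags = flags)
  out <- clean_ct(tab)
  expect_equal(colnames(out$ct), c("w1", "w2"))
  expect_true(is.na(out$ct["g2", "w1"]))
  expect_equal(sum(!is.na(out$ct)), 3)
  flags[] <- "failed_pcr"
  expect_error(clean_ct(ct_table(ct, "g1", flags)),
               class = "wormupr_empty_table")
})

test_that("the efficiency formula reproduces the printed optimum", {
  # optimal slope -3.3: amplification factor 10^(1/3.3) rounds to 2
  expect_equal(round(10^(1 / 3.3)), 2)
  expect_equal(primer_efficiency(-3.3), 100 * 10^(1 / 3.3) / 2)
  expect_equal(primer_efficiency(-3.3), 100.46, tolerance = 1e-4)
  # steep-slope limit: factor 1, efficiency 50%
  expect_equal(primer_efficiency(-1e9), 50, tolerance = 1e-6)
  expect_error(primer_efficiency(0.5), class = "wormupr_invalid_slope")
})

test_that("standard curves recover slope and efficiency", {
  dil <- -(0:4) * log10(2)  # 1:2 series
  exact <- suppressWarnings(fit_standard_curve(dil, 20 - 3.3 * dil))
  expect_equal(exact$slope, -3.3)
  expect_equal(exact$r_squared, 1)
  set.seed(1)
  noisy <- fit_standard_curve(dil, 20 - 3.3 * dil + rnorm(5, 0, 0.1))
  # slope standard error here is ~0.105; allow 3 SE
  expect_lt(abs(noisy$slope + 3.3), 0.32)
  # a flat titration has no usable slope
  expect_error(suppressWarnings(fit_standard_curve(dil, rep(20, 5))),
               class = "wormupr_invalid_slope")
  expect_error(fit_standard_curve(dil[1:2], c(20, 21)),
               class = "wormupr_insufficient_data")
})

test_that("slopes in the accepted efficiency band round-trip through the formula", {
  # efficiency 90..115% <-> slope = -1/log10(2 * eff / 100)
  for (eff in c(90, 100, 107.5, 115)) {
    slope <- -1 / log10(2 * eff / 100)
    expect_lt(slope, 0)
    expect_equal(primer_efficiency(slope), eff, tolerance = 1e-9)
  }
})

test_that("delta-Ct expression obeys its identities", {
  tab <- toy_ct()
  ex <- relative_expression(tab)
  # hand-computed: hk means are 23, 23; hsp-6 dCt = -3, -2
  expect_equal(unname(ex["hsp-6", ]), c(8, 4))
  expect_equal(unname(ex["cdc-42", ]), 2^(-c(-1, 0)))
  # a lone housekeeping gene always reads 1
  one <- ct_table(tab$ct, housekeeping = "cdc-42")
  expect_equal(unname(relative_expression(one)["cdc-42", ]), c(1, 1))
  # Ct one cycle below the housekeeping mean doubles expression
  ct <- rbind(g = 22, hk = 23); colnames(ct) <- "w1"
  expect_equal(relative_expression(ct_table(ct, "hk"))["g", "w1"], 2)
  # adding a constant to a worm's column leaves expression unchanged
  shifted <- tab$ct; shifted[, 1] <- shifted[, 1] + 3
  ex2 <- relative_expression(ct_table(shifted, tab$housekeeping))
  expect_equal(ex2, ex)
})

test_that("expression CV is the sample SD over the mean", {
  expect_equal(expression_cv(rep(4, 5))$cv, 0)
  expect_equal(expression_cv(c(8, 10, 12))$cv, 0.2)
  expect_equal(expression_cv(c(8, 10, 12) * 50)$cv, 0.2)
  expect_error(expression_cv(c(1, 2)), class = "wormupr_insufficient_data")
})

test_that("variability normalization pins the reference record at 1", {
  rec <- rbind(expression_cv(c(8, 10, 12), "nlp-29", "wt"),
               expression_cv(c(9, 10, 11), "hsp-6", "wt"))
  out <- normalize_variability(rec, "nlp-29", "wt")
  expect_equal(out$cv_normalized[1], 1)
  expect_equal(out$cv_normalized[2], rec$cv[2] / rec$cv[1])
  expect_error(normalize_variability(rec, "absent", "wt"),
               class = "wormupr_normalization_error")
})

test_that("the planted CV ladder is recovered in order", {
  exp <- qpcr_ladder_experiment(seed = 300, n_runs = 30)
  expect_gte(exp$order_correct_frac, 0.95)
  rel_err <- abs(exp$mean_recovered - exp$planted) / exp$planted
  expect_true(all(rel_err < 0.15))
})
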
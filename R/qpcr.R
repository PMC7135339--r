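#' Ct table container
#'
#' Genes x individual worms matrix of qPCR Ct values with a designated
#' housekeeping-gene subset and per-well quality flags.
#'
#' @param ct numeric matrix (rownames = genes, colnames = worm ids);
#'   values in cycles, `NA` allowed.
#' @param housekeeping character vector of housekeeping gene names
#'   (must appear in `rownames(ct)`).
#' @param well_flags optional character matrix of the same shape with
#'   values `"pass"`, `"failed_pcr"` or `"wrong_melt_peak"`.
#' @return A `ct_table` object.
#' @export
ct_table <- function(ct, housekeeping, well_flags = NULL) {
  ct <- as.matrix(ct)
  if (is.null(rownames(ct))) stop("ct needs gene rownames")
  if (is.null(colnames(ct))) colnames(ct) <- paste0("worm", seq_len(ncol(ct)))
  if (!all(housekeeping %in% rownames(ct))) {
    stop("housekeeping genes must exist in the table")
  }
  if (any(ct <= 0 | ct >= 45, na.rm = TRUE)) {
    stop("Ct values must lie in (0, 45)")
  }
  if (is.null(well_flags)) {
    well_flags <- matrix("pass", nrow(ct), ncol(ct),
                         dimnames = dimnames(ct))
    well_flags[is.na(ct)] <- "failed_pcr"
  }
  stopifnot(all(dim(well_flags) == dim(ct)),
            all(well_flags %in% c("pass", "failed_pcr", "wrong_melt_peak")))
  structure(list(ct = ct, housekeeping = housekeeping,
                 well_flags = well_flags),
            class = "ct_table")
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("<ct_table: %d genes x %d worms, %d housekeeping, %d flagged wells>\n",
              nrow(x$ct), ncol(x$ct), length(x$housekeeping),
              sum(x$well_flags != "pass")))
  invisible(x)
}

#' Clean up a Ct table by well flags
#'
#' Blanks individual wells flagged `failed_pcr` or `wrong_melt_peak` and
#' drops worms for which every PCR failed.
#'
#' @param table a [ct_table()].
#' @return The cleaned `ct_table`.
#' @export
clean_ct <- function(table) {
  ct <- table$ct
  ct[table$well_flags != "pass"] <- NA_real_
  dead <- colSums(!is.na(ct)) == 0
  if (all(dead)) {
    stop_wormupr("empty_table", "every worm failed all PCRs")
  }
  ct_table(ct[, !dead, drop = FALSE], table$housekeeping,
           table$well_flags[, !dead, drop = FALSE])
}

#' Primer efficiency from a standard-curve slope
#'
#' `efficiency_pct = 100 * 10^(-1/slope) / 2`: the per-cycle
#' amplification factor implied by the slope of Ct against log10
#' dilution, expressed relative to perfect doubling (an optimal slope of
#' -3.3 gives a factor of 10^(1/3.3) ~ 2, i.e. ~100%).
#'
#' @param slope cycles per log10 dilution; must be negative.
#' @return Efficiency in percent.
#' @export
primer_efficiency <- function(slope) {
  if (any(slope >= 0)) {
    stop_wormupr("invalid_slope", "standard-curve slope must be negative")
  }
  100 * 10^(-1 / slope) / 2
}

#' Fit a qPCR standard curve
#'
#' Least-squares line of Ct on log10 dilution over the linear
#' amplification range; slope, R-squared and the implied primer
#' efficiency are returned.
#'
#' @param dilution_log10 numeric vector of log10 dilution factors.
#' @param ct matching Ct values.
#' @return List with `slope`, `intercept`, `r_squared`,
#'   `efficiency_pct`.
#' @export
fit_standard_curve <- function(dilution_log10, ct) {
  if (length(dilution_log10) < 3 || length(ct) != length(dilution_log10)) {
    stop_wormupr("insufficient_data",
                 "need at least 3 dilution points of matching length")
  }
  fit <- lm(ct ~ dilution_log10)
  slope <- unname(coef(fit)[2])
  r2 <- summary(fit)$r.squared
  list(slope = slope, intercept = unname(coef(fit)[1]), r_squared = r2,
       efficiency_pct = primer_efficiency(slope))
}

#' Housekeeping-normalized Ct values
#'
#' Per worm, each gene's Ct minus the mean housekeeping Ct of that worm
#' (the delta-Ct matrix underlying [relative_expression()]); variability
#' can alternatively be computed on this cycle scale.
#'
#' @param table a [ct_table()].
#' @return Numeric matrix of delta-Ct values, genes x worms.
#' @export
delta_ct <- function(table) {
  ct <- table$ct
  hk <- ct[table$housekeeping, , drop = FALSE]
  sweep(ct, 2, colMeans(hk, na.rm = TRUE), "-")
}

#' Relative expression by the delta-Ct method
#'
#' Per worm, each gene's Ct is referenced to the mean housekeeping Ct of
#' that worm: `expression = 2^-(Ct_gene - mean(Ct_housekeeping))`. Worms
#' with no housekeeping values are excluded (with a warning).
#'
#' @param table a [ct_table()] (cleaned).
#' @return Numeric matrix of relative expression, genes x worms.
#' @export
relative_expression <- function(table) {
  ct <- table$ct
  hk <- ct[table$housekeeping, , drop = FALSE]
  hk_mean <- colMeans(hk, na.rm = TRUE)
  bad <- !is.finite(hk_mean)
  if (any(bad)) {
    warning(sprintf("%d worm(s) without housekeeping Ct excluded",
                    sum(bad)))
    ct <- ct[, !bad, drop = FALSE]
    hk_mean <- hk_mean[!bad]
  }
  dct <- sweep(ct, 2, hk_mean, "-")
  2^(-dct)
}

#' Coefficient of variation of per-worm expression
#'
#' `cv = sample SD / mean` of relative expression across worms of one
#' genotype, the study's measure of inter-individual variability.
#'
#' @param expressions numeric vector of one gene's relative expression
#'   across worms (missing wells excluded).
#' @param gene,genotype identifiers carried into the record.
#' @return One-row data frame: `gene`, `genotype`, `n`, `cv`.
#' @export
expression_cv <- function(expressions, gene = NA_character_,
                          genotype = NA_character_) {
  x <- expressions[!is.na(expressions)]
  if (length(x) < 3) {
    stop_wormupr("insufficient_data", "need at least 3 worms")
  }
  m <- mean(x)
  if (m == 0) {
    warning("zero mean expression: CV undefined")
    cv <- NA_real_
  } else {
    cv <- sd(x) / m
  }
  data.frame(gene = gene, genotype = genotype, n = length(x), cv = cv,
             stringsAsFactors = FALSE)
}

#' Normalize variability records to a reference gene/genotype
#'
#' Divides every CV by the CV of the reference record, so the reference
#' (e.g. the highly variable nlp-29 locus in wild type) reads 1.
#'
#' @param records data frame of rows from [expression_cv()].
#' @param reference_gene,reference_genotype the reference record.
#' @return The input with a `cv_normalized` column.
#' @export
normalize_variability <- function(records, reference_gene,
                                  reference_genotype) {
  ref <- records$cv[records$gene == reference_gene &
                      records$genotype == reference_genotype]
  if (length(ref) != 1 || is.na(ref) || ref <= 0) {
    stop_wormupr("normalization_error",
                 "missing or zero-variability reference record")
  }
  records$cv_normalized <- records$cv / ref
  records
}
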
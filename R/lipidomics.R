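#' Lipid feature table container
#'
#' Features x samples intensity matrix with per-sample metadata (group,
#' pooled-QC flag, injection order, protein content) and optional
#' per-feature annotations.
#'
#' @param intensities numeric matrix, features in rows (rownames = feature
#'   ids), samples in columns; `NA` marks a feature not detected in that
#'   sample.
#' @param sample_meta data frame with columns `sample`, `group`, `is_qc`,
#'   `injection_order`, `protein_ug` (protein in micrograms; may be `NA`
#'   for QCs).
#' @param feature_meta optional data frame keyed by `feature_id`.
#' @return A `lipid_table` object.
#' @export
lipid_table <- function(intensities, sample_meta, feature_meta = NULL) {
  intensities <- as.matrix(intensities)
  stopifnot(ncol(intensities) == nrow(sample_meta),
            all(c("sample", "group", "is_qc", "injection_order",
                  "protein_ug") %in% names(sample_meta)))
  if (anyDuplicated(sample_meta$injection_order)) {
    stop("injection_order must be unique per sample")
  }
  if (any(intensities < 0, na.rm = TRUE)) {
    stop("intensities must be >= 0 where present")
  }
  if (any(!sample_meta$is_qc & (is.na(sample_meta$protein_ug) |
                                sample_meta$protein_ug <= 0))) {
    stop("protein_ug must be > 0 for biological samples")
  }
  colnames(intensities) <- sample_meta$sample
  if (is.null(rownames(intensities))) {
    rownames(intensities) <- paste0("F", seq_len(nrow(intensities)))
  }
  structure(list(intensities = intensities, sample_meta = sample_meta,
                 feature_meta = feature_meta),
            class = "lipid_table")
}

#' @export
print.lipid_table <- function(x, ...) {
  cat(sprintf("<lipid_table: %d features x %d samples (%d QC)>\n",
              nrow(x$intensities), ncol(x$intensities),
              sum(x$sample_meta$is_qc)))
  invisible(x)
}

qc_columns <- function(table) which(table$sample_meta$is_qc)

#' QC presence and RSD feature filter
#'
#' Keeps features that are detected in every pooled QC sample and whose
#' relative standard deviation over the QCs (100 * sample SD / mean) is
#' strictly below `rsd_max` percent.
#'
#' @param table a [lipid_table()].
#' @param rsd_max maximum QC RSD in percent (default 30).
#' @return The filtered `lipid_table`; the per-feature QC RSDs of the
#'   survivors are attached as attribute `"qc_rsd"`.
#' @export
qc_presence_rsd_filter <- function(table, rsd_max = 30) {
  qc <- qc_columns(table)
  if (length(qc) < 2) {
    stop_wormupr("insufficient_qc", "need at least 2 pooled QC samples")
  }
  qx <- table$intensities[, qc, drop = FALSE]
  present <- rowSums(is.na(qx)) == 0
  rsd <- 100 * apply(qx, 1, sd) / rowMeans(qx)
  rsd[rowMeans(qx) == 0] <- Inf
  keep <- present & !is.na(rsd) & rsd < rsd_max
  out <- table
  out$intensities <- table$intensities[keep, , drop = FALSE]
  if (!is.null(table$feature_meta)) {
    out$feature_meta <-
      table$feature_meta[match(rownames(out$intensities),
                               table$feature_meta$feature_id), ,
                         drop = FALSE]
  }
  attr(out, "qc_rsd") <- rsd[keep]
  out
}

#' Protein-content normalization
#'
#' Divides every biological sample's intensities by its protein content
#' (micrograms); pooled QC samples are left untouched.
#'
#' @param table a [lipid_table()].
#' @return The normalized `lipid_table`.
#' @export
protein_normalize <- function(table) {
  meta <- table$sample_meta
  bio <- !meta$is_qc
  missing <- bio & (is.na(meta$protein_ug) | meta$protein_ug <= 0)
  if (any(missing)) {
    stop(paste("missing protein content for samples:",
               paste(meta$sample[missing], collapse = ", ")))
  }
  out <- table
  out$intensities[, bio] <-
    sweep(table$intensities[, bio, drop = FALSE], 2,
          meta$protein_ug[bio], "/")
  out
}

#' QC-anchored injection-order drift normalization
#'
#' Per feature, fits a locally weighted regression (lowess, span 0.75) of
#' the pooled-QC intensities on injection order, divides every sample by
#' the trend value interpolated at its injection order, and rescales so
#' the QC median is preserved. With fewer than 4 QCs the correction falls
#' back to a global QC-median ratio (with a message).
#'
#' @param table a [lipid_table()].
#' @param span lowess smoother span (default 0.75).
#' @return The drift-corrected `lipid_table`.
#' @export
qc_drift_normalize <- function(table, span = 0.75) {
  qc <- qc_columns(table)
  ord <- table$sample_meta$injection_order
  out <- table
  x <- table$intensities
  if (length(qc) < 4) {
    # too few anchors for a trend: align each feature's level to the
    # grand QC median instead (no order-dependent correction possible)
    message("fewer than 4 QC samples: falling back to QC-median ratio correction")
    grand <- median(x[, qc], na.rm = TRUE)
    for (i in seq_len(nrow(x))) {
      qmed <- median(x[i, qc], na.rm = TRUE)
      if (is.na(qmed) || qmed == 0) next
      out$intensities[i, ] <- x[i, ] / qmed * grand
    }
    return(out)
  }
  for (i in seq_len(nrow(x))) {
    qv <- x[i, qc]
    ok <- !is.na(qv)
    if (sum(ok) < 4) next
    fit <- lowess(ord[qc][ok], qv[ok], f = span)
    trend <- approx(fit$x, fit$y, xout = ord, rule = 2)$y
    if (any(trend <= 0)) next
    corrected <- x[i, ] / trend
    scale <- median(qv[ok]) / median((qv / trend[qc])[ok])
    out$intensities[i, ] <- corrected * scale
  }
  out
}

#' Per-feature Welch differential test
#'
#' Two-sided Welch t-test per feature between two biological groups on
#' (normalized) intensities, with no multiple-testing correction: a raw
#' p-value below `alpha` together with the fold-change sign sets the
#' direction call. An FDR (Benjamini-Hochberg) column is reported for
#' reference but not used for the calls. Missing intensities are excluded
#' pairwise; features with fewer than 3 values in either group are
#' flagged `insufficient`.
#'
#' @param table a [lipid_table()].
#' @param group_a,group_b group labels (A is the mutant/treatment, B the
#'   reference: fold change is A over B).
#' @param alpha significance level (default 0.05).
#' @return Data frame with `feature_id`, `log2_fc`, `p_value`, `fdr`,
#'   `direction` (up/down/unchanged/insufficient).
#' @export
welch_differential <- function(table, group_a, group_b, alpha = 0.05) {
  meta <- table$sample_meta
  ca <- which(!meta$is_qc & meta$group == group_a)
  cb <- which(!meta$is_qc & meta$group == group_b)
  x <- table$intensities
  res <- lapply(seq_len(nrow(x)), function(i) {
    va <- x[i, ca]; va <- va[!is.na(va)]
    vb <- x[i, cb]; vb <- vb[!is.na(vb)]
    if (length(va) < 3 || length(vb) < 3) {
      return(c(log2_fc = NA_real_, p_value = NA_real_))
    }
    fc <- mean(va) / mean(vb)
    p <- if (sd(va) == 0 && sd(vb) == 0) {
      if (mean(va) == mean(vb)) 1 else 0
    } else {
      t.test(va, vb, var.equal = FALSE)$p.value
    }
    c(log2_fc = log2(fc), p_value = p)
  })
  res <- do.call(rbind, res)
  fdr <- p.adjust(res[, "p_value"], method = "BH")
  direction <- rep("unchanged", nrow(x))
  direction[is.na(res[, "p_value"])] <- "insufficient"
  sig <- !is.na(res[, "p_value"]) & res[, "p_value"] < alpha
  direction[sig & res[, "log2_fc"] > 0] <- "up"
  direction[sig & res[, "log2_fc"] < 0] <- "down"
  data.frame(
    feature_id = rownames(x),
    log2_fc = res[, "log2_fc"],
    p_value = res[, "p_value"],
    fdr = fdr,
    direction = direction,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Annotation match-score filter
#'
#' Keeps annotations whose forward and reverse spectral matching scores
#' are both strictly above `min_score`.
#'
#' @param annotations data frame with `match_score_fwd` and
#'   `match_score_rev` in `[0, 1]`.
#' @param min_score strict lower bound (default 0.75).
#' @return The filtered data frame.
#' @export
annotation_score_filter <- function(annotations, min_score = 0.75) {
  keep <- annotations$match_score_fwd > min_score &
    annotations$match_score_rev > min_score
  annotations[keep, , drop = FALSE]
}

#' Parse a lipid sum-composition shorthand
#'
#' Splits names like `"TG 52:3"` into lipid class, total acyl carbons and
#' total double bonds.
#'
#' @param name character vector of shorthand names.
#' @return Data frame with `lipid_class`, `carbons`, `double_bonds`.
#' @export
parse_sum_composition <- function(name) {
  m <- regmatches(name, regexec("^([A-Za-z][A-Za-z0-9]*) (\\d+):(\\d+)$",
                                name))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop_wormupr("parse_error",
                 paste("malformed sum composition:",
                       paste(name[bad], collapse = ", ")))
  }
  out <- data.frame(
    lipid_class = vapply(m, `[`, "", 2L),
    carbons = as.integer(vapply(m, `[`, "", 3L)),
    double_bonds = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  if (any(out$carbons <= 0)) {
    stop_wormupr("parse_error", "carbons must be > 0")
  }
  out
}

#' Triacylglycerol sum-composition landscape
#'
#' Groups differential results by sum composition (total carbons x total
#' double bonds) and counts, per cell, the detected isomers and the
#' significantly up/down members.
#'
#' @param results data frame from [welch_differential()].
#' @param annotations data frame with `feature_id`, `name` (sum
#'   composition shorthand); only rows of `lipid_class` are used.
#' @param lipid_class class to tabulate (default `"TG"`).
#' @return Data frame with `carbons`, `double_bonds`, `n_isomers`,
#'   `n_up`, `n_down`.
#' @export
tg_landscape <- function(results, annotations, lipid_class = "TG") {
  ann <- merge(annotations, results, by = "feature_id")
  if (nrow(ann) == 0) {
    return(data.frame(carbons = integer(0), double_bonds = integer(0),
                      n_isomers = integer(0), n_up = integer(0),
                      n_down = integer(0)))
  }
  comp <- parse_sum_composition(ann$name)
  ann <- cbind(ann, comp)
  ann <- ann[ann$lipid_class == lipid_class, , drop = FALSE]
  if (nrow(ann) == 0) {
    return(data.frame(carbons = integer(0), double_bonds = integer(0),
                      n_isomers = integer(0), n_up = integer(0),
                      n_down = integer(0)))
  }
  key <- interaction(ann$carbons, ann$double_bonds, drop = TRUE)
  agg <- do.call(rbind, lapply(split(ann, key), function(d) {
    data.frame(carbons = d$carbons[1], double_bonds = d$double_bonds[1],
               n_isomers = nrow(d),
               n_up = sum(d$direction == "up"),
               n_down = sum(d$direction == "down"))
  }))
  agg <- agg[order(agg$carbons, agg$double_bonds), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Classify landscape cells by their isomer direction calls
#'
#' A sum-composition cell is called `"up"` (`"down"`) when a strict
#' majority of its detected isomers is significantly up (down); cells
#' without a majority are `"unchanged"`. The majority rule keeps a single
#' false-positive isomer from recoloring a multi-isomer cell.
#'
#' @param landscape data frame from [tg_landscape()].
#' @return The landscape with a `call` column.
#' @export
classify_landscape_cells <- function(landscape) {
  landscape$call <- ifelse(
    landscape$n_up > landscape$n_isomers / 2, "up",
    ifelse(landscape$n_down > landscape$n_isomers / 2, "down",
           "unchanged"))
  landscape
}

#' Per-sample class totals
#'
#' Sums (normalized) intensities over all features of one lipid class for
#' every biological sample. Only features present in the (QC-passing)
#' table are summed.
#'
#' @param table a [lipid_table()].
#' @param annotations data frame with `feature_id`, `name`.
#' @param lipid_class class to total (default `"TG"`).
#' @return Data frame with `sample`, `group`, `total`.
#' @export
class_total <- function(table, annotations, lipid_class = "TG") {
  comp <- parse_sum_composition(annotations$name)
  ids <- annotations$feature_id[comp$lipid_class == lipid_class]
  rows <- rownames(table$intensities) %in% ids
  bio <- !table$sample_meta$is_qc
  totals <- colSums(table$intensities[rows, bio, drop = FALSE], na.rm = TRUE)
  data.frame(sample = table$sample_meta$sample[bio],
             group = table$sample_meta$group[bio],
             total = unname(totals),
             stringsAsFactors = FALSE)
}

#' Intersection-region counts for 2-3 named sets
#'
#' Exact Venn-region counts; the regions partition the union of the sets.
#'
#' @param sets named list of 2 or 3 character vectors of feature ids.
#' @return Data frame with `region` (e.g. `"A&B"`) and `count`.
#' @export
set_overlaps <- function(sets) {
  k <- length(sets)
  if (k < 2 || k > 3) stop("set_overlaps supports 2 or 3 sets")
  sets <- lapply(sets, unique)
  u <- unique(unlist(sets))
  membership <- vapply(sets, function(s) u %in% s, logical(length(u)))
  if (length(u) == 1) membership <- matrix(membership, nrow = 1)
  pattern <- apply(membership, 1, function(b) {
    paste(names(sets)[b], collapse = "&")
  })
  combos <- unlist(lapply(seq_len(k), function(m) {
    combn(names(sets), m, paste, collapse = "&")
  }))
  counts <- vapply(combos, function(cb) sum(pattern == cb), 1L)
  data.frame(region = combos, count = unname(counts),
             stringsAsFactors = FALSE, row.names = NULL)
}
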
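#' Ordinal suppression grades
#' @export
suppression_grades <- c("very strong", "strong", "medium", "weak", "none")

#' Validate a suppressor annotation table
#'
#' Checks the screen bookkeeping invariants: grades on the ordinal scale
#' and the autophagy flag set exactly where a flag source is recorded.
#'
#' @param table data frame with columns `gene`, grade columns
#'   `grade_fzo1`, `grade_drp1`, `grade_spg7`, `autophagy_flag`
#'   (logical), `flag_source` (`"autophagy_screen"`, `"literature"` or
#'   `NA`) and optional `go_category`.
#' @return The table, invisibly, after validation.
#' @export
validate_suppressor_table <- function(table) {
  grade_cols <- intersect(c("grade_fzo1", "grade_drp1", "grade_spg7"),
                          names(table))
  for (g in grade_cols) {
    if (!all(table[[g]] %in% suppression_grades)) {
      stop(sprintf("column %s contains values off the ordinal scale", g))
    }
  }
  if (!identical(table$autophagy_flag, !is.na(table$flag_source))) {
    stop("autophagy_flag must be TRUE exactly where flag_source is set")
  }
  invisible(table)
}

#' Percentage of suppressors flagged as autophagy regulators
#'
#' `100 * flagged / total`, rounded to the nearest integer percent (the
#' reporting convention of the screen summary).
#'
#' @param table a validated suppressor table.
#' @return Integer percent.
#' @export
fraction_flagged <- function(table) {
  if (nrow(table) == 0) stop_wormupr("empty_table", "empty suppressor table")
  as.integer(round(100 * sum(table$autophagy_flag) / nrow(table)))
}

#' Percentage of genes suppressing a given genetic background
#'
#' Counts grades other than `"none"` in the background's grade column,
#' optionally restricted to autophagy-flagged genes, as an integer
#' percent of the rows considered.
#'
#' @param table a validated suppressor table.
#' @param background one of `"fzo1"`, `"drp1"`, `"spg7"`.
#' @param among_flagged restrict numerator and denominator to
#'   autophagy-flagged rows (default `TRUE`, the screen's convention for
#'   the cross-background follow-up).
#' @return Integer percent.
#' @export
fraction_suppressing <- function(table, background,
                                 among_flagged = TRUE) {
  col <- paste0("grade_", background)
  if (!col %in% names(table)) {
    stop(sprintf("background %s absent from table", background))
  }
  if (among_flagged) table <- table[table$autophagy_flag, , drop = FALSE]
  if (nrow(table) == 0) stop_wormupr("empty_table", "no rows to consider")
  as.integer(round(100 * sum(table[[col]] != "none") / nrow(table)))
}

#' Count rows in given GO categories
#'
#' @param table a suppressor table (or any subset of it).
#' @param categories character vector of GO category labels.
#' @return Integer count of rows whose `go_category` matches any listed
#'   category.
#' @export
count_by_go <- function(table, categories) {
  if (length(categories) == 0) return(0L)
  sum(!is.na(table$go_category) & table$go_category %in% categories)
}

#' Synthetic counts-faithful screen fixture
#'
#' The per-gene grade table of the original screen is a supplementary
#' dataset not shipped here; this synthetic stand-in reproduces exactly
#' the counts printed in the screen summary: 299 suppressors of the
#' fusion-mutant reporter, 143 flagged as autophagy regulators, 138 of
#' the flagged set also suppressing the fission mutant, 90 suppressing
#' the protease mutant, and 41 of those 90 in the GO categories
#' 'Translation' or 'Ribosome Biogenesis'. Grade labels beyond
#' none/medium are arbitrary.
#'
#' @return A validated suppressor table with 299 rows.
#' @export
synthetic_screen_table <- function() {
  n <- 299L; n_flag <- 143L; n_drp <- 138L; n_spg <- 90L; n_go <- 41L
  gene <- sprintf("gene-%03d", seq_len(n))
  flagged <- seq_len(n) <= n_flag
  flag_source <- ifelse(flagged,
                        rep_len(c("autophagy_screen", "literature"), n),
                        NA_character_)
  flag_source[!flagged] <- NA_character_
  grade_fzo1 <- rep("medium", n)  # all rows are suppressors of fzo-1
  grade_drp1 <- rep("none", n)
  grade_drp1[seq_len(n_drp)] <- "medium"       # within the flagged 143
  grade_spg7 <- rep("none", n)
  grade_spg7[seq_len(n_spg)] <- "medium"       # within the flagged 143
  go_category <- rep(NA_character_, n)
  go_category[seq_len(n_go)] <-
    rep_len(c("Translation", "Ribosome Biogenesis"), n_go)
  tab <- data.frame(gene = gene,
                    grade_fzo1 = grade_fzo1,
                    grade_drp1 = grade_drp1,
                    grade_spg7 = grade_spg7,
                    autophagy_flag = flagged,
                    flag_source = flag_source,
                    go_category = go_category,
                    stringsAsFactors = FALSE)
  validate_suppressor_table(tab)
  tab
}
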
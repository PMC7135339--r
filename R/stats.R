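#' Brown-Forsythe test for equality of group variances
#'
#' One-way ANOVA on the absolute deviations from the group medians.
#'
#' @param groups named list of numeric vectors.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
brown_forsythe <- function(groups) {
  z <- unlist(lapply(groups, function(g) abs(g - median(g))))
  f <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  fit <- stats::anova(stats::lm(z ~ f))
  list(statistic = fit$`F value`[1], p_value = fit$`Pr(>F)`[1],
       df = fit$Df)
}

#' Dunnett many-to-one adjusted p-values
#'
#' Two-sided p-values for comparing each treatment group mean to the
#' control, using the equicorrelated multivariate-t distribution of the
#' maximum absolute Dunnett statistic. The quasi-Monte-Carlo integration
#' is run under a fixed internal RNG state so results are reproducible.
#'
#' @param groups named list of numeric vectors; one must be the control.
#' @param control_label name of the control group.
#' @return Data frame with `comparison`, `estimate`, `t`, `p_value`.
#' @export
dunnett_pvalues <- function(groups, control_label) {
  stopifnot(control_label %in% names(groups))
  ctrl <- groups[[control_label]]
  trt <- groups[names(groups) != control_label]
  k <- length(trt)
  ns <- vapply(trt, length, 1L)
  n0 <- length(ctrl)
  N <- sum(ns) + n0
  df <- N - (k + 1)
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 1.0)) / df
  tstat <- vapply(seq_len(k), function(i) {
    (mean(trt[[i]]) - mean(ctrl)) / sqrt(mse * (1 / ns[i] + 1 / n0))
  }, 1.0)
  lam <- sqrt(ns / (ns + n0))
  corr <- outer(lam, lam)
  diag(corr) <- 1
  # pmvt draws from the session RNG; isolate it for reproducibility
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(190848L)
  pv <- vapply(abs(tstat), function(q) {
    if (k == 1) {
      2 * pt(-q, df)
    } else {
      1 - mvtnorm::pmvt(lower = rep(-q, k), upper = rep(q, k),
                        df = df, corr = corr, sigma = NULL)[1]
    }
  }, 1.0)
  data.frame(
    comparison = paste(names(trt), "-", control_label),
    estimate = vapply(trt, mean, 1.0) - mean(ctrl),
    t = tstat,
    p_value = pmin(pmax(pv, 0), 1),
    row.names = NULL
  )
}

#' Dunn many-to-one rank comparisons with Bonferroni adjustment
#'
#' Post-hoc z tests on mean ranks (with tie correction) of each treatment
#' group against the control, Bonferroni-adjusted over the many-to-one
#' family.
#'
#' @inheritParams dunnett_pvalues
#' @return Data frame with `comparison`, `z`, `p_value` (adjusted).
#' @export
dunn_pvalues <- function(groups, control_label) {
  stopifnot(control_label %in% names(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), vapply(groups, length, 1L))
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mr <- tapply(r, g, mean)
  ns <- tapply(r, g, length)
  trt <- setdiff(names(groups), control_label)
  z <- vapply(trt, function(lab) {
    (mr[[lab]] - mr[[control_label]]) /
      sqrt((N * (N + 1) / 12 - tie_corr) *
             (1 / ns[[lab]] + 1 / ns[[control_label]]))
  }, 1.0)
  p <- pmin(2 * pnorm(-abs(z)) * length(trt), 1)
  data.frame(
    comparison = paste(trt, "-", control_label),
    z = z,
    p_value = p,
    row.names = NULL
  )
}

new_comparison_result <- function(test_name, decisions, alpha,
                                  normality_p, variance_p) {
  structure(list(test_name = test_name, decisions = decisions,
                 alpha = alpha, normality_p = normality_p,
                 variance_p = variance_p),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result: %s (alpha = %g)>\n", x$test_name,
              x$alpha))
  print(x$decisions)
  invisible(x)
}

#' Gated two-group comparison
#'
#' Shapiro-Wilk normality on each group at the gate level; if both pass,
#' an F-test of variances decides between the pooled-variance t-test and
#' Welch's correction. When a normality gate fails, Welch's t is used as
#' the robust fallback (the two-group procedure stays in the t family;
#' rank-based routing applies only to many-group designs). Gate p-values
#' are reported alongside the decision.
#'
#' @param group_a,group_b numeric vectors, each of length >= 3.
#' @param alpha significance level (default 0.05); also the gate level.
#' @param gate_alpha level for the normality/variance gates (default
#'   `alpha`).
#' @return A `comparison_result` with `test_name` `"t"` or `"welch_t"`.
#' @export
compare_two <- function(group_a, group_b, alpha = 0.05,
                        gate_alpha = alpha) {
  if (length(group_a) < 3 || length(group_b) < 3) {
    stop_wormupr("insufficient_data",
                 "each group needs at least 3 observations")
  }
  norm_p <- c(a = shapiro_p(group_a), b = shapiro_p(group_b))
  normal <- all(norm_p > gate_alpha, na.rm = TRUE)
  var_p <- tryCatch(var.test(group_a, group_b)$p.value,
                    error = function(e) NA_real_)
  pooled <- normal && !is.na(var_p) && var_p > gate_alpha
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    # degenerate: no within-group variation, decide on the means alone
    same <- mean(group_a) == mean(group_b)
    tt <- list(statistic = c(t = if (same) 0 else Inf),
               p.value = if (same) 1 else 0)
    pooled <- TRUE
  } else {
    tt <- t.test(group_a, group_b, var.equal = pooled)
  }
  new_comparison_result(
    test_name = if (pooled) "t" else "welch_t",
    decisions = data.frame(
      comparison = "A - B",
      estimate = mean(group_a) - mean(group_b),
      statistic = unname(tt$statistic),
      p_value = tt$p.value
    ),
    alpha = alpha, normality_p = norm_p, variance_p = var_p
  )
}

# Shapiro-Wilk p-value; constant samples have no evidence against
# normality the test can express, treat as a degenerate pass (p = 1).
shapiro_p <- function(x) {
  if (length(unique(x)) < 2) return(1)
  shapiro.test(x)$p.value
}

#' Gated many-to-one group comparison
#'
#' Shapiro-Wilk per group and Brown-Forsythe across groups at the gate
#' level. If every gate passes: one-way ANOVA with Dunnett's many-to-one
#' post hoc test. Otherwise: Kruskal-Wallis with Dunn's many-to-one post
#' hoc test (Bonferroni-adjusted).
#'
#' @param groups named list of numeric vectors (>= 3 groups, each n >= 3).
#' @param control_label name of the control group.
#' @param alpha significance level (default 0.05).
#' @param gate_alpha gate level (default `alpha`).
#' @return A `comparison_result` with `test_name` `"anova_dunnett"` or
#'   `"kruskal_dunn"`.
#' @export
compare_many_to_control <- function(groups, control_label, alpha = 0.05,
                                    gate_alpha = alpha) {
  if (length(groups) < 3) {
    stop_wormupr("insufficient_data", "need at least 3 groups")
  }
  if (any(vapply(groups, length, 1L) < 3)) {
    stop_wormupr("insufficient_data",
                 "each group needs at least 3 observations")
  }
  stopifnot(control_label %in% names(groups))
  norm_p <- vapply(groups, shapiro_p, 1.0)
  bf <- tryCatch(brown_forsythe(groups),
                 error = function(e) list(p_value = NA_real_))
  parametric <- all(norm_p > gate_alpha) && !is.na(bf$p_value) &&
    bf$p_value > gate_alpha
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, 1L)),
              levels = names(groups))
  if (parametric) {
    omnibus <- stats::anova(stats::lm(x ~ g))$`Pr(>F)`[1]
    dec <- dunnett_pvalues(groups, control_label)
    test_name <- "anova_dunnett"
  } else {
    omnibus <- kruskal.test(x, g)$p.value
    dec <- dunn_pvalues(groups, control_label)
    test_name <- "kruskal_dunn"
  }
  res <- new_comparison_result(test_name, dec, alpha, norm_p, bf$p_value)
  res$omnibus_p <- omnibus
  res
}
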
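# Two-arm group statistics: Wilcoxon rank-sum for parameter levels,
# pooled-variance t-tests for 0 h - 3 h changes, Fisher's exact test for
# categorical data, and the clinical-improvement rule. All comparisons are
# two-sided at alpha = 0.05 with no multiplicity correction (explorative
# analysis), and that choice is recorded in the output metadata.

group_comparison <- function(variable, test, statistic, p,
                             n1 = NA, mean1 = NA, sd1 = NA,
                             n2 = NA, mean2 = NA, sd2 = NA) {
  stopifnot(is.na(p) || (p >= 0 && p <= 1))
  data.frame(variable = variable, n1 = n1, mean1 = mean1, sd1 = sd1,
             n2 = n2, mean2 = mean2, sd2 = sd2, test = test,
             statistic = as.numeric(statistic), p = p,
             stringsAsFactors = FALSE)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney test: exact enumeration of the rank-sum
#' distribution when samples are small and untied, otherwise the normal
#' approximation with tie and continuity correction. Fully tied data
#' (every observation identical) yield p = 1.
#'
#' @param x,y Numeric samples, both nonempty.
#' @param variable Label recorded in the result.
#' @return One-row `data.frame` (a group comparison) with group summaries,
#'   the rank-sum statistic `W` and the two-sided p-value.
#' @export
rank_sum_test <- function(x, y, variable = "") {
  if (!length(x) || !length(y)) stop("empty sample")
  if (stats::var(c(x, y)) == 0) {
    return(group_comparison(variable, "rank_sum",
                            length(x) * length(y) / 2, 1,
                            length(x), mean(x), stats::sd(x),
                            length(y), mean(y), stats::sd(y)))
  }
  wt <- suppressWarnings(stats::wilcox.test(x, y, correct = TRUE))
  group_comparison(variable, "rank_sum", unname(wt$statistic),
                   min(wt$p.value, 1),
                   length(x), mean(x), stats::sd(x),
                   length(y), mean(y), stats::sd(y))
}

#' Two-sample pooled-variance t-test
#'
#' Equal-variance Student t-test, `df = n_x + n_y - 2`, two-sided.
#'
#' @param x,y Numeric samples with at least 2 observations each and
#'   positive pooled variance.
#' @param variable Label recorded in the result.
#' @return One-row group-comparison `data.frame`.
#' @export
t_test_two_sample <- function(x, y, variable = "") {
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per group")
  sp2 <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 <= 0) stop("zero pooled variance")
  tt <- stats::t.test(x, y, var.equal = TRUE)
  group_comparison(variable, "t_equal_var", unname(tt$statistic),
                   tt$p.value,
                   length(x), mean(x), stats::sd(x),
                   length(y), mean(y), stats::sd(y))
}

#' Pooled t-test from printed summary statistics
#'
#' Same pooled-variance t statistic as [t_test_two_sample()], computed from
#' group means, SDs and sizes; this recomputes a published comparison from
#' its printed summaries.
#'
#' @param m1,sd1,n1 Mean, SD and size of group 1.
#' @param m2,sd2,n2 Mean, SD and size of group 2.
#' @param variable Label recorded in the result.
#' @return One-row group-comparison `data.frame`.
#' @export
t_test_from_summary <- function(m1, sd1, n1, m2, sd2, n2, variable = "") {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 per group")
  if (sd1 < 0 || sd2 < 0 || (sd1 == 0 && sd2 == 0))
    stop("invalid SDs")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  tstat <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
  p <- 2 * stats::pt(-abs(tstat), df)
  group_comparison(variable, "t_equal_var", tstat, p,
                   n1, m1, sd1, n2, m2, sd2)
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the usual convention: the sum of hypergeometric
#' probabilities of all tables no more probable than the observed one.
#'
#' @param table 2x2 matrix of nonnegative integer counts with positive
#'   margins.
#' @param variable Label recorded in the result.
#' @return One-row group-comparison `data.frame`; `statistic` is the
#'   conditional odds-ratio estimate.
#' @export
fisher_exact_2x2 <- function(table, variable = "") {
  table <- as.matrix(table)
  if (!all(dim(table) == 2) || any(table < 0) || any(table != round(table)))
    stop("need a 2x2 table of nonnegative integer counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero margin")
  ft <- stats::fisher.test(table)
  group_comparison(variable, "fisher", unname(ft$estimate),
                   min(ft$p.value, 1))
}

#' Early clinical improvement rule
#'
#' A subject improves when the NIHSS score drops by at least
#' `min_improvement` points (default 4) from baseline to the 3-h
#' assessment.
#'
#' @param nihss_baseline,nihss_3h Integer NIHSS scores in \[0, 42\].
#' @param min_improvement Improvement threshold in points (inclusive).
#' @return Logical.
#' @export
clinical_improvement <- function(nihss_baseline, nihss_3h,
                                 min_improvement = 4) {
  if (any(nihss_baseline < 0 | nihss_baseline > 42) ||
      any(nihss_3h < 0 | nihss_3h > 42))
    stop("NIHSS scores must lie in [0, 42]")
  (nihss_baseline - nihss_3h) >= min_improvement
}

#' Default test plan for the imaging comparison table
#'
#' Baseline and follow-up parameter levels are compared with the rank-sum
#' test; the 0 h - 3 h changes of the relative perfusion parameters with
#' the pooled-variance t-test; ADC changes, not being relative perfusion
#' parameters, stay with the rank-sum test.
#'
#' @return `data.frame` with columns `variable` and `test` covering the
#'   3 ROIs x 4 parameters x 3 rows (baseline, follow-up, delta).
#' @export
default_test_plan <- function() {
  g <- expand.grid(roi = feature_rois, param = feature_params,
                   tp = c("baseline", "followup", "delta"),
                   stringsAsFactors = FALSE)
  g$variable <- paste(g$roi, g$param, g$tp, sep = "_")
  g$test <- ifelse(g$tp == "delta" & g$param != "adc",
                   "t_equal_var", "rank_sum")
  g[, c("variable", "test")]
}

#' Two-arm comparison table over cohort features
#'
#' Runs the planned test for every variable and assembles the study-style
#' comparison table (one row per ROI x parameter x timerow). No
#' multiplicity adjustment is applied; the output carries
#' `attr(, "multiplicity") = "none"`.
#'
#' @param features Cohort features `data.frame` with an `arm` column
#'   (`"theophylline"` vs `"control"`) and the planned variables.
#' @param test_plan `data.frame` mapping `variable` to `test`
#'   (`"rank_sum"` or `"t_equal_var"`); default [default_test_plan()].
#' @return `data.frame` of group comparisons, one row per variable.
#' @export
build_group_table <- function(features, test_plan = default_test_plan()) {
  missing_vars <- setdiff(test_plan$variable, names(features))
  if (length(missing_vars))
    stop("unknown variable(s) in test plan: ",
         paste(missing_vars, collapse = ", "))
  theo <- features$arm == "theophylline"
  ctrl <- features$arm == "control"
  rows <- lapply(seq_len(nrow(test_plan)), function(i) {
    v <- test_plan$variable[i]
    x <- features[[v]][theo]
    y <- features[[v]][ctrl]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    # a degenerate variable (constant in both arms, e.g. an identically
    # zero delta) carries no evidence of a group difference
    if (length(x) && length(y) && stats::var(c(x, y)) == 0) {
      return(group_comparison(v, test_plan$test[i], NA, 1,
                              length(x), mean(x), stats::sd(x),
                              length(y), mean(y), stats::sd(y)))
    }
    switch(test_plan$test[i],
           rank_sum = rank_sum_test(x, y, variable = v),
           t_equal_var = t_test_two_sample(x, y, variable = v),
           stop("unknown test: ", test_plan$test[i]))
  })
  out <- do.call(rbind, rows)
  attr(out, "multiplicity") <- "none"
  attr(out, "alpha") <- 0.05
  out
}
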
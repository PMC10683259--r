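# Cohort descriptive statistics: group percentages, chi-squared tests
# for categorical variables, one-way ANOVA for continuous variables, and
# sex-specific internal z-scores.

#' Pearson chi-squared test on a contingency table
#'
#' Plain Pearson chi-squared without continuity correction (the
#' convention needed to reproduce the published table p-values),
#' df = (r-1)(c-1), upper-tail p.
#'
#' @param counts non-negative integer matrix, at least 2x2.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_squared_from_table <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop_methrisk("contingency table must be at least 2x2",
                  "methrisk_degenerate_table")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_methrisk("counts must be non-negative integers",
                  "methrisk_invalid_input")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop_methrisk("zero row or column margin: degenerate table",
                  "methrisk_degenerate_table")
  }
  ct <- stats::chisq.test(counts, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value), expected = ct$expected)
}

#' One-way ANOVA F-test
#'
#' Classic one-way analysis of variance for a continuous variable over
#' groups; missing values are dropped pairwise.
#'
#' @param values numeric vector.
#' @param groups grouping vector (coerced to factor).
#' @return List with `F`, `df1`, `df2`, `p_value`.
#' @export
anova_one_way <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  tab <- table(groups)
  if (length(tab) < 2L || any(tab < 2L)) {
    stop_methrisk("need >= 2 groups with >= 2 observations each",
                  "methrisk_invalid_input")
  }
  fit <- stats::anova(stats::aov(values ~ groups))
  msw <- fit[2L, "Mean Sq"]
  if (msw == 0 && fit[1L, "Mean Sq"] == 0) {
    stop_methrisk("zero variance within and between groups: F undefined",
                  "methrisk_degenerate_anova")
  }
  list(F = fit[1L, "F value"], df1 = fit[1L, "Df"], df2 = fit[2L, "Df"],
       p_value = fit[1L, "Pr(>F)"])
}

#' Internal z-scores within strata
#'
#' Standardizes an outcome within groups (typically by sex):
#' `(x - group mean) / group SD`, with the sample SD (denominator
#' n - 1). Missing values stay missing and are excluded from the group
#' moments.
#'
#' @param table a [cohort_table()].
#' @param outcome name of the numeric outcome column.
#' @param by character vector of grouping column names (default
#'   `"sex"`).
#' @param suffix suffix for the new column name.
#' @return The cohort table with an added `<outcome><suffix>` column.
#' @export
internal_z_scores <- function(table, outcome, by = "sex", suffix = "_z") {
  if (!outcome %in% names(table)) {
    stop_methrisk(paste0("unknown outcome: ", outcome),
                  "methrisk_invalid_input")
  }
  x <- table[[outcome]]
  stopifnot(is.numeric(x))
  g <- interaction(as.data.frame(table)[, by, drop = FALSE], drop = TRUE)
  z <- rep(NA_real_, length(x))
  for (lev in levels(g)) {
    idx <- which(g == lev & !is.na(x))
    if (length(idx) < 2L) {
      stop_methrisk(paste0("group '", lev, "' has fewer than 2 observations"),
                    "methrisk_invalid_input")
    }
    s <- stats::sd(x[idx])
    if (s == 0) {
      stop_methrisk(paste0("group '", lev, "' has zero SD"),
                    "methrisk_zero_sd")
    }
    z[idx] <- (x[idx] - mean(x[idx])) / s
  }
  vt <- variable_types(table)
  df <- as.data.frame(table)
  df[[paste0(outcome, suffix)]] <- z
  vt[paste0(outcome, suffix)] <- "continuous"
  cohort_table(df, vt)
}

#' Percentages of a contingency table along an axis
#'
#' @param counts contingency matrix.
#' @param axis `"column"` (percent of column total, the published-table
#'   convention), `"row"`, or `"total"`.
#' @param digits decimals for reporting (default 1).
#' @return Matrix of percentages rounded to `digits`.
#' @export
group_percentages <- function(counts, axis = c("column", "row", "total"),
                              digits = 1L) {
  axis <- match.arg(axis)
  counts <- as.matrix(counts)
  denom <- switch(axis,
                  column = rep(colSums(counts), each = nrow(counts)),
                  row = rep(rowSums(counts), times = ncol(counts)),
                  total = sum(counts))
  if (any(denom == 0)) {
    stop_methrisk("zero margin: percentages undefined",
                  "methrisk_degenerate_table")
  }
  round(100 * counts / denom, digits)
}

#' Format a p-value in published-table style
#'
#' Three decimals; values below 0.001 are reported as `"< 0.001"`.
#'
#' @param p numeric p-value(s).
#' @return Character vector.
#' @export
format_p_value <- function(p) {
  ifelse(p < 0.001, "< 0.001", formatC(round(p, 3L), format = "g"))
}

#' Descriptive-statistics report for a cohort table
#'
#' For each requested variable, tests its association with a grouping
#' variable: chi-squared (no continuity correction) for categoricals,
#' one-way ANOVA for continuous variables, mirroring the published
#' cohort-description table.
#'
#' @param table a [cohort_table()].
#' @param group name of the grouping (column) variable.
#' @param variables variables to describe (default: all others).
#' @return data.frame with variable, kind, test, statistic, df and
#'   p-value (raw and formatted).
#' @export
descriptives_report <- function(table, group, variables = NULL) {
  vt <- variable_types(table)
  stopifnot(group %in% names(vt), vt[[group]] == "categorical")
  variables <- variables %||% setdiff(names(vt), group)
  rows <- lapply(variables, function(v) {
    if (vt[[v]] == "categorical") {
      tab <- base::table(table[[v]], table[[group]])
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      res <- chi_squared_from_table(tab)
      data.frame(variable = v, kind = "categorical", test = "chi-squared",
                 statistic = res$statistic, df = res$df,
                 p_value = res$p_value, stringsAsFactors = FALSE)
    } else {
      res <- anova_one_way(table[[v]], table[[group]])
      data.frame(variable = v, kind = "continuous", test = "anova",
                 statistic = res$F, df = res$df1, p_value = res$p_value,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_formatted <- format_p_value(out$p_value)
  out
}
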
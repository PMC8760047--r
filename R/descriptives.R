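#' Welch two-sample t test from summary statistics
#'
#' Unequal-variance t test computed from per-group means, SDs and sizes:
#' `t = (mean2 - mean1) / sqrt(sd1^2/n1 + sd2^2/n2)`, with
#' Welch-Satterthwaite degrees of freedom. Group 1 is conventionally the
#' control group, so a positive t means a larger mean in group 2.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return Object of class `group_comparison`: list with `statistic`, `df`
#'   (fractional), `df_integer`, `p`, and the per-group summaries.
#' @examples
#' welch_t(35.47, 12.63, 1601, 41.72, 12.66, 1134)
#' @export
welch_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop_config("need n >= 2 per group")
  if (sd1 <= 0 || sd2 <= 0) stop_config("group SDs must be positive")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  t <- (mean2 - mean1) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  structure(list(test = "welch_t", statistic = t, df = df,
                 df_integer = round(df), p = p,
                 groups = data.frame(group = c(1, 2), n = c(n1, n2),
                                     mean = c(mean1, mean2), sd = c(sd1, sd2))),
            class = "group_comparison")
}

#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson chi-square, `sum((O - E)^2 / E)`, with no continuity
#' correction and `df = (r - 1)(c - 1)`.
#'
#' @param counts Matrix of observed counts (rows = groups, columns =
#'   categories), all expected counts must be positive.
#' @return Object of class `group_comparison` with `statistic`, `df`, `p`
#'   and the observed table.
#' @examples
#' pearson_chi2(rbind(control = c(1014, 437, 150), case = c(470, 399, 265)))
#' @export
pearson_chi2 <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_config("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop_config("zero marginal total in contingency table")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(list(test = "pearson_chi2",
                 statistic = unname(ct$statistic), df = unname(ct$parameter),
                 df_integer = unname(ct$parameter), p = ct$p.value,
                 observed = counts),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  if (x$test == "welch_t")
    cat(sprintf("Welch t(%.1f) = %.3f, p = %.4g\n", x$df, x$statistic, x$p))
  else
    cat(sprintf("Pearson chi-square(%d) = %.3f, p = %.4g\n",
                x$df_integer, x$statistic, x$p))
  invisible(x)
}

#' Categorize BMI values into normal / overweight / obese
#'
#' WHO cut-points with inclusive lower bounds: normal weight below 25
#' (underweight folded in), overweight in \[25, 30), obese at 30 and above.
#'
#' @param bmi Numeric vector of positive BMI values (kg/m^2).
#' @return Named integer vector of counts `(normal, overweight, obese)`.
#' @examples
#' bmi_categorize(c(24.9, 25.0, 29.9, 30.0))
#' @export
bmi_categorize <- function(bmi) {
  if (any(is.na(bmi)) || any(bmi <= 0))
    stop_config("BMI values must be positive and non-missing")
  cats <- cut(bmi, breaks = c(0, 25, 30, Inf), right = FALSE,
              labels = c("normal", "overweight", "obese"))
  table(cats) |> c()
}

#' Table-1 style group descriptives for a cohort
#'
#' Subject-level demographic comparisons between controls and cases: Welch
#' t tests for age and BMI, Pearson chi-square tests for the three BMI
#' weight categories and for sex.
#'
#' @param data Cohort table.
#' @return Data.frame with one row per variable: per-group summaries,
#'   the test statistic, degrees of freedom, and p-value.
#' @export
cohort_table1 <- function(data) {
  s <- data[!duplicated(data$subject_id),
            c("subject_id", "group", "age", "sex", "bmi")]
  ctrl <- s[s$group == "control", ]
  case <- s[s$group == "case", ]
  if (nrow(ctrl) < 2 || nrow(case) < 2)
    stop_config("both groups must be present")
  num_row <- function(var) {
    w <- welch_t(mean(ctrl[[var]]), sd(ctrl[[var]]), nrow(ctrl),
                 mean(case[[var]]), sd(case[[var]]), nrow(case))
    data.frame(variable = var,
               control = sprintf("%.2f (%.2f)", mean(ctrl[[var]]), sd(ctrl[[var]])),
               case = sprintf("%.2f (%.2f)", mean(case[[var]]), sd(case[[var]])),
               test = "Welch t", statistic = w$statistic, df = w$df, p = w$p)
  }
  wc <- rbind(control = bmi_categorize(ctrl$bmi), case = bmi_categorize(case$bmi))
  cw <- pearson_chi2(wc)
  sx <- rbind(control = c(sum(ctrl$sex == "female"), sum(ctrl$sex == "male")),
              case = c(sum(case$sex == "female"), sum(case$sex == "male")))
  cs <- pearson_chi2(sx)
  fmt_counts <- function(x) paste(sprintf("%d (%.2f)", x, 100 * x / sum(x)),
                                  collapse = " / ")
  rbind(
    data.frame(variable = "n", control = as.character(nrow(ctrl)),
               case = as.character(nrow(case)), test = "", statistic = NA,
               df = NA, p = NA),
    num_row("age"),
    num_row("bmi"),
    data.frame(variable = "weight_category",
               control = fmt_counts(wc["control", ]),
               case = fmt_counts(wc["case", ]), test = "chi-square",
               statistic = cw$statistic, df = cw$df, p = cw$p),
    data.frame(variable = "sex_female",
               control = sprintf("%d (%.2f)", sx["control", 1],
                                 100 * sx["control", 1] / sum(sx["control", ])),
               case = sprintf("%d (%.2f)", sx["case", 1],
                              100 * sx["case", 1] / sum(sx["case", ])),
               test = "chi-square", statistic = cs$statistic, df = cs$df,
               p = cs$p))
}
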
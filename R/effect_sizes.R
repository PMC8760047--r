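#' Cohen's d from a mixed-model group coefficient
#'
#' Converts a group-contrast coefficient and its standard error into a
#' standardized mean difference using the t statistic, the denominator
#' degrees of freedom and the (possibly unequal) group sizes:
#' `d = t * (n1 + n2) / (sqrt(DF) * sqrt(n1 * n2))`. The 95% CI uses the
#' large-sample standard error
#' `SE_d = sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))`.
#'
#' @param b Coefficient (outcome units per group contrast).
#' @param se_b Standard error of `b` (> 0).
#' @param df Denominator degrees of freedom (>= 1).
#' @param n1,n2 Group sizes (>= 2). Required: d is undefined without them.
#' @param conf_level Confidence level, default 0.95.
#' @return Object of class `effect_size`: list with `kind = "cohens_d"`,
#'   `value`, `ci_low`, `ci_high`, and the `source` quantities.
#' @examples
#' cohens_d(b = 34.21, se_b = 10.35, df = 2274, n1 = 1601, n2 = 1134)
#' @export
cohens_d <- function(b, se_b, df, n1, n2, conf_level = 0.95) {
  if (missing(n1) || missing(n2) || is.na(n1) || is.na(n2))
    stop_config("group sizes n1 and n2 are required for Cohen's d")
  stopifnot(se_b > 0, df >= 1, n1 >= 2, n2 >= 2)
  t <- b / se_b
  d <- t * (n1 + n2) / (sqrt(df) * sqrt(n1 * n2))
  se_d <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  structure(list(kind = "cohens_d", value = d,
                 ci_low = d - z * se_d, ci_high = d + z * se_d,
                 source = list(b = b, se_b = se_b, df = df, n1 = n1, n2 = n2)),
            class = "effect_size")
}

#' Partial correlation from a mixed-model coefficient
#'
#' Recovers the partial correlation between a continuous predictor and the
#' outcome from the coefficient's t statistic: `r = t / sqrt(t^2 + DF)`.
#' The CI uses the Fisher z transform with effective sample size `DF + 2`.
#'
#' @inheritParams cohens_d
#' @return Object of class `effect_size` with `kind = "partial_r"`.
#' @examples
#' partial_r(b = 61.22, se_b = 17.61, df = 2414)
#' @export
partial_r <- function(b, se_b, df, conf_level = 0.95) {
  stopifnot(se_b > 0, df >= 1)
  t <- b / se_b
  r <- t / sqrt(t^2 + df)
  z <- qnorm(1 - (1 - conf_level) / 2)
  n_eff <- df + 2
  fz <- atanh(r)
  half <- z / sqrt(n_eff - 3)
  structure(list(kind = "partial_r", value = r,
                 ci_low = tanh(fz - half), ci_high = tanh(fz + half),
                 source = list(b = b, se_b = se_b, df = df)),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  lbl <- c(cohens_d = "Cohen's d", partial_r = "partial r")[[x$kind]]
  cat(sprintf("%s = %.3f [%.3f, %.3f]\n", lbl, x$value, x$ci_low, x$ci_high))
  invisible(x)
}

# Report-style rounding: round half away from zero at `digits` decimals,
# matching how results tables are conventionally printed.
round_half_up <- function(x, digits = 2) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
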
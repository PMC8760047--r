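base_covariates <- function() c("age", "sex", "hemisphere", "icv")

family_terms <- function(family) {
  switch(family,
         group_only = c("group", base_covariates()),
         bmi_only = c("bmi", base_covariates()),
         joint = c("group", "bmi", base_covariates()),
         stop_config("unknown model family: ", family))
}

#' Run the per-region model families
#'
#' For every region present in the cohort, fits the three model families —
#' group-only, BMI-only, and joint — each with the covariates age, sex,
#' hemisphere and ICV and the standard random structure (site and subject
#' intercepts). Extracts the group and BMI coefficients, applies
#' Benjamini-Hochberg FDR adjustment *within each model family x term*
#' across the regions, and attaches effect sizes: Cohen's d (with the
#' fit's group sizes) for group contrasts, partial r for BMI associations.
#'
#' Regions whose fit fails are reported with a warning and skipped; other
#' regions are unaffected. Regions named in [roi_labels()] but absent from
#' the table trigger a warning.
#'
#' @param data Cohort table.
#' @param families Subset of `c("group_only", "bmi_only", "joint")`.
#' @param alpha Significance level for the FDR-adjusted flags.
#' @param df_method Passed to [fit_lmm()].
#' @return Data.frame of class `roi_results`, one row per region x family x
#'   term: `b`, `se`, `df`, `p_raw`, `p_fdr`, effect size with CI,
#'   `significant`. The fitted models are attached as attribute `fits`.
#' @export
run_model_families <- function(data,
                               families = c("group_only", "bmi_only", "joint"),
                               alpha = 0.05,
                               df_method = c("containment", "residual")) {
  df_method <- match.arg(df_method)
  families <- match.arg(families, several.ok = TRUE)
  rois <- intersect(roi_labels(), unique(data$roi))
  missing_rois <- setdiff(roi_labels(), rois)
  if (length(missing_rois))
    warning("regions absent from the table and skipped: ",
            paste(missing_rois, collapse = ", "))
  if (!length(rois)) stop_config("no known regions in the table")

  rows <- list()
  fits <- list()
  for (fam in families) {
    for (roi in rois) {
      fit <- tryCatch(
        fit_lmm(data, model_spec(roi, family_terms(fam)), df_method = df_method),
        error = function(e) e)
      if (inherits(fit, "error")) {
        warning("fit failed for ", roi, " (", fam, "): ",
                conditionMessage(fit))
        next
      }
      fits[[paste(fam, roi, sep = ".")]] <- fit
      for (term in intersect(c("group", "bmi"), family_terms(fam)[1:2])) {
        cname <- if (term == "group") "groupcase" else "bmi"
        cf <- fit$coefficients[fit$coefficients$term == cname, ]
        rows[[length(rows) + 1L]] <- data.frame(
          roi = roi, family = fam, term = term, b = cf$b, se = cf$se,
          df = cf$df, p_raw = cf$p, n1 = fit$n1, n2 = fit$n2,
          converged = fit$converged)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- ave(out$p_raw, out$family, out$term,
                   FUN = function(p) p.adjust(p, method = "BH"))
  es <- lapply(seq_len(nrow(out)), function(i) {
    r <- out[i, ]
    if (r$term == "group") cohens_d(r$b, r$se, r$df, r$n1, r$n2)
    else partial_r(r$b, r$se, r$df)
  })
  out$es_kind <- vapply(es, function(e) e$kind, "")
  out$es <- vapply(es, function(e) e$value, 1)
  out$es_low <- vapply(es, function(e) e$ci_low, 1)
  out$es_high <- vapply(es, function(e) e$ci_high, 1)
  out$significant <- out$p_fdr < alpha
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "alpha") <- alpha
  class(out) <- c("roi_results", "data.frame")
  out
}

#' Screen group x BMI and BMI x site interactions
#'
#' Per region, two screens: (1) a fixed group x BMI interaction added to
#' the joint model, tested through its coefficient; (2) a BMI x site
#' interaction, tested as a likelihood-ratio test of a random (mean-centred)
#' BMI slope by site against the intercept-only structure, both fitted with
#' ML. Because the null value of a variance parameter lies on the boundary,
#' the LRT p-value uses the equal-mixture `0.5 chi^2_0 + 0.5 chi^2_1`
#' reference. Each screen is FDR-adjusted across regions; an interaction is
#' retained (flag `retained`) only when FDR-significant.
#'
#' @param data Cohort table.
#' @param alpha Significance level applied to FDR-adjusted p-values.
#' @return Data.frame with columns `roi`, `screen`, `statistic`, `p_raw`,
#'   `p_fdr`, `retained`.
#' @export
screen_interactions <- function(data, alpha = 0.05) {
  rois <- intersect(roi_labels(), unique(data$roi))
  rows <- list()
  for (roi in rois) {
    spec_int <- model_spec(roi, c("group", "bmi", base_covariates(), "group:bmi"))
    fit <- fit_lmm(data, spec_int)
    cf <- fit$coefficients[grepl(":", fit$coefficients$term), ]
    rows[[length(rows) + 1L]] <- data.frame(
      roi = roi, screen = "group_x_bmi", statistic = cf$t, p_raw = cf$p)

    d <- model_frame(data, model_spec(roi))
    d$bmi_c <- d$bmi - mean(d$bmi)
    base <- lme4::lmer(
      volume ~ group + bmi + age + sex + hemisphere + icv +
        (1 | site_id) + (1 | subject_id),
      data = d, REML = FALSE,
      control = lme4::lmerControl(check.scaleX = "ignore",
                                  check.conv.singular = "ignore",
                                  calc.derivs = FALSE))
    slope <- lme4::lmer(
      volume ~ group + bmi + age + sex + hemisphere + icv +
        (1 | site_id) + (0 + bmi_c | site_id) + (1 | subject_id),
      data = d, REML = FALSE,
      control = lme4::lmerControl(check.scaleX = "ignore",
                                  check.conv.singular = "ignore",
                                  calc.derivs = FALSE))
    lrt <- max(0, 2 * (as.numeric(logLik(slope)) - as.numeric(logLik(base))))
    p <- if (lrt <= 0) 1 else 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      roi = roi, screen = "bmi_x_site", statistic = lrt, p_raw = p)
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- ave(out$p_raw, out$screen,
                   FUN = function(p) p.adjust(p, method = "BH"))
  out$retained <- out$p_fdr < alpha
  rownames(out) <- NULL
  out
}

#' Between-group variance comparison per region
#'
#' Compares case and control variances of the subject-level bilateral mean
#' volumes: `100 * |var_case - var_control| / var_control` per region.
#'
#' @param data Cohort table with both groups present.
#' @return Data.frame with columns `roi`, `var_control`, `var_case`,
#'   `pct_difference`.
#' @export
variance_comparison <- function(data) {
  rois <- intersect(roi_labels(), unique(data$roi))
  out <- lapply(rois, function(roi) {
    sm <- subject_means(data, roi)
    v0 <- var(sm$volume[sm$group == "control"])
    v1 <- var(sm$volume[sm$group == "case"])
    if (is.na(v0) || is.na(v1) ||
        sum(sm$group == "control") < 2 || sum(sm$group == "case") < 2)
      stop_config("both groups must be present with >= 2 subjects (", roi, ")")
    data.frame(roi = roi, var_control = v0, var_case = v1,
               pct_difference = 100 * abs(v1 - v0) / v0)
  })
  do.call(rbind, out)
}

#' Post-hoc medication models on the case subset
#'
#' Explores, among cases only, the interplay of the number of medication
#' classes (0-3), BMI, lithium and lateral-ventricular volume:
#'
#' 1. BMI ~ medication count (+ age, sex; site random intercept);
#' 2. ventricles ~ medication count (+ standard covariates and random
#'    structure);
#' 3. ventricles ~ medication count + BMI, with a medication x BMI
#'    interaction screen and the VIF of the two predictors;
#' 4. ventricles ~ lithium.
#'
#' Marginal R-squared is reported for the ventricle models (BMI-only,
#' medication-only, joint) to quantify how much unique variance the two
#' predictors carry.
#'
#' @param data Cohort table; must contain `medication_count` and `lithium`
#'   columns (otherwise the analysis is skipped with a message).
#' @param alpha Significance level.
#' @return List of class `medication_posthoc` with elements `bmi_model`
#'   (coefficient row for medication count), `ventricle_models`
#'   (coefficient rows), `interaction` (medication x BMI), `vif`,
#'   `r_squared` (named: bmi, medications, joint), or `NULL` (invisibly)
#'   when medication fields are absent.
#' @export
posthoc_medication_models <- function(data, alpha = 0.05) {
  if (!all(c("medication_count", "lithium") %in% names(data))) {
    message("medication fields absent; post-hoc medication models skipped")
    return(invisible(NULL))
  }
  cases <- data[data$group == "case", , drop = FALSE]
  if (!nrow(cases)) stop_config("no cases in the table")

  # (1) BMI ~ medications, subject level with a site random intercept
  s <- cases[!duplicated(cases$subject_id), , drop = FALSE]
  s$sexf <- sex01(s$sex)
  mfit <- lme4::lmer(bmi ~ medication_count + age + sexf + (1 | site_id),
                     data = s, REML = TRUE,
                     control = lme4::lmerControl(check.conv.singular = "ignore"))
  b <- lme4::fixef(mfit); se <- sqrt(diag(as.matrix(vcov(mfit))))
  dfm <- nrow(s) - length(b) - nlevels(factor(s$site_id))
  bmi_row <- data.frame(model = "bmi~medications", term = "medication_count",
                        b = b[["medication_count"]],
                        se = se[["medication_count"]],
                        df = dfm,
                        t = b[["medication_count"]] / se[["medication_count"]])
  bmi_row$p <- 2 * pt(-abs(bmi_row$t), bmi_row$df)

  vent_coef <- function(fit, terms, model) {
    cf <- fit$coefficients[fit$coefficients$term %in% terms, ]
    cbind(model = model, cf)
  }
  covs <- base_covariates()
  f_med <- fit_lmm(cases, model_spec("lateral_ventricles",
                                     c("medication_count", covs)))
  f_bmi <- fit_lmm(cases, model_spec("lateral_ventricles", c("bmi", covs)))
  f_joint <- fit_lmm(cases, model_spec("lateral_ventricles",
                                       c("medication_count", "bmi", covs)))
  f_int <- fit_lmm(cases, model_spec("lateral_ventricles",
                                     c("medication_count", "bmi", covs,
                                       "medication_count:bmi")))
  f_li <- fit_lmm(cases, model_spec("lateral_ventricles", c("lithium", covs)))

  vent <- rbind(
    vent_coef(f_med, "medication_count", "ventricles~medications"),
    vent_coef(f_joint, c("medication_count", "bmi"), "ventricles~medications+bmi"),
    vent_coef(f_li, "lithium", "ventricles~lithium"))
  int_row <- f_int$coefficients[grepl(":", f_int$coefficients$term), ]

  vif <- compute_vif(cases, model_spec("lateral_ventricles",
                                       c("medication_count", "bmi", covs)))
  r2 <- c(bmi = r_squared(f_bmi)$marginal,
          medications = r_squared(f_med)$marginal,
          joint = r_squared(f_joint)$marginal)
  structure(list(bmi_model = bmi_row, ventricle_models = vent,
                 interaction = int_row, vif = vif, r_squared = r2,
                 alpha = alpha),
            class = "medication_posthoc")
}
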
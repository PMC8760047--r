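#' Specify a per-region mixed model
#'
#' Describes one linear mixed model on a cohort table: the outcome region,
#' the ordered fixed terms, and the random-effect structure. The default
#' random structure — a site intercept plus a subject intercept with
#' hemisphere-level residuals — captures between-site variability,
#' between-subject variability, and within-subject hemisphere differences.
#'
#' @param roi Region label (see [roi_labels()]).
#' @param fixed_terms Character vector of fixed predictors, a subset of
#'   `group`, `bmi`, `age`, `sex`, `hemisphere`, `icv`, `group:bmi`,
#'   `medication_count`, `lithium`, `medication_count:bmi`. Duplicates are
#'   an error.
#' @param site_intercept,subject_intercept Logical; include a random
#'   intercept for site / for subject. The subject intercept together with
#'   the hemisphere-level residual is the "hemisphere within subject"
#'   structure (each subject contributes one residual per hemisphere).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(roi,
                       fixed_terms = c("group", "bmi", "age", "sex",
                                       "hemisphere", "icv"),
                       site_intercept = TRUE,
                       subject_intercept = TRUE) {
  allowed <- c("group", "bmi", "age", "sex", "hemisphere", "icv",
               "group:bmi", "medication_count", "lithium",
               "medication_count:bmi")
  bad <- setdiff(fixed_terms, allowed)
  if (length(bad))
    stop_config("unknown fixed term(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(fixed_terms))
    stop_config("duplicated fixed terms are not allowed")
  structure(list(roi = roi, fixed_terms = fixed_terms,
                 site_intercept = isTRUE(site_intercept),
                 subject_intercept = isTRUE(subject_intercept)),
            class = "model_spec")
}

# Prepare the per-region modelling frame: filter, listwise-delete missing
# volumes, set factor codings (control/male/left reference levels).
model_frame <- function(data, spec) {
  d <- data[data$roi == spec$roi & !is.na(data$volume), , drop = FALSE]
  if (nrow(d) == 0L)
    stop_config("no observations for region '", spec$roi, "'")
  d$group <- factor(d$group, levels = c("control", "case"))
  d$sex <- factor(d$sex, levels = c("male", "female"))
  d$hemisphere <- factor(d$hemisphere, levels = c("left", "right"))
  d$site_id <- factor(d$site_id)
  d$subject_id <- factor(d$subject_id)
  d
}

fixed_formula <- function(spec, response = "volume") {
  as.formula(paste(response, "~", paste(spec$fixed_terms, collapse = " + ")))
}

#' Fit a per-region linear mixed model
#'
#' Fits `volume ~ fixed terms + (1 | site) + (1 | subject)` on the
#' hemisphere-level rows of one region, after listwise deletion of missing
#' volumes. Estimation is REML by default (ML for likelihood comparisons)
#' via `lme4`. Coefficient p-values use a containment-style denominator
#' degrees of freedom, `DF = n_obs - n_fixed_coefficients - n_grouping_levels`
#' (the number of levels of every random grouping factor in the model); the
#' `residual` alternative uses `n_obs - n_fixed_coefficients`.
#'
#' Data in which the outcome is an exact linear function of the fixed design
#' (zero residual variance) are detected and fitted by ordinary least
#' squares with all variance components fixed at zero; such fits are marked
#' `degenerate`. Convergence problems are flagged on the returned object,
#' never silently absorbed.
#'
#' @param data Cohort table (see [read_cohort()] or [generate_cohort()]).
#' @param spec A [model_spec()].
#' @param method `"REML"` (default) or `"ML"`.
#' @param df_method `"containment"` (default) or `"residual"`.
#' @return An object of class `lmm_fit`: a list with `coefficients` (term,
#'   b, se, df, t, p), `varcomp` (site, subject, residual variances), `aic`,
#'   `loglik`, `n_obs`, `n_subjects`, `n1`/`n2` (group sizes when `group` is
#'   a term), `converged`, `singular`, `degenerate`, and the fitted model.
#' @examples
#' cohort <- generate_cohort(generator_config(n_sites = 5,
#'   subjects_per_site = 40, qc_missing_rate = 0, seed = 11))
#' fit <- fit_lmm(cohort, model_spec("hippocampus"))
#' fit$coefficients
#' @export
fit_lmm <- function(data, spec, method = c("REML", "ML"),
                    df_method = c("containment", "residual")) {
  method <- match.arg(method)
  df_method <- match.arg(df_method)
  d <- model_frame(data, spec)
  if (spec$site_intercept && nlevels(droplevels(d$site_id)) < 2)
    stop_config("need >= 2 sites to fit a site random intercept")
  ff <- fixed_formula(spec)
  X <- model.matrix(ff, d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop_config("singular fixed-effect design for region '", spec$roi,
                "' (aliased terms: ",
                paste(colnames(X)[qrX$pivot[-seq_len(qrX$rank)]],
                      collapse = ", "), ")")
  y <- d$volume
  one_hemi <- sum(tapply(d$hemisphere, d$subject_id, function(h) length(h) == 1L),
                  na.rm = TRUE)
  if (one_hemi > 0)
    message(one_hemi, " subject(s) contribute a single hemisphere for '",
            spec$roi, "'")

  n_obs <- length(y)
  p <- ncol(X)
  groups_used <- character(0)
  if (spec$site_intercept) groups_used <- c(groups_used, "site_id")
  if (spec$subject_intercept) groups_used <- c(groups_used, "subject_id")
  n_levels <- sum(vapply(groups_used,
                         function(g) nlevels(droplevels(d[[g]])), 1L))
  df_den <- switch(df_method,
                   containment = n_obs - p - n_levels,
                   residual = n_obs - p)
  df_den <- max(df_den, 1)

  ols <- qr.coef(qrX, y)
  resid_sd <- sd(y - as.vector(X %*% ols))
  degenerate <- isTRUE(resid_sd < 1e-10 * max(1, sd(y)))

  if (degenerate || length(groups_used) == 0L) {
    lf <- lm(ff, data = d)
    sm <- suppressWarnings(summary(lf))  # exact fits trip lm's perfect-fit warning
    b <- coef(lf)
    se <- sm$coefficients[, "Std. Error"]
    vcomp <- c(site = 0, subject = 0,
               residual = if (degenerate) 0 else sm$sigma^2)
    fit_obj <- lf
    conv <- TRUE; singular <- FALSE
    aic <- if (degenerate) NA_real_ else AIC(lf)
    ll <- if (degenerate) NA_real_ else as.numeric(logLik(lf))
  } else {
    re <- paste(sprintf("(1 | %s)", groups_used), collapse = " + ")
    full <- as.formula(paste(deparse1(ff), "+", re))
    conv <- TRUE
    fit_obj <- withCallingHandlers(
      lme4::lmer(full, data = d, REML = (method == "REML"),
                 control = lme4::lmerControl(check.scaleX = "ignore",
                                             check.conv.singular = "ignore")),
      warning = function(w) {
        if (grepl("converge|unidentifiable|Hessian", conditionMessage(w)))
          conv <<- FALSE
        invokeRestart("muffleWarning")
      })
    b <- lme4::fixef(fit_obj)
    se <- sqrt(diag(as.matrix(vcov(fit_obj))))
    vcdf <- as.data.frame(lme4::VarCorr(fit_obj))
    getv <- function(g) {
      v <- vcdf$vcov[vcdf$grp == g]
      if (length(v)) sum(v) else 0
    }
    vcomp <- c(site = getv("site_id"), subject = getv("subject_id"),
               residual = getv("Residual"))
    singular <- lme4::isSingular(fit_obj)
    aic <- AIC(fit_obj)
    ll <- as.numeric(logLik(fit_obj))
  }

  tval <- b / se
  pval <- 2 * pt(-abs(tval), df_den)
  coefs <- data.frame(term = names(b), b = unname(b), se = unname(se),
                      df = df_den, t = unname(tval), p = unname(pval),
                      row.names = NULL)

  n_subjects <- nlevels(droplevels(d$subject_id))
  n1 <- n2 <- NA_integer_
  if ("group" %in% spec$fixed_terms) {
    gs <- table(d$group[!duplicated(d$subject_id)])
    n1 <- as.integer(gs[["control"]]); n2 <- as.integer(gs[["case"]])
  }
  structure(list(coefficients = coefs, varcomp = vcomp, aic = aic,
                 loglik = ll, n_obs = n_obs, n_subjects = n_subjects,
                 n1 = n1, n2 = n2, converged = conv, singular = singular,
                 degenerate = degenerate, method = method,
                 df_method = df_method, spec = spec,
                 fixed_pred = as.vector(X %*% b), model = fit_obj),
            class = "lmm_fit")
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Linear mixed model: %s (%s, df = %s)\n", x$spec$roi,
              x$method, x$df_method))
  cat(sprintf("  n_obs = %d, n_subjects = %d%s\n", x$n_obs, x$n_subjects,
              if (!is.na(x$n1)) sprintf(" (control %d / case %d)", x$n1, x$n2)
              else ""))
  print(x$coefficients, digits = 4)
  cat("Variance components (site / subject / residual):",
      paste(signif(x$varcomp, 4), collapse = " / "), "\n")
  if (!x$converged) cat("WARNING: model did not converge cleanly\n")
  if (x$degenerate) cat("NOTE: exact-fit (zero residual) data; OLS solution\n")
  invisible(x)
}

#' Variance inflation factors over the subject-level design
#'
#' Computes `VIF_j = 1 / (1 - R^2_j)` for each fixed predictor, where
#' `R^2_j` comes from regressing predictor j on the remaining predictors
#' over the subject-level design (one row per subject; the within-subject
#' `hemisphere` term, if present, is excluded). Perfectly collinear
#' predictors are reported as `Inf` rather than raising an error.
#'
#' @param data Cohort table.
#' @param spec A [model_spec()] with at least two fixed terms.
#' @return Named numeric vector of VIFs, one per design column.
#' @export
compute_vif <- function(data, spec) {
  terms <- setdiff(spec$fixed_terms, "hemisphere")
  if (length(terms) < 2)
    stop_config("VIF needs at least two subject-level fixed terms")
  d <- model_frame(data, spec)
  d <- d[!duplicated(d$subject_id), , drop = FALSE]
  X <- model.matrix(as.formula(paste("~", paste(terms, collapse = " + "))), d)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  ones <- rep(1, nrow(X))
  vapply(seq_len(ncol(X)), function(j) {
    yj <- X[, j]
    Z <- cbind(ones, X[, -j, drop = FALSE])
    fit <- lm.fit(Z, yj)
    tss <- sum((yj - mean(yj))^2)
    if (tss == 0) return(NA_real_)
    r2 <- 1 - sum(fit$residuals^2) / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> setNames(colnames(X))
}

#' Compare random-effect structures by AIC
#'
#' Refits a shared fixed-effect specification under several random-effect
#' structures with maximum likelihood (required for AIC comparability) and
#' returns the structures ranked by AIC with differences to the best.
#'
#' @param data Cohort table.
#' @param spec_list List of [model_spec()]s sharing `roi` and `fixed_terms`
#'   but differing in random structure.
#' @return Data.frame with columns `structure`, `aic`, `delta_aic`,
#'   `loglik`, ordered by AIC.
#' @export
compare_random_structures <- function(data, spec_list) {
  stopifnot(length(spec_list) >= 2)
  key <- function(s) paste(s$roi, paste(s$fixed_terms, collapse = "+"))
  if (length(unique(vapply(spec_list, key, ""))) != 1L)
    stop_config("specs must share the region and fixed terms")
  lab <- vapply(spec_list, function(s) {
    parts <- c(if (s$site_intercept) "site", if (s$subject_intercept) "subject")
    if (length(parts)) paste(parts, collapse = "+") else "none"
  }, "")
  fits <- lapply(spec_list, function(s) fit_lmm(data, s, method = "ML"))
  out <- data.frame(structure = lab,
                    aic = vapply(fits, function(f) f$aic, 1),
                    loglik = vapply(fits, function(f) f$loglik, 1))
  out <- out[order(out$aic), , drop = FALSE]
  out$delta_aic <- out$aic - out$aic[1]
  rownames(out) <- NULL
  out
}

#' Marginal and conditional R-squared of a mixed-model fit
#'
#' Variance-decomposition R-squared: the marginal value is the variance of
#' the fixed-effect predictions over the total (fixed + random-intercept +
#' residual) variance; the conditional value adds the random-effect
#' variance to the numerator.
#'
#' @param fit An [fit_lmm()] result.
#' @return List with `marginal` and `conditional` proportions (both `NA`
#'   with a warning when the total variance is zero).
#' @export
r_squared <- function(fit) {
  stopifnot(inherits(fit, "lmm_fit"))
  vf <- var(fit$fixed_pred)
  vre <- sum(fit$varcomp[c("site", "subject")])
  vres <- fit$varcomp[["residual"]]
  total <- vf + vre + vres
  if (total <= 0) {
    warning("total variance is zero; R-squared undefined")
    return(list(marginal = NA_real_, conditional = NA_real_))
  }
  list(marginal = vf / total, conditional = (vf + vre) / total)
}
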
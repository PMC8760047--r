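# Subject-level frame used by the mediation models: bilateral mean volume
# plus 0/1 codings and the site factor.
mediation_frame <- function(data, roi) {
  sm <- subject_means(data, roi)
  if (nrow(sm) == 0L) stop_config("no usable subjects for region '", roi, "'")
  sm$g <- group01(sm$group)
  sm$sexf <- sex01(sm$sex)
  sm$site_id <- factor(sm$site_id)
  sm
}

# OLS with coefficient standard errors; X assumed full rank.
ols_fit <- function(X, y) {
  qx <- qr(X)
  b <- qr.coef(qx, y)
  res <- y - as.vector(X %*% b)
  dfree <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / max(dfree, 1)
  se <- sqrt(diag(chol2inv(qx$qr) * sigma2))
  list(coef = b, se = setNames(se, colnames(X)), df = dfree)
}

# Design matrices for the collapsed (subject-level, site-as-fixed) engine.
# Constant columns other than the intercept are dropped so that degenerate
# configurations (e.g. a constant ICV) stay estimable; the group and BMI
# columns themselves must survive.
collapsed_designs <- function(sm) {
  Z <- model.matrix(~ site_id, sm)
  build <- function(cols) {
    X <- cbind(`(Intercept)` = 1, do.call(cbind, cols),
               Z[, -1, drop = FALSE])
    keep <- c(TRUE, vapply(2:ncol(X), function(j) var(X[, j]) > 0, TRUE))
    X[, keep, drop = FALSE]
  }
  Xm <- build(list(g = sm$g, age = sm$age, sexf = sm$sexf))
  Xo <- build(list(g = sm$g, bmi = sm$bmi, age = sm$age, sexf = sm$sexf,
                   icv = sm$icv))
  Xt <- build(list(g = sm$g, age = sm$age, sexf = sm$sexf, icv = sm$icv))
  if (!all(c("g") %in% colnames(Xm)) || !all(c("g", "bmi") %in% colnames(Xo)))
    stop_config("group or BMI carries no variance; mediation undefined")
  list(Xm = Xm, Xo = Xo, Xt = Xt)
}

# Mediator model BMI ~ group + age + sex (+ site): returns path a.
mediator_fit <- function(data, roi, engine = c("full", "collapsed")) {
  engine <- match.arg(engine)
  sm <- mediation_frame(data, roi)
  if (engine == "collapsed" || nlevels(sm$site_id) < 2) {
    ds <- collapsed_designs(sm)
    f <- ols_fit(ds$Xm, sm$bmi)
    a <- f$coef[["g"]]; se <- f$se[["g"]]; dfree <- f$df
  } else {
    fit <- lme4::lmer(bmi ~ g + age + sexf + (1 | site_id), data = sm,
                      REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
    b <- lme4::fixef(fit)
    se_all <- sqrt(diag(as.matrix(vcov(fit))))
    a <- b[["g"]]; se <- se_all[[which(names(b) == "g")]]
    dfree <- nrow(sm) - length(b) - nlevels(sm$site_id)
  }
  t <- a / se
  list(a = a, se = se, df = dfree, t = t, p = 2 * pt(-abs(t), max(dfree, 1)))
}

#' Point estimates of the mediation paths for one region
#'
#' Estimates the four mediation quantities for group -> BMI -> volume:
#' path a (group coefficient of the mediator model
#' `BMI ~ group + age + sex` with a site intercept), path b and the direct
#' effect c' (BMI and group coefficients of the joint outcome model), and
#' the total effect c (group coefficient of the outcome model without BMI).
#' The `full` engine fits hemisphere-level mixed models via [fit_lmm()];
#' the `collapsed` engine works on subject-level bilateral means with site
#' as a fixed factor, which is fast enough for bootstrap resampling at
#' scale.
#'
#' @param data Cohort table.
#' @param roi Region label.
#' @param engine `"full"` (mixed-model refits) or `"collapsed"`.
#' @return List with `a`, `se_a`, `b_path`, `se_b_path`, `c`, `se_c`,
#'   `c_prime`, `se_c_prime`, `indirect_hat` (= a * b_path), `n_subjects`,
#'   `engine`.
#' @export
mediation_paths <- function(data, roi = "lateral_ventricles",
                            engine = c("full", "collapsed")) {
  engine <- match.arg(engine)
  sm <- mediation_frame(data, roi)
  med <- mediator_fit(data, roi, engine)
  if (engine == "collapsed") {
    ds <- collapsed_designs(sm)
    fj <- ols_fit(ds$Xo, sm$volume)
    ft <- ols_fit(ds$Xt, sm$volume)
    out <- list(a = med$a, se_a = med$se,
                b_path = fj$coef[["bmi"]], se_b_path = fj$se[["bmi"]],
                c = ft$coef[["g"]], se_c = ft$se[["g"]],
                c_prime = fj$coef[["g"]], se_c_prime = fj$se[["g"]],
                converged = TRUE)
  } else {
    covs <- base_covariates()
    fj <- fit_lmm(data, model_spec(roi, c("group", "bmi", covs)))
    ft <- fit_lmm(data, model_spec(roi, c("group", covs)))
    pick <- function(f, term) f$coefficients[f$coefficients$term == term, ]
    out <- list(a = med$a, se_a = med$se,
                b_path = pick(fj, "bmi")$b, se_b_path = pick(fj, "bmi")$se,
                c = pick(ft, "groupcase")$b, se_c = pick(ft, "groupcase")$se,
                c_prime = pick(fj, "groupcase")$b,
                se_c_prime = pick(fj, "groupcase")$se,
                converged = fj$converged && ft$converged)
  }
  out$indirect_hat <- out$a * out$b_path
  out$n_subjects <- nrow(sm)
  out$engine <- engine
  out
}

#' Check the four mediation gate criteria for a region
#'
#' Mediation of the group effect through BMI is attempted only when:
#' (1) group is an FDR-significant predictor of the region's volume
#' (group-only family); (2) group significantly predicts the mediator BMI;
#' (3) BMI is FDR-significant in the joint model; and (4) the group
#' coefficient is attenuated in the joint model relative to the group-only
#' model (`|b_joint| < |b_group_only|`). Criterion 4 fails under
#' suppression, where adjusting for BMI *increases* the group difference.
#'
#' @param data Cohort table (used for the mediator model).
#' @param results A [run_model_families()] result containing the
#'   `group_only` and `joint` families.
#' @param roi Region label.
#' @param alpha Significance level; defaults to the level stored in
#'   `results`.
#' @param engine Mediator-model engine, see [mediation_paths()].
#' @return List with `roi`, the four named booleans in `criteria`, and
#'   `pass` (all four true).
#' @export
check_mediation_criteria <- function(data, results, roi, alpha = NULL,
                                     engine = c("full", "collapsed")) {
  stopifnot(inherits(results, "roi_results"))
  engine <- match.arg(engine)
  if (is.null(alpha)) alpha <- attr(results, "alpha")
  if (is.null(alpha)) alpha <- 0.05
  g0 <- results[results$roi == roi & results$family == "group_only" &
                  results$term == "group", ]
  jg <- results[results$roi == roi & results$family == "joint" &
                  results$term == "group", ]
  jb <- results[results$roi == roi & results$family == "joint" &
                  results$term == "bmi", ]
  if (nrow(g0) != 1L || nrow(jg) != 1L || nrow(jb) != 1L)
    stop_config("results must contain group_only and joint families for '",
                roi, "'")
  med <- mediator_fit(data, roi, engine)
  criteria <- c(group_predicts_volume = isTRUE(g0$significant),
                group_predicts_bmi = med$p < alpha,
                mediator_significant_in_joint = isTRUE(jb$significant),
                group_coefficient_attenuated = abs(jg$b) < abs(g0$b))
  list(roi = roi, criteria = criteria, pass = all(criteria),
       mediator_p = med$p, alpha = alpha)
}

#' Sobel test of an indirect effect
#'
#' Normal-approximation z test of the product of the two path
#' coefficients: `Z = a * b / sqrt(a^2 * se_b^2 + b^2 * se_a^2)`, two-sided
#' p from the standard normal.
#'
#' @param a,se_a Mediator-path coefficient and its standard error.
#' @param b,se_b Outcome-path coefficient and its standard error.
#' @return List with `z` and `p`.
#' @examples
#' sobel_test(a = 2, se_a = 0.2, b = 3, se_b = 0.5)
#' @export
sobel_test <- function(a, se_a, b, se_b) {
  if (se_a <= 0 || se_b <= 0) stop_config("standard errors must be positive")
  denom <- sqrt(a^2 * se_b^2 + b^2 * se_a^2)
  z <- if (denom == 0) 0 else a * b / denom
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Proportion of a total effect carried by the indirect path
#'
#' `100 * |indirect| / |c|`, in percent. Magnitudes are used so the value
#' is invariant to the sign convention of the group coding; when the
#' indirect and total effects disagree in sign, the mediation is flagged as
#' inconsistent (the "proportion" is not interpretable as a share).
#'
#' @param indirect Indirect effect (a * b).
#' @param c_total Total effect (group coefficient without the mediator).
#' @return List with `percent` and `inconsistent` (`percent` is `NA` with a
#'   warning when `c_total` is zero).
#' @examples
#' proportion_mediated(112.97, 613.65)
#' @export
proportion_mediated <- function(indirect, c_total) {
  if (c_total == 0) {
    warning("total effect is zero; proportion mediated undefined")
    return(list(percent = NA_real_, inconsistent = NA))
  }
  list(percent = 100 * abs(indirect) / abs(c_total),
       inconsistent = sign(indirect) != sign(c_total))
}

#' Bootstrap mediation analysis of group differences through BMI
#'
#' Nonparametric bootstrap of the indirect effect a * b for one region.
#' The resampling unit is the participant (both hemispheres travel
#' together), stratified by site with the original per-site counts, so no
#' replicate loses a site. Each replicate refits the mediator model
#' (`BMI ~ group + age + sex`, site intercept) and the outcome models
#' (`volume ~ group [+ BMI] + age + sex + ICV + hemisphere`, standard
#' random structure); the percentile 2.5/97.5 interval of the replicate
#' `a_i * b_i` values is the reported CI, and the proportion mediated
#' carries its own percentile interval. A Sobel test on the point
#' estimates is included as a cross-check.
#'
#' Replicates that fail to converge are dropped and counted; more than 5%
#' dropped aborts the analysis. One master seed spawns per-replicate
#' sub-seeds, so enlarging `n_boot` extends, rather than reshuffles, the
#' earlier replicates, and identical seeds give identical intervals.
#'
#' @param data Cohort table.
#' @param roi Region label.
#' @param n_boot Number of bootstrap replicates (default 5000).
#' @param seed Master RNG seed.
#' @param engine `"full"` refits the hemisphere-level mixed models every
#'   replicate; `"collapsed"` refits subject-level bilateral-mean models
#'   with site as a fixed factor (orders of magnitude faster, near
#'   identical paths; see the methods vignette).
#' @param gate Optional [check_mediation_criteria()] result; if it failed
#'   and `force` is not set, the analysis stops.
#' @param force Skip the gate and the minimum-size check.
#' @param conf_level Confidence level of the percentile intervals.
#' @return Object of class `bdbmi_mediation`: paths with SEs, the
#'   bootstrap indirect distribution (`boot_indirect`), `ci`, proportion
#'   mediated with CI and inconsistency flag, Sobel z/p, counts and seed.
#' @export
bootstrap_mediation <- function(data, roi = "lateral_ventricles",
                                n_boot = 5000, seed = 1L,
                                engine = c("full", "collapsed"),
                                gate = NULL, force = FALSE,
                                conf_level = 0.95) {
  engine <- match.arg(engine)
  if (!is.null(gate) && !isTRUE(gate$pass) && !force)
    stop_config("mediation gate not passed for '", roi,
                "' (failed: ",
                paste(names(gate$criteria)[!gate$criteria], collapse = ", "),
                "); use force = TRUE to override")
  sm <- mediation_frame(data, roi)
  if (nrow(sm) < 200 && !force)
    stop_config("fewer than 200 usable subjects; use force = TRUE to override")

  point <- mediation_paths(data, roi, engine)
  rseeds <- spawn_seeds(seed, n_boot)
  site_rows <- split(seq_len(nrow(sm)), sm$site_id)

  a_i <- b_i <- c_i <- rep(NA_real_, n_boot)
  if (engine == "collapsed") {
    ds <- collapsed_designs(sm)
    ja <- match("g", colnames(ds$Xm))
    jb <- match("bmi", colnames(ds$Xo))
    jc <- match("g", colnames(ds$Xt))
    bmi <- sm$bmi; vol <- sm$volume
    for (i in seq_len(n_boot)) {
      idx <- with_seed(rseeds[i], unlist(lapply(site_rows, function(rr)
        rr[sample.int(length(rr), length(rr), replace = TRUE)]),
        use.names = FALSE))
      fa <- .lm.fit(ds$Xm[idx, , drop = FALSE], bmi[idx])
      fb <- .lm.fit(ds$Xo[idx, , drop = FALSE], vol[idx])
      fc <- .lm.fit(ds$Xt[idx, , drop = FALSE], vol[idx])
      a_i[i] <- fa$coefficients[ja]
      b_i[i] <- fb$coefficients[jb]
      c_i[i] <- fc$coefficients[jc]
    }
  } else {
    droi <- data[data$roi == roi & !is.na(data$volume), , drop = FALSE]
    rows_by_subject <- split(seq_len(nrow(droi)), droi$subject_id)
    rows_by_subject <- rows_by_subject[lengths(rows_by_subject) > 0]
    subj_of <- sm$subject_id
    for (i in seq_len(n_boot)) {
      idx <- with_seed(rseeds[i], unlist(lapply(site_rows, function(rr)
        rr[sample.int(length(rr), length(rr), replace = TRUE)]),
        use.names = FALSE))
      picked <- subj_of[idx]
      reps <- lapply(seq_along(picked), function(k) {
        rr <- droi[rows_by_subject[[picked[k]]], , drop = FALSE]
        rr$subject_id <- sprintf("B%06d", k)
        rr
      })
      db <- do.call(rbind, reps)
      est <- tryCatch({
        p <- suppressMessages(mediation_paths(db, roi, engine = "full"))
        if (!isTRUE(p$converged)) rep(NA_real_, 3) else c(p$a, p$b_path, p$c)
      }, error = function(e) rep(NA_real_, 3))
      a_i[i] <- est[1]; b_i[i] <- est[2]; c_i[i] <- est[3]
    }
  }

  ok <- complete.cases(a_i, b_i, c_i)
  n_dropped <- sum(!ok)
  if (n_dropped > 0.05 * n_boot)
    stop_config(n_dropped, " of ", n_boot,
                " bootstrap replicates failed (> 5%); aborting")
  ind <- (a_i * b_i)[ok]
  prop <- (100 * abs(a_i * b_i) / abs(c_i))[ok]
  qs <- c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2)
  ci <- unname(quantile(ind, qs))
  prop_ci <- unname(quantile(prop, qs))
  pm <- proportion_mediated(point$indirect_hat, point$c)
  sob <- sobel_test(point$a, point$se_a, point$b_path, point$se_b_path)

  structure(c(point,
              list(boot_indirect = ind, ci = ci, conf_level = conf_level,
                   significant = !(ci[1] <= 0 && 0 <= ci[2]),
                   prop_mediated = pm$percent, prop_ci = prop_ci,
                   inconsistent = pm$inconsistent,
                   sobel_z = sob$z, sobel_p = sob$p,
                   n_boot = n_boot, n_dropped = n_dropped,
                   seed = seed, roi = roi)),
            class = "bdbmi_mediation")
}

#' @export
print.bdbmi_mediation <- function(x, ...) {
  cat(sprintf("Bootstrap mediation (%s, %s engine, %d replicates%s)\n",
              x$roi, x$engine, x$n_boot,
              if (x$n_dropped) sprintf(", %d dropped", x$n_dropped) else ""))
  cat(sprintf("  a (group -> BMI)      = %8.3f (SE %.3f)\n", x$a, x$se_a))
  cat(sprintf("  b (BMI -> volume)     = %8.3f (SE %.3f)\n", x$b_path, x$se_b_path))
  cat(sprintf("  c (total effect)      = %8.3f (SE %.3f)\n", x$c, x$se_c))
  cat(sprintf("  c' (direct effect)    = %8.3f (SE %.3f)\n", x$c_prime, x$se_c_prime))
  cat(sprintf("  indirect (a*b)        = %8.3f, %g%% CI [%.3f, %.3f]%s\n",
              x$indirect_hat, 100 * x$conf_level, x$ci[1], x$ci[2],
              if (x$significant) " *" else ""))
  cat(sprintf("  proportion mediated   = %.2f%% [%.2f%%, %.2f%%]%s\n",
              x$prop_mediated, x$prop_ci[1], x$prop_ci[2],
              if (isTRUE(x$inconsistent)) " (inconsistent)" else ""))
  cat(sprintf("  Sobel Z = %.3f, p = %.4g\n", x$sobel_z, x$sobel_p))
  invisible(x)
}
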
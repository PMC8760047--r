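test_that("noise-free data are recovered exactly and flagged degenerate", {
  cfg <- one_roi_config(roi = "caudate", intercept = 3000, b_group = -50,
                        b_bmi = -1.7, b_age = -6, b_sex = -25, b_icv = 0.002,
                        b_hemisphere = -20, seed = 5)
  cohort <- generate_cohort(cfg)
  fit <- fit_lmm(cohort, model_spec("caudate"))
  expect_true(fit$degenerate)
  truth <- c(groupcase = -50, bmi = -1.7, age = -6, sexfemale = -25,
             hemisphereright = -20, icv = 0.002)
  for (term in names(truth)) {
    b <- fit$coefficients$b[fit$coefficients$term == term]
    expect_lt(abs(b - truth[[term]]) / abs(truth[[term]]), 1e-6)
  }
  expect_equal(r_squared(fit)$marginal, 1)
})

test_that("with zero variance components the mixed fit equals closed-form OLS", {
  cfg <- one_roi_config(roi = "pallidum", intercept = 1800, b_group = -30,
                        b_bmi = -2, b_age = -4, b_icv = 0.001,
                        sd_residual = 150, n_sites = 6, subjects_per_site = 60,
                        seed = 1)
  cohort <- generate_cohort(cfg)
  fit <- fit_lmm(cohort, model_spec("pallidum"))
  d <- cohort
  d$case <- as.numeric(d$group == "case")
  d$female <- as.numeric(d$sex == "female")
  d$right <- as.numeric(d$hemisphere == "right")
  X <- cbind(1, d$case, d$bmi, d$age, d$female, d$right, d$icv)
  beta <- solve(t(X) %*% X, t(X) %*% d$volume)[, 1]
  got <- fit$coefficients$b
  expect_lt(max(abs(got - beta) / pmax(abs(beta), 1e-8)), 1e-6)
})

test_that("the BMI slope is recovered within 2 SE at realistic scale", {
  cfg <- one_roi_config(b_bmi = 60, intercept = 6000, sd_site = 800,
                        sd_subject = 3000, sd_residual = 900,
                        n_sites = 10, subjects_per_site = 200, seed = 14)
  cohort <- generate_cohort(cfg)
  fit <- fit_lmm(cohort, model_spec("lateral_ventricles"))
  cf <- fit$coefficients[fit$coefficients$term == "bmi", ]
  expect_lt(abs(cf$b - 60), 2 * cf$se)
  expect_gt(cf$df, 1)
  expect_equal(cf$t, cf$b / cf$se)
})

test_that("centering a covariate changes only the intercept", {
  cfg <- one_roi_config(roi = "thalamus", intercept = 7000, b_group = -90,
                        b_bmi = 5, b_age = -15, sd_site = 300,
                        sd_subject = 600, sd_residual = 200,
                        n_sites = 6, subjects_per_site = 50, seed = 31)
  cohort <- generate_cohort(cfg)
  f1 <- fit_lmm(cohort, model_spec("thalamus"))
  cohort$age <- cohort$age - mean(cohort$age)
  f2 <- fit_lmm(cohort, model_spec("thalamus"))
  slopes <- f1$coefficients$term != "(Intercept)"
  scale <- max(abs(f1$coefficients$b[slopes]))
  expect_lt(max(abs(f1$coefficients$b[slopes] - f2$coefficients$b[slopes])) /
              scale, 1e-8)
  expect_lt(max(abs(f1$coefficients$se[slopes] - f2$coefficients$se[slopes])) /
              scale, 1e-8)
})

test_that("VIFs are near one for independent predictors and infinite under collinearity", {
  # covariates made independent of group so the design is orthogonal
  cfg <- one_roi_config(sd_residual = 100, n_sites = 8,
                        subjects_per_site = 250, seed = 3, path_a = 0,
                        bmi_model = list(control = c(mean = 25, sd = 4),
                                         case = c(mean = 25, sd = 4),
                                         path_a = NULL),
                        age_model = list(control = c(mean = 38, sd = 12),
                                         case = c(mean = 38, sd = 12)))
  cohort <- generate_cohort(cfg)
  vif <- compute_vif(cohort, model_spec("lateral_ventricles",
                                        c("group", "bmi", "age", "sex", "icv")))
  expect_true(all(abs(vif[c("bmi", "age", "icv")] - 1) < 0.05))
  dup <- cohort
  dup$bmi <- dup$age
  vif2 <- compute_vif(dup, model_spec("lateral_ventricles",
                                      c("bmi", "age", "sex", "icv")))
  expect_true(is.infinite(vif2[["bmi"]]) || is.infinite(vif2[["age"]]))
})

test_that("a one-sex cohort with a sex term is a design error", {
  cfg <- one_roi_config(sd_residual = 50, seed = 2,
                        sex_model = c(control = 1, case = 1))
  cohort <- generate_cohort(cfg)
  expect_error(fit_lmm(cohort, model_spec("lateral_ventricles")), "singular")
})

test_that("AIC comparison prefers the richer structure when site variance exists", {
  specs <- list(model_spec("amygdala", site_intercept = FALSE),
                model_spec("amygdala", site_intercept = TRUE))
  wins <- 0L
  n_sim <- 100L
  for (i in seq_len(n_sim)) {
    cfg <- one_roi_config(roi = "amygdala", intercept = 1700, sd_site = 120,
                          sd_subject = 120, sd_residual = 60,
                          n_sites = 8, subjects_per_site = 15, seed = 1000 + i)
    tab <- compare_random_structures(generate_cohort(cfg), specs)
    if (tab$structure[1] == "site+subject") wins <- wins + 1L
  }
  expect_gte(wins / n_sim, 0.90)

  # identical specs give identical AIC
  cohort <- generate_cohort(one_roi_config(roi = "amygdala", sd_site = 120,
                                           sd_subject = 120, sd_residual = 60,
                                           seed = 77))
  tab <- compare_random_structures(cohort, list(model_spec("amygdala"),
                                                model_spec("amygdala")))
  expect_equal(tab$aic[1], tab$aic[2])
})

test_that("without site variance the structures are near-equivalent by AIC", {
  deltas <- vapply(1:20, function(i) {
    cfg <- one_roi_config(roi = "amygdala", intercept = 1700, sd_site = 0,
                          sd_subject = 120, sd_residual = 60,
                          n_sites = 8, subjects_per_site = 15, seed = 2000 + i)
    tab <- compare_random_structures(
      generate_cohort(cfg),
      list(model_spec("amygdala", site_intercept = FALSE),
           model_spec("amygdala", site_intercept = TRUE)))
    tab$delta_aic[2]
  }, 1)
  expect_lte(median(deltas), 4)
})

test_that("marginal and conditional R-squared follow the built-in variance shares", {
  # fixed : random : residual variance = 1 : 1 : 2
  cfg <- one_roi_config(b_bmi = 1, intercept = 100,
                        sd_site = sqrt(0.5), sd_subject = sqrt(0.5),
                        sd_residual = sqrt(2),
                        n_sites = 10, subjects_per_site = 300, seed = 12,
                        bmi_model = list(control = c(mean = 25, sd = 1),
                                         case = c(mean = 25, sd = 1),
                                         path_a = NULL))
  cohort <- generate_cohort(cfg)
  fit <- fit_lmm(cohort, model_spec("lateral_ventricles", "bmi"))
  r2 <- r_squared(fit)
  expect_lt(abs(r2$marginal - 0.25), 0.05)
  expect_lt(abs(r2$conditional - 0.50), 0.05)

  # all-zero effects give marginal ~ 0
  cfg0 <- one_roi_config(sd_subject = 100, sd_residual = 100, seed = 4)
  f0 <- fit_lmm(generate_cohort(cfg0), model_spec("lateral_ventricles"))
  expect_lt(r_squared(f0)$marginal, 0.02)

  # zero total variance is reported as undefined
  cfgc <- one_roi_config(intercept = 500, seed = 6)
  fc <- fit_lmm(generate_cohort(cfgc), model_spec("lateral_ventricles", "bmi"))
  expect_warning(r2c <- r_squared(fc), "undefined")
  expect_true(is.na(r2c$marginal))
})
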
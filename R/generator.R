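#' Default fixed-effect coefficients for the eight subcortical regions
#'
#' One row per region: baseline intercept plus fixed-effect coefficients for
#' diagnostic group (case vs control, positive = larger volume in cases),
#' BMI (mm^3 per kg/m^2), age (mm^3 per year), sex (female vs male),
#' intracranial volume (mm^3 per mm^3 ICV) and hemisphere (right vs left).
#'
#' The group and BMI coefficients default to the *direct* (jointly adjusted)
#' effects reported by a 17-site mega-analysis of 2735 individuals, expressed
#' in case-positive coding; the total group effect a generated cohort carries
#' is then `b_group + path_a * b_bmi` (see [generator_config()]). Age, sex,
#' hemisphere, and ICV coefficients are plausible magnitudes for adult
#' subcortical anatomy (ventricular expansion with age, approximate
#' proportionality to ICV, small lateral asymmetries); they only shape the
#' covariate structure and are not themselves study estimates.
#'
#' @return A data.frame with columns `roi`, `intercept`, `b_group`, `b_bmi`,
#'   `b_age`, `b_sex`, `b_icv`, `b_hemisphere`.
#' @export
default_roi_effects <- function() {
  typical <- c(lateral_ventricles = 7700, accumbens = 600, amygdala = 1700,
               hippocampus = 4100, pallidum = 1800, putamen = 5100,
               caudate = 3700, thalamus = 7600)
  b_group <- c(500.84, -5.38, -29.70, -46.59, -29.76, 2.26, -53.62, -94.66)
  b_bmi   <- c(51.54, 0.33, 3.55, 0.95, -2.02, 3.43, -1.71, 5.35)
  b_age   <- c(60, -1.5, -2, -8, -4, -12, -6, -15)
  b_sex   <- c(-40, -4, -10, -25, -12, -35, -25, -50)
  b_icv   <- typical / 1.5e6
  b_hemisphere <- c(-150, -5, 30, 40, -10, -50, -20, -30)
  # Choose intercepts so that volumes land near `typical` at the default
  # covariate means (age 38, 58% female, BMI 25.4, ICV 1.5e6, 41% cases).
  intercept <- typical - b_icv * 1.5e6 - b_age * 38.1 - b_bmi * 25.4 -
    b_sex * 0.585 - b_group * 0.415
  data.frame(roi = names(typical), intercept = unname(intercept),
             b_group = b_group, b_bmi = b_bmi, b_age = b_age, b_sex = b_sex,
             b_icv = unname(b_icv), b_hemisphere = b_hemisphere,
             row.names = NULL)
}

#' Default variance components for the synthetic cohort
#'
#' Standard deviations (mm^3) of the site random intercept, the subject
#' random intercept, and the hemisphere-level residual, per region. Subject
#' SDs are scaled so that group-contrast standard errors at n = 2735 match
#' the magnitudes seen in large multi-site subcortical studies; site and
#' residual SDs are set to roughly 35% and 30% of the subject SD, giving a
#' site ICC of about 10%.
#'
#' @return A data.frame with columns `roi`, `sd_site`, `sd_subject`,
#'   `sd_residual`.
#' @export
default_variance_components <- function() {
  sd_subject <- c(lateral_ventricles = 3500, accumbens = 110, amygdala = 200,
                  hippocampus = 410, pallidum = 245, putamen = 470,
                  caudate = 440, thalamus = 690)
  data.frame(roi = names(sd_subject),
             sd_site = unname(0.35 * sd_subject),
             sd_subject = unname(sd_subject),
             sd_residual = unname(0.30 * sd_subject),
             row.names = NULL)
}

#' Configuration for the synthetic multi-site cohort generator
#'
#' Bundles and validates every parameter of [generate_cohort()]. Defaults
#' emulate the structure of a 17-site case-control study of 2735 individuals
#' (1134 cases with bipolar disorder, 1601 controls): per-group age and sex
#' distributions, a BMI shift of +2.37 kg/m^2 in cases (the `path_a`
#' coefficient of the built-in mediation path), region-level fixed effects,
#' and site/subject/residual variance components.
#'
#' @param n_sites Number of data-collection sites.
#' @param subjects_per_site Subjects per site; a scalar or a length-`n_sites`
#'   vector.
#' @param case_fraction Proportion of subjects in the case group. The split
#'   is applied deterministically per site (rounded), not resampled.
#' @param age_model List with `control` and `case` entries, each
#'   `c(mean =, sd =)` in years. Draws are truncated to \[18, 90\].
#' @param sex_model Named vector `c(control =, case =)` of probabilities of
#'   being female.
#' @param bmi_model List with `control = c(mean =, sd =)`,
#'   `case = c(mean =, sd =)` in kg/m^2, and `path_a`: if non-`NULL`, the
#'   case BMI mean is `control mean + path_a`, making the group-to-BMI path
#'   of the mediation model explicit (the default, 2.37, equals the
#'   case-control difference of the per-group means, so the two
#'   parameterisations coincide). BMI is floored at 14 kg/m^2.
#' @param icv_model `c(mean =, sd =)` of intracranial volume in mm^3
#'   (independent of group).
#' @param roi_effects Data.frame as returned by [default_roi_effects()];
#'   may contain any subset of the canonical regions.
#' @param variance_components Data.frame as returned by
#'   [default_variance_components()]; must cover every region in
#'   `roi_effects`.
#' @param qc_missing_rate Probability that a subject x region measurement is
#'   withheld (both hemispheres jointly), emulating region-level quality
#'   control failure.
#' @param medication_model Optional list enabling medication fields for
#'   cases: `probs` (length-4 probabilities of 0-3 medication classes),
#'   `bmi_per_class` and `ventricle_per_class` (additive effects per class
#'   on BMI and on lateral-ventricle volume), `latent_sd`,
#'   `bmi_per_latent`, `ventricle_per_latent` (a shared latent driver
#'   loading on medication count, BMI and ventricular volume), `lithium_p`
#'   and `lithium_ventricle` (probability of lithium treatment and its
#'   ventricular effect). `NULL` (default) omits medication columns.
#' @param seed Integer RNG seed; identical seed and configuration give an
#'   identical cohort.
#'
#' @return An object of class `generator_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
generator_config <- function(n_sites = 17,
                             subjects_per_site = 161,
                             case_fraction = 1134 / 2735,
                             age_model = list(control = c(mean = 35.47, sd = 12.63),
                                              case = c(mean = 41.72, sd = 12.66)),
                             sex_model = c(control = 0.5721, case = 0.6032),
                             bmi_model = list(control = c(mean = 24.43, sd = 4.12),
                                              case = c(mean = 26.80, sd = 5.22),
                                              path_a = 2.37),
                             icv_model = c(mean = 1.5e6, sd = 1.5e5),
                             roi_effects = default_roi_effects(),
                             variance_components = default_variance_components(),
                             qc_missing_rate = 0.10,
                             medication_model = NULL,
                             seed = 1L) {
  if (length(n_sites) != 1L || n_sites < 1 || n_sites != round(n_sites))
    stop_config("`n_sites` must be a positive integer")
  if (!length(subjects_per_site) %in% c(1L, n_sites))
    stop_config("`subjects_per_site` must be scalar or length n_sites")
  if (any(subjects_per_site < 1) || any(subjects_per_site != round(subjects_per_site)))
    stop_config("`subjects_per_site` must be positive integers")
  if (case_fraction < 0 || case_fraction > 1)
    stop_config("`case_fraction` must be in [0, 1]")
  if (qc_missing_rate < 0 || qc_missing_rate > 1)
    stop_config("`qc_missing_rate` must be in [0, 1]")
  for (g in c("control", "case")) {
    if (age_model[[g]][["sd"]] < 0 || bmi_model[[g]][["sd"]] < 0)
      stop_config("negative standard deviation in age_model or bmi_model")
  }
  if (icv_model[["sd"]] < 0) stop_config("negative `icv_model` sd")
  need <- c("roi", "intercept", "b_group", "b_bmi", "b_age", "b_sex",
            "b_icv", "b_hemisphere")
  if (!all(need %in% names(roi_effects)))
    stop_config("`roi_effects` missing columns: ",
                paste(setdiff(need, names(roi_effects)), collapse = ", "))
  if (anyDuplicated(roi_effects$roi))
    stop_config("duplicated region in `roi_effects`")
  unknown <- setdiff(roi_effects$roi, roi_labels())
  if (length(unknown))
    stop_config("unknown region label(s): ", paste(unknown, collapse = ", "))
  if (!all(roi_effects$roi %in% variance_components$roi))
    stop_config("`variance_components` must cover every region in `roi_effects`")
  sds <- variance_components[, c("sd_site", "sd_subject", "sd_residual")]
  if (any(unlist(sds) < 0)) stop_config("variance components must be >= 0")
  if (!is.null(medication_model)) {
    mm <- medication_model
    defaults <- list(probs = c(0.25, 0.40, 0.25, 0.10), bmi_per_class = 0,
                     ventricle_per_class = 0, latent_sd = 0,
                     bmi_per_latent = 0, ventricle_per_latent = 0,
                     lithium_p = 0.455, lithium_ventricle = 0)
    medication_model <- utils::modifyList(defaults, mm)
    p <- medication_model$probs
    if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop_config("`medication_model$probs` must be 4 probabilities summing to 1")
  }
  structure(list(n_sites = as.integer(n_sites),
                 subjects_per_site = as.integer(rep_len(subjects_per_site, n_sites)),
                 case_fraction = case_fraction, age_model = age_model,
                 sex_model = sex_model, bmi_model = bmi_model,
                 icv_model = icv_model, roi_effects = roi_effects,
                 variance_components = variance_components,
                 qc_missing_rate = qc_missing_rate,
                 medication_model = medication_model,
                 seed = as.integer(seed)),
            class = "generator_config")
}

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Generate a synthetic multi-site cohort
#'
#' Simulates a long-format cohort table (one row per subject x hemisphere x
#' region) from a [generator_config()]. Volumes follow
#' `intercept + b_group*case + b_bmi*bmi + b_age*age + b_sex*female +
#' b_icv*icv + b_hemisphere*right + u_site + u_subject + e`, with
#' independent normal site intercepts, subject intercepts and
#' hemisphere-level residuals. BMI is drawn per group with the configured
#' case shift (the mediation path a), so a cohort carries a built-in
#' indirect effect of `path_a * b_bmi` per region, recorded in the
#' `provenance` attribute. Region-level QC missingness withholds both
#' hemispheres of a subject x region jointly (volume set to `NA`).
#'
#' The generator is deterministic: the same configuration (including seed)
#' yields an identical table. The caller's RNG state is left untouched.
#'
#' @param config A [generator_config()].
#' @return A data.frame (cohort table) with columns `subject_id`, `site_id`,
#'   `group`, `age`, `sex`, `bmi`, `icv`, `hemisphere`, `roi`, `volume`, and
#'   (if a medication model is configured) `medication_count`, `lithium`.
#'   Attribute `provenance` holds the configuration, seed, and the built-in
#'   per-region indirect effects.
#' @examples
#' cfg <- generator_config(n_sites = 4, subjects_per_site = 30, seed = 7)
#' cohort <- generate_cohort(cfg)
#' head(cohort)
#' attr(cohort, "provenance")$indirect_effects
#' @export
generate_cohort <- function(config = generator_config()) {
  if (!inherits(config, "generator_config"))
    stop_config("`config` must be created by generator_config()")
  with_seed(config$seed, {
    nps <- config$subjects_per_site
    n <- sum(nps)
    site <- rep(seq_along(nps), nps)
    n_case <- round(config$case_fraction * nps)
    group <- unlist(lapply(seq_along(nps), function(s) {
      sample(rep(c("case", "control"), c(n_case[s], nps[s] - n_case[s])))
    }))
    is_case <- group == "case"

    age <- numeric(n); sex_p <- numeric(n); bmi <- numeric(n)
    for (g in c("control", "case")) {
      idx <- which(group == g)
      am <- config$age_model[[g]]
      age[idx] <- rnorm_trunc(length(idx), am[["mean"]], am[["sd"]], 18, 90)
      sex_p[idx] <- config$sex_model[[g]]
    }
    sex <- ifelse(runif(n) < sex_p, "female", "male")
    bm <- config$bmi_model
    case_mean <- if (!is.null(bm$path_a)) bm$control[["mean"]] + bm$path_a
                 else bm$case[["mean"]]
    bmi[!is_case] <- rnorm(sum(!is_case), bm$control[["mean"]], bm$control[["sd"]])
    bmi[is_case] <- rnorm(sum(is_case), case_mean, bm$case[["sd"]])
    bmi <- pmax(bmi, 14)
    icv <- pmax(rnorm(n, config$icv_model[["mean"]], config$icv_model[["sd"]]), 8e5)

    med <- lith <- latent <- NULL
    mm <- config$medication_model
    if (!is.null(mm)) {
      med <- rep(NA_integer_, n); lith <- rep(NA_integer_, n)
      nc <- sum(is_case)
      if (mm$latent_sd > 0) {
        latent <- rnorm(nc, 0, mm$latent_sd)
        # map the latent driver onto 0-3 classes through its quartiles
        qs <- quantile(latent, cumsum(mm$probs)[1:3])
        med[is_case] <- findInterval(latent, qs)
        bmi[is_case] <- bmi[is_case] + mm$bmi_per_latent * latent
      } else {
        med[is_case] <- sample(0:3, nc, replace = TRUE, prob = mm$probs)
      }
      bmi[is_case] <- bmi[is_case] + mm$bmi_per_class * med[is_case]
      bmi <- pmax(bmi, 14)
      lith[is_case] <- rbinom(nc, 1, mm$lithium_p)
    }

    subj <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                       site_id = sprintf("site%02d", site),
                       group = group, age = age, sex = sex, bmi = bmi,
                       icv = icv, stringsAsFactors = FALSE)

    eff <- config$roi_effects
    vc <- config$variance_components
    pieces <- vector("list", nrow(eff))
    for (k in seq_len(nrow(eff))) {
      e <- eff[k, ]
      v <- vc[vc$roi == e$roi, ]
      u_site <- rnorm(length(nps), 0, v$sd_site)[site]
      u_subj <- rnorm(n, 0, v$sd_subject)
      mu <- e$intercept + e$b_group * is_case + e$b_bmi * bmi +
        e$b_age * age + e$b_sex * (sex == "female") + e$b_icv * icv +
        u_site + u_subj
      if (!is.null(mm) && e$roi == "lateral_ventricles") {
        extra <- ifelse(is_case,
                        mm$ventricle_per_class * med +
                          mm$lithium_ventricle * lith, 0)
        if (!is.null(latent))
          extra[is_case] <- extra[is_case] + mm$ventricle_per_latent * latent
        mu <- mu + extra
      }
      vol_l <- mu + rnorm(n, 0, v$sd_residual)
      vol_r <- mu + e$b_hemisphere + rnorm(n, 0, v$sd_residual)
      miss <- runif(n) < config$qc_missing_rate
      vol_l[miss] <- NA_real_; vol_r[miss] <- NA_real_
      block <- rbind(
        cbind(subj, hemisphere = "left", roi = e$roi,
              volume = pmax(vol_l, 1), stringsAsFactors = FALSE),
        cbind(subj, hemisphere = "right", roi = e$roi,
              volume = pmax(vol_r, 1), stringsAsFactors = FALSE))
      pieces[[k]] <- block
    }
    out <- do.call(rbind, pieces)
    if (!is.null(mm)) {
      out$medication_count <- med[match(out$subject_id, subj$subject_id)]
      out$lithium <- lith[match(out$subject_id, subj$subject_id)]
    }
    out <- out[order(out$subject_id, out$roi, out$hemisphere), , drop = FALSE]
    rownames(out) <- NULL
    indirect <- if (!is.null(bm$path_a)) bm$path_a * eff$b_bmi else rep(NA_real_, nrow(eff))
    attr(out, "provenance") <- list(
      config = config, seed = config$seed, n_subjects = n,
      indirect_effects = setNames(indirect, eff$roi))
    out
  })
}
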
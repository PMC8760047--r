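# Shared fixtures: compact generator configurations built in code.

# Single-region configuration with every knob explicit; defaults are a
# null, noise-free region.
one_roi_config <- function(roi = "lateral_ventricles", intercept = 1000,
                           b_group = 0, b_bmi = 0, b_age = 0, b_sex = 0,
                           b_icv = 0, b_hemisphere = 0,
                           sd_site = 0, sd_subject = 0, sd_residual = 0,
                           path_a = NULL, n_sites = 5, subjects_per_site = 40,
                           qc_missing_rate = 0, seed = 1L,
                           bmi_model = NULL, ...) {
  if (is.null(bmi_model))
    bmi_model <- list(control = c(mean = 24.43, sd = 4.12),
                      case = c(mean = 26.80, sd = 5.22), path_a = path_a)
  generator_config(
    n_sites = n_sites, subjects_per_site = subjects_per_site,
    roi_effects = data.frame(roi = roi, intercept = intercept,
                             b_group = b_group, b_bmi = b_bmi, b_age = b_age,
                             b_sex = b_sex, b_icv = b_icv,
                             b_hemisphere = b_hemisphere),
    variance_components = data.frame(roi = roi, sd_site = sd_site,
                                     sd_subject = sd_subject,
                                     sd_residual = sd_residual),
    bmi_model = bmi_model,
    qc_missing_rate = qc_missing_rate, seed = seed, ...)
}

# The study-conditions mediation configuration: a = 2.4, b = 47 on the
# ventricles (indirect ~ 113, total ~ 614, proportion mediated ~ 18.4%).
mediation_sim_config <- function(seed, path_a = 2.4, b_bmi = 47,
                                 b_group = 501, n_sites = 10,
                                 subjects_per_site = 60) {
  eff <- default_roi_effects()
  eff <- eff[eff$roi == "lateral_ventricles", ]
  eff$b_group <- b_group
  eff$b_bmi <- b_bmi
  vc <- default_variance_components()
  vc <- vc[vc$roi == "lateral_ventricles", ]
  generator_config(
    n_sites = n_sites, subjects_per_site = subjects_per_site,
    roi_effects = eff, variance_components = vc,
    bmi_model = list(control = c(mean = 24.43, sd = 4.12),
                     case = c(mean = 26.80, sd = 5.22), path_a = path_a),
    qc_missing_rate = 0.10, seed = seed)
}

# Independent step-up FDR oracle: adjusted p_i is the smallest level at
# which hypothesis i is rejected, computed by a literal scan.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    vals <- sorted[i:m] * m / (i:m)
    adj[i] <- min(1, min(vals))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# Independent chi-square oracle: literal cell-by-cell expected counts.
chi2_bruteforce <- function(counts) {
  n <- sum(counts)
  stat <- 0
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      e <- sum(counts[i, ]) * sum(counts[, j]) / n
      stat <- stat + (counts[i, j] - e)^2 / e
    }
  }
  stat
}
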
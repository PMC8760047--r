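cohort_required_columns <- function() {
  c("subject_id", "site_id", "group", "age", "sex", "bmi", "icv",
    "hemisphere", "roi", "volume")
}

normalize_labels <- function(x) gsub("[ .-]+", "_", tolower(trimws(x)))

#' Validate (and normalize) a cohort table
#'
#' Checks the cohort-table contract: required columns present; hemisphere,
#' region, group and sex labels normalized to the canonical vocabulary; no
#' missing values in the covariates (group, age, sex, BMI, ICV); exactly
#' one row per subject x hemisphere x region; non-negative volumes;
#' covariates constant within subject. Violations are reported with the
#' offending rows or keys.
#'
#' @param data Data.frame to validate.
#' @return The validated, normalized data.frame (invisibly usable).
#' @export
validate_cohort <- function(data) {
  missing_cols <- setdiff(cohort_required_columns(), names(data))
  if (length(missing_cols))
    stop_config("missing column(s): ", paste(missing_cols, collapse = ", "))
  data$hemisphere <- normalize_labels(data$hemisphere)
  data$roi <- normalize_labels(data$roi)
  data$group <- normalize_labels(data$group)
  data$sex <- normalize_labels(data$sex)

  bad <- which(!data$hemisphere %in% c("left", "right"))
  if (length(bad))
    stop_config("invalid hemisphere label(s) at row(s): ",
                paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!data$roi %in% roi_labels())
  if (length(bad))
    stop_config("unknown region label '", data$roi[bad[1]], "' at row(s): ",
                paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!data$group %in% c("control", "case"))
  if (length(bad))
    stop_config("group must be control/case; offending row(s): ",
                paste(utils::head(bad, 5), collapse = ", "))
  bad <- which(!data$sex %in% c("male", "female"))
  if (length(bad))
    stop_config("sex must be male/female; offending row(s): ",
                paste(utils::head(bad, 5), collapse = ", "))

  for (col in c("group", "age", "sex", "bmi", "icv")) {
    bad <- which(is.na(data[[col]]))
    if (length(bad))
      stop_config("missing ", col, " at row(s): ",
                  paste(utils::head(bad, 5), collapse = ", "))
  }
  if (any(data$bmi <= 0) || any(data$icv <= 0))
    stop_config("BMI and ICV must be positive")
  bad <- which(!is.na(data$volume) & data$volume < 0)
  if (length(bad))
    stop_config("negative volume at row(s): ",
                paste(utils::head(bad, 5), collapse = ", "))

  key <- paste(data$subject_id, data$hemisphere, data$roi, sep = "|")
  dup <- key[duplicated(key)]
  if (length(dup))
    stop_config("duplicated subject x hemisphere x region key(s): ",
                paste(utils::head(unique(dup), 5), collapse = ", "))

  for (col in c("group", "age", "sex", "bmi", "icv")) {
    n_per <- tapply(data[[col]], data$subject_id,
                    function(x) length(unique(x)))
    if (any(n_per > 1))
      stop_config(col, " varies within subject(s): ",
                  paste(utils::head(names(n_per)[n_per > 1], 5),
                        collapse = ", "))
  }
  data
}

#' Read a cohort table from CSV
#'
#' Reads a long-format cohort CSV (comma separated, UTF-8, '.' decimal,
#' documented header: `subject_id, site_id, group, age, sex, bmi, icv,
#' hemisphere, roi, volume` plus optional `medication_count`, `lithium`)
#' and validates it with [validate_cohort()], normalizing hemisphere and
#' region labels to the canonical vocabulary.
#'
#' @param path Path to the CSV file.
#' @return Validated cohort data.frame.
#' @export
read_cohort <- function(path) {
  data <- read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(data)
}

#' Write a cohort table (with provenance) to CSV
#'
#' Writes the cohort as a plain CSV and, when the table carries a
#' `provenance` attribute (as tables from [generate_cohort()] do), a
#' companion `<path>.provenance.json` capturing the generator
#' configuration and seed, so the file can be regenerated byte-identically.
#'
#' @param data Cohort table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  write.csv(data, path, row.names = FALSE)
  prov <- attr(data, "provenance")
  if (!is.null(prov)) {
    prov$config <- unclass(prov$config)
    jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

fmt_p <- function(p) ifelse(p < 0.001, "<0.001", sprintf("%.3f", p))

#' Assemble a Markdown + CSV/JSON report from pipeline outputs
#'
#' Writes whatever stage outputs are supplied into `dir`: a demographic
#' (Table-1 style) block, a results (Table-2 style) block with
#' coefficients, FDR-adjusted p-values and effect sizes per region and
#' model family, a change-in-group-effect-size table (group d with vs
#' without BMI adjustment), the interaction screens, and the mediation
#' path summary (including which gate criteria failed when mediation was
#' skipped). Partial reports are allowed; each block is written only when
#' its input is present. CSV/JSON outputs are deterministic given the same
#' inputs.
#'
#' @param dir Output directory (created if needed).
#' @param table1 Optional [cohort_table1()] output.
#' @param results Optional [run_model_families()] output.
#' @param interactions Optional [screen_interactions()] output.
#' @param variance Optional [variance_comparison()] output.
#' @param mediation Optional [bootstrap_mediation()] output.
#' @param gate Optional [check_mediation_criteria()] output (reported when
#'   mediation was gated off).
#' @param legacy_sign Flip the sign of group coefficients and effect sizes
#'   in the rendered results block, reproducing reports that code the
#'   contrast as control minus case. CSV outputs keep the native
#'   case-positive coding.
#' @return Path of the Markdown report, invisibly.
#' @export
write_report <- function(dir, table1 = NULL, results = NULL,
                         interactions = NULL, variance = NULL,
                         mediation = NULL, gate = NULL,
                         legacy_sign = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  md <- c("# Cohort analysis report", "")

  if (!is.null(table1)) {
    write.csv(table1, file.path(dir, "table1_descriptives.csv"),
              row.names = FALSE)
    md <- c(md, "## Demographics", "",
            "| variable | control | case | statistic | df | p |",
            "|---|---|---|---|---|---|",
            sprintf("| %s | %s | %s | %s | %s | %s |", table1$variable,
                    table1$control, table1$case,
                    ifelse(is.na(table1$statistic), "",
                           sprintf("%.2f", table1$statistic)),
                    ifelse(is.na(table1$df), "", sprintf("%.0f", table1$df)),
                    ifelse(is.na(table1$p), "", fmt_p(table1$p))), "")
  }

  if (!is.null(results)) {
    write.csv(as.data.frame(results), file.path(dir, "roi_results.csv"),
              row.names = FALSE)
    shown <- as.data.frame(results)
    if (legacy_sign) {
      flip <- shown$term == "group"
      for (col in c("b", "es")) shown[[col]][flip] <- -shown[[col]][flip]
      tmp <- shown$es_low[flip]
      shown$es_low[flip] <- -shown$es_high[flip]
      shown$es_high[flip] <- -tmp
    }
    md <- c(md, "## Region-level model families", "",
            "| roi | family | term | b | SE b | DF | p (FDR) | effect | 95% CI |",
            "|---|---|---|---|---|---|---|---|---|",
            sprintf("| %s | %s | %s | %.2f | %.2f | %d | %s%s | %.2f | %.2f, %.2f |",
                    shown$roi, shown$family, shown$term, shown$b, shown$se,
                    shown$df, fmt_p(shown$p_fdr),
                    ifelse(shown$significant, "*", ""),
                    round_half_up(shown$es), round_half_up(shown$es_low),
                    round_half_up(shown$es_high)), "")
    both <- c("group_only", "joint")
    if (all(both %in% results$family)) {
      g0 <- shown[shown$family == "group_only" & shown$term == "group", ]
      g1 <- shown[shown$family == "joint" & shown$term == "group", ]
      common <- intersect(g0$roi, g1$roi)
      delta <- data.frame(roi = common,
                          d_unadjusted = g0$es[match(common, g0$roi)],
                          d_bmi_adjusted = g1$es[match(common, g1$roi)])
      delta$change <- delta$d_bmi_adjusted - delta$d_unadjusted
      write.csv(delta, file.path(dir, "group_effect_size_change.csv"),
                row.names = FALSE)
      md <- c(md, "## Change in group effect size after BMI adjustment", "",
              "| roi | d (unadjusted) | d (BMI-adjusted) | change |",
              "|---|---|---|---|",
              sprintf("| %s | %.2f | %.2f | %+.2f |", delta$roi,
                      delta$d_unadjusted, delta$d_bmi_adjusted, delta$change),
              "")
    }
  }

  if (!is.null(interactions)) {
    write.csv(interactions, file.path(dir, "interaction_screens.csv"),
              row.names = FALSE)
    md <- c(md, "## Interaction screens", "",
            sprintf("- %s / %s: statistic %.3f, p (FDR) %s%s",
                    interactions$roi, interactions$screen,
                    interactions$statistic, fmt_p(interactions$p_fdr),
                    ifelse(interactions$retained, " (retained)", "")), "")
  }

  if (!is.null(variance)) {
    write.csv(variance, file.path(dir, "variance_comparison.csv"),
              row.names = FALSE)
    md <- c(md, "## Between-group variance comparison", "",
            sprintf("- %s: %.1f%% difference", variance$roi,
                    variance$pct_difference), "")
  }

  if (!is.null(mediation)) {
    paths <- data.frame(
      path = c("a", "b", "c", "c_prime", "indirect"),
      estimate = c(mediation$a, mediation$b_path, mediation$c,
                   mediation$c_prime, mediation$indirect_hat),
      ci_low = c(NA, NA, NA, NA, mediation$ci[1]),
      ci_high = c(NA, NA, NA, NA, mediation$ci[2]))
    write.csv(paths, file.path(dir, "mediation_paths.csv"), row.names = FALSE)
    jsonlite::write_json(
      mediation[c("roi", "a", "b_path", "c", "c_prime", "indirect_hat",
                  "ci", "prop_mediated", "prop_ci", "sobel_z", "sobel_p",
                  "n_boot", "n_dropped", "seed", "engine")],
      file.path(dir, "mediation.json"), auto_unbox = TRUE, digits = NA)
    md <- c(md, "## Mediation of the group effect through BMI", "",
            sprintf("- region: %s", mediation$roi),
            sprintf("- indirect effect %.2f [%.2f, %.2f]%s",
                    mediation$indirect_hat, mediation$ci[1], mediation$ci[2],
                    if (mediation$significant) " *" else ""),
            sprintf("- proportion mediated %.2f%% [%.2f%%, %.2f%%]",
                    mediation$prop_mediated, mediation$prop_ci[1],
                    mediation$prop_ci[2]),
            sprintf("- Sobel Z = %.2f, p = %s", mediation$sobel_z,
                    fmt_p(mediation$sobel_p)), "")
  } else if (!is.null(gate)) {
    failed <- names(gate$criteria)[!gate$criteria]
    md <- c(md, "## Mediation of the group effect through BMI", "",
            sprintf("Mediation was not run for %s: gate %s.", gate$roi,
                    if (gate$pass) "passed" else
                      paste0("failed on ", paste(failed, collapse = ", "))),
            "")
  }

  out <- file.path(dir, "report.md")
  writeLines(md, out)
  invisible(out)
}
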
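# Internal helpers shared across modules.

#' Canonical subcortical region labels
#'
#' The eight bilateral subcortical structures handled by the pipeline, in
#' canonical spelling. Cohort files may use any capitalisation or spaces;
#' [read_cohort()] normalises to these labels.
#'
#' @return Character vector of length 8.
#' @export
roi_labels <- function() {
  c("lateral_ventricles", "accumbens", "amygdala", "hippocampus",
    "pallidum", "putamen", "caudate", "thalamus")
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

# Draw independent sub-seeds from a master seed; first k draws are stable
# when n grows, so increasing n_boot extends rather than reshuffles streams.
spawn_seeds <- function(master, n) {
  with_seed(master, sample.int(.Machine$integer.max, n))
}

stop_config <- function(...) stop(..., call. = FALSE)

# One row per subject for a given region: bilateral mean volume plus
# subject-level covariates. Subjects with no non-missing volume are dropped.
subject_means <- function(data, roi = NULL) {
  if (!is.null(roi)) data <- data[data$roi == roi, , drop = FALSE]
  data <- data[!is.na(data$volume), , drop = FALSE]
  if (nrow(data) == 0L) return(data[0, , drop = FALSE])
  first <- !duplicated(data$subject_id)
  out <- data[first, setdiff(names(data), c("hemisphere", "volume", "roi")),
              drop = FALSE]
  vol <- tapply(data$volume, data$subject_id, mean)
  out$volume <- as.numeric(vol[match(out$subject_id, names(vol))])
  rownames(out) <- NULL
  out
}

# 0/1 numeric codings used by the internal model builders.
group01 <- function(x) as.numeric(x == "case")
sex01 <- function(x) as.numeric(x == "female")
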
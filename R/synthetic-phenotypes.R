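#' Generate a synthetic imaging cohort with planted diagnosis effects
#'
#' One row per subject with age, sex, total brain volume (TBV, cm^3),
#' diagnosis (ordered CN < MCI < Dementia) and one column per
#' (tract, measure) combination named `tract.measure`. Each measure is a sum
#' of standardized covariate effects, a planted diagnosis effect
#' `beta * diagnosis code` (CN = 0, MCI = 1, Dementia = 2) and Gaussian
#' noise. Measures are on a standardized scale.
#'
#' @param config a [synth_config()]
#' @param n number of subjects (default `config$n_subjects_pheno`)
#' @param stream RNG stream index; use a different value to draw an
#'   independent cohort (e.g. a replication cohort) from the same config
#' @return list(table = data.frame of class `subject_table`,
#'   truth = data.frame(tract, measure, beta))
#' @export
generate_subject_phenotypes <- function(config, n = config$n_subjects_pheno,
                                        stream = 4L) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(stream_seed(config$seed, stream))
  diag_levels <- c("CN", "MCI", "Dementia")
  props <- config$diag_props[diag_levels]
  tab <- data.frame(
    subject = sprintf("P%04d", seq_len(n)),
    age = round(rnorm(n, 73.8, 8.4), 1),
    sex = factor(sample(c("F", "M"), n, replace = TRUE,
                        prob = c(0.541, 0.459))),
    tbv = round(rnorm(n, 1500, 150), 1),
    diagnosis = factor(sample(diag_levels, n, replace = TRUE, prob = props),
                       levels = diag_levels, ordered = TRUE),
    stringsAsFactors = FALSE)
  if (nlevels(droplevels(tab$sex)) < 2) tab$sex[1] <- setdiff(c("F", "M"), tab$sex[1])
  diag_code <- as.integer(tab$diagnosis) - 1L
  eff <- config$pheno_covariate_effects
  zage <- as.numeric(scale(tab$age)); zsex <- as.numeric(tab$sex == "M")
  ztbv <- as.numeric(scale(tab$tbv))
  de <- config$diagnosis_effects
  beta_of <- function(tr, ms) {
    hit <- de$tract == tr & de$measure == ms
    if (any(hit)) de$beta[hit][1] else 0
  }
  truth <- expand.grid(tract = config$tracts, measure = diffusion_measures,
                       stringsAsFactors = FALSE)
  truth$beta <- mapply(beta_of, truth$tract, truth$measure)
  for (i in seq_len(nrow(truth))) {
    col <- paste(truth$tract[i], truth$measure[i], sep = ".")
    tab[[col]] <- eff["age"] * zage + eff["sex"] * zsex + eff["tbv"] * ztbv +
      truth$beta[i] * diag_code + rnorm(n, 0, config$noise_sd)
  }
  class(tab) <- c("subject_table", "data.frame")
  attr(tab, "tracts") <- config$tracts
  attr(tab, "measures") <- diffusion_measures
  list(table = tab, truth = truth)
}

measure_column <- function(table, tract, measure) {
  col <- paste(tract, measure, sep = ".")
  if (!col %in% names(table))
    stop_cs(sprintf("no column for tract '%s', measure '%s'", tract, measure),
            "cs_lookup_error")
  col
}
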
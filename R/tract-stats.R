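#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values, monotone in rank order and clipped at 1. A thin,
#' validated wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param pvalues numeric vector of p-values in (0, 1]
#' @return q-values in the input order
#' @export
fdr_adjust <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stop_cs("p-values must lie in (0, 1]", "cs_config_error")
  p.adjust(pvalues, method = "BH")
}

# one-shot 3.5-SD outlier rule on the raw measure (ties at the cut retained)
trim_outliers <- function(y, n_sd = 3.5) {
  mu <- mean(y, na.rm = TRUE); s <- sd(y, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(TRUE, length(y)))
  abs(y - mu) <= n_sd * s
}

#' Diffusion-measure association with diagnosis severity
#'
#' Fits `measure ~ diagnosis + age + sex + TBV` by least squares after a
#' single pass of 3.5-SD outlier removal on the raw measure. Diagnosis is
#' coded numerically (CN = 0, MCI = 1, Dementia = 2), so the reported beta
#' is the effect per severity step; the p-value is the Wald test of that
#' coefficient.
#'
#' @param table a `subject_table` from [generate_subject_phenotypes()] (or
#'   any data.frame with age, sex, tbv, diagnosis and `tract.measure`
#'   columns)
#' @param tract,measure which column to analyze
#' @param sd_cut outlier threshold in SD units
#' @return data.frame(tract, measure, beta, se, p, n_used)
#' @export
diagnosis_association <- function(table, tract, measure, sd_cut = 3.5) {
  col <- measure_column(table, tract, measure)
  keep <- trim_outliers(table[[col]], sd_cut) &
    complete.cases(table[, c("age", "sex", "tbv", "diagnosis")])
  d <- table[keep, ]
  if (nrow(d) < 10) stop_cs("fewer than 10 complete subjects",
                            "cs_config_error")
  d$diag_code <- as.integer(d$diagnosis) - 1L
  fit <- lm(d[[col]] ~ diag_code + age + sex + tbv, data = d)
  if (fit$df.residual <= 0)
    stop_cs("zero residual degrees of freedom", "cs_model_error")
  sm <- summary(fit)$coefficients
  data.frame(tract = tract, measure = measure,
             beta = sm["diag_code", "Estimate"],
             se = sm["diag_code", "Std. Error"],
             p = sm["diag_code", "Pr(>|t|)"],
             n_used = nrow(d), stringsAsFactors = FALSE)
}

#' Diagnosis associations for every tract and measure, FDR-adjusted
#'
#' The FDR family is all tract x measure combinations within the cohort.
#'
#' @param table a `subject_table`
#' @param tracts,measures combinations to test (defaults from the table's
#'   attributes)
#' @param sd_cut outlier threshold
#' @return data.frame with columns tract, measure, beta, se, p, q, n_used
#' @export
diagnosis_association_all <- function(table,
                                      tracts = attr(table, "tracts"),
                                      measures = attr(table, "measures"),
                                      sd_cut = 3.5) {
  grid <- expand.grid(tract = tracts, measure = measures,
                      stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
    diagnosis_association(table, grid$tract[i], grid$measure[i], sd_cut)))
  res$q <- fdr_adjust(res$p)
  res
}

#' Replication of discovery associations in an independent cohort
#'
#' A (tract, measure) association replicates when it is significant at
#' `q < q_cut` in both cohorts and the diagnosis effect has the same sign.
#'
#' @param discovery,replication results of [diagnosis_association_all()]
#' @param q_cut FDR threshold applied in both cohorts
#' @return list(replicated = data.frame of replicated keys, concordance =
#'   effect-size table with both betas and significance flags)
#' @export
replication_check <- function(discovery, replication, q_cut = 0.05) {
  m <- merge(discovery, replication, by = c("tract", "measure"),
             suffixes = c("_disc", "_repl"))
  if (!nrow(m)) stop_cs("no shared (tract, measure) keys",
                        "cs_alignment_error")
  m$sig_disc <- m$q_disc < q_cut
  m$sig_repl <- m$q_repl < q_cut
  m$concordant <- sign(m$beta_disc) == sign(m$beta_repl)
  m$replicated <- m$sig_disc & m$sig_repl & m$concordant
  list(replicated = m[m$replicated, c("tract", "measure", "beta_disc",
                                      "beta_repl", "q_disc", "q_repl")],
       concordance = m[, c("tract", "measure", "beta_disc", "beta_repl",
                           "sig_disc", "sig_repl", "concordant",
                           "replicated")])
}

#' Covariate screen against all diffusion measures
#'
#' For each covariate and each (tract, measure): -log10 p from a
#' single-covariate linear model, before and after adjusting for age, sex
#' and TBV. Constant covariates are flagged with p = 1.
#'
#' @param table a `subject_table`
#' @param covariates covariate column names to screen
#' @param tracts,measures combinations (defaults from attributes)
#' @return long data.frame(covariate, tract, measure, p_raw, p_adjusted,
#'   neglog10_raw, neglog10_adjusted, flagged)
#' @export
covariate_screen <- function(table, covariates,
                             tracts = attr(table, "tracts"),
                             measures = attr(table, "measures")) {
  stopifnot(all(covariates %in% names(table)))
  adj <- c("age", "sex", "tbv")
  grid <- expand.grid(covariate = covariates, tract = tracts,
                      measure = measures, stringsAsFactors = FALSE)
  cov_p <- function(y, cv, extra) {
    x <- table[[cv]]
    if (length(unique(x[!is.na(x)])) < 2) return(c(p = 1, flag = 1))
    # adjustment terms first so an aliased screened covariate is the one
    # dropped (reported flagged, p = 1) rather than silently re-labeled
    rhs <- c(setdiff(extra, cv), cv)
    f <- stats::as.formula(paste("y ~", paste(rhs, collapse = " + ")))
    fit <- lm(f, data = cbind(y = y, table))
    cm <- summary(fit)$coefficients
    row <- grep(paste0("^", cv), rownames(cm))[1]
    if (is.na(row)) return(c(p = 1, flag = 1))
    c(p = cm[row, 4], flag = 0)
  }
  out <- lapply(seq_len(nrow(grid)), function(i) {
    y <- table[[measure_column(table, grid$tract[i], grid$measure[i])]]
    raw <- cov_p(y, grid$covariate[i], character(0))
    adj_p <- cov_p(y, grid$covariate[i], adj)
    data.frame(covariate = grid$covariate[i], tract = grid$tract[i],
               measure = grid$measure[i], p_raw = raw["p"],
               p_adjusted = adj_p["p"],
               neglog10_raw = -log10(raw["p"]),
               neglog10_adjusted = -log10(adj_p["p"]),
               flagged = raw["flag"] == 1, stringsAsFactors = FALSE,
               row.names = NULL)
  })
  do.call(rbind, out)
}
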
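#' Per-region expression container
#'
#' @param expr named list, one genes x subjects matrix per region
#' @param covariates data.frame of subject covariates (one row per subject,
#'   aligned with matrix columns)
#' @return a `region_expression_set`
#' @export
region_expression_set <- function(expr, covariates) {
  stopifnot(is.list(expr), length(expr) >= 1,
            all(vapply(expr, is.matrix, logical(1))))
  structure(list(expr = expr, covariates = covariates,
                 regions = names(expr)),
            class = "region_expression_set")
}

#' @export
print.region_expression_set <- function(x, ...) {
  cat(sprintf("<region_expression_set> %d regions x %d genes x %d subjects\n",
              length(x$expr), nrow(x$expr[[1]]), ncol(x$expr[[1]])))
  invisible(x)
}

# dummy-coded, column-scaled covariate design (no intercept column);
# attr "covariate" maps each column back to its source covariate
expression_design <- function(cov) {
  mm <- model.matrix(~ age + sex + pmi + ph + ethnicity + braak, cov)
  src <- c("age", "sex", "pmi", "ph", "ethnicity", "braak")[attr(mm, "assign")[-1]]
  Z <- scale(mm[, -1, drop = FALSE])
  Z[!is.finite(Z)] <- 0  # constant columns
  attr(Z, "covariate") <- src
  Z
}

#' Generate multi-region expression with planted cross-region gene blocks
#'
#' Each region receives an independent Gaussian genes x subjects matrix plus
#' covariate effects (age, sex, PMI, pH, ethnicity, Braak stage) with
#' per-gene random loadings. For each entry of `config$planted_sync`, gene
#' blocks in the two named regions load on a shared latent factor:
#' `x = sqrt(rho) * f + sqrt(1 - rho) * e`, so every cross-region gene pair
#' within the block has population correlation `rho` before covariate noise
#' is added. Non-planted cross-region pairs are independent given the
#' covariates.
#'
#' @param config a [synth_config()]
#' @return list(expression = [region_expression_set()], truth = list of
#'   planted blocks with member genes per side)
#' @export
generate_region_expression <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$n_subjects < 10)
    stop_cs("need at least 10 subjects", "cs_config_error")
  set.seed(stream_seed(config$seed, 3L))
  N <- config$n_subjects
  G <- config$n_genes_per_region
  subjects <- sprintf("S%03d", seq_len(N))
  genes <- sprintf("gene%04d", seq_len(G))
  cov <- data.frame(
    subject = subjects,
    age = round(rnorm(N, 78, 9), 1),
    sex = factor(sample(c("F", "M"), N, replace = TRUE)),
    pmi = round(pmax(rnorm(N, 12, 4), 1), 1),
    ph = round(rnorm(N, 6.5, 0.3), 2),
    ethnicity = factor(sample(c("EA", "AA", "H"), N, replace = TRUE,
                              prob = c(0.7, 0.2, 0.1))),
    braak = sample(0:6, N, replace = TRUE),
    stringsAsFactors = FALSE)
  # guarantee >= 2 levels for categorical covariates at small N
  if (nlevels(droplevels(cov$sex)) < 2) cov$sex[1] <- setdiff(c("F", "M"), cov$sex[1])
  cov$sex <- factor(as.character(cov$sex))
  if (length(unique(cov$ethnicity)) < 2) cov$ethnicity[1:2] <- c("EA", "AA")
  cov$ethnicity <- factor(as.character(cov$ethnicity))

  sdv <- config$noise_sd
  expr <- lapply(config$regions, function(r)
    matrix(rnorm(G * N, 0, sdv), G, N, dimnames = list(genes, subjects)))
  names(expr) <- config$regions

  # planted synchronized blocks: shared latent factor per block
  cursor <- setNames(rep(1L, config$n_regions), config$regions)
  truth_blocks <- list()
  for (ps in config$planted_sync) {
    if (ps$rho <= 0) next
    rA <- config$regions[ps$regions[1]]
    rB <- config$regions[ps$regions[2]]
    sA <- ps$size[1]; sB <- if (length(ps$size) > 1) ps$size[2] else ps$size[1]
    if (cursor[rA] + sA - 1L > G || cursor[rB] + sB - 1L > G)
      stop_cs("planted sync blocks exhaust n_genes_per_region",
              "cs_config_error")
    idxA <- seq(cursor[rA], length.out = sA)
    idxB <- seq(cursor[rB], length.out = sB)
    cursor[rA] <- cursor[rA] + sA; cursor[rB] <- cursor[rB] + sB
    f <- rnorm(N)
    lode <- function(n_genes) sqrt(ps$rho) * matrix(rep(f, n_genes), n_genes,
                                                    N, byrow = TRUE)
    expr[[rA]][idxA, ] <- sdv * (lode(sA) +
      sqrt(1 - ps$rho) * matrix(rnorm(sA * N), sA, N))
    expr[[rB]][idxB, ] <- sdv * (lode(sB) +
      sqrt(1 - ps$rho) * matrix(rnorm(sB * N), sB, N))
    truth_blocks[[length(truth_blocks) + 1L]] <- list(
      regionA = rA, regionB = rB, rho = ps$rho,
      genesA = genes[idxA], genesB = genes[idxB])
  }

  # covariate confounding shared across regions via the same design
  Z <- expression_design(cov)
  col_scale <- config$covariate_effects[attr(Z, "covariate")]
  for (r in config$regions) {
    L <- matrix(rnorm(G * ncol(Z)), G, ncol(Z)) *
      matrix(col_scale, G, ncol(Z), byrow = TRUE)
    expr[[r]] <- expr[[r]] + L %*% t(Z)
  }

  list(expression = region_expression_set(expr, cov),
       truth = list(sync_blocks = truth_blocks))
}
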
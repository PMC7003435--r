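#' Residualize expression on subject covariates
#'
#' Replaces each gene's values with least-squares residuals on the covariate
#' design (age, sex, PMI, pH, ethnicity, Braak stage; categoricals
#' dummy-coded). Removing covariate-driven variance suppresses spurious
#' cross-region correlations from shared batch or demographic structure.
#' Aliased design columns are dropped with a warning.
#'
#' @param set a [region_expression_set()]
#' @return a [region_expression_set()] of residuals (per-gene mean 0)
#' @export
residualize_expression <- function(set) {
  stopifnot(inherits(set, "region_expression_set"))
  cov <- set$covariates
  X <- model.matrix(~ age + sex + pmi + ph + ethnicity + braak, cov)
  expr <- lapply(set$expr, function(E) {
    stopifnot(ncol(E) == nrow(X))
    fit <- lm.fit(X, t(E))
    if (fit$rank < ncol(X))
      warning(sprintf("rank-deficient covariate design: dropped %d aliased column(s)",
                      ncol(X) - fit$rank))
    R <- t(fit$residuals)
    dimnames(R) <- dimnames(E)
    R
  })
  out <- region_expression_set(expr, cov)
  # covariate dimensions absorbed by the projection, beyond the centering
  # already implicit in correlation; downstream tests should drop this many
  # degrees of freedom
  attr(out, "df_drop") <- qr(X)$rank - 1L
  out
}

spearman_p <- function(rho, n, df_adjust = 0L) {
  # two-sided p from the t approximation with n - 2 df; df_adjust drops
  # additional degrees of freedom consumed by prior residualization
  df <- n - 2 - df_adjust
  r2 <- pmin(rho^2, 1 - 1e-15)
  tstat <- abs(rho) * sqrt(df / (1 - r2))
  2 * pt(tstat, df = df, lower.tail = FALSE)
}

#' Cross-region tissue-to-tissue correlated gene pairs
#'
#' Computes Spearman correlations for every (geneA, geneB) cross pair over
#' the subjects shared by the two matrices, with two-sided p-values from the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees
#' of freedom, and retains pairs with `p < alpha`. Work proceeds in row
#' blocks so memory stays proportional to the block, not to all pairs.
#' Constant (zero rank-variance) genes are skipped and counted.
#'
#' @param a,b genes x subjects matrices for the two regions (column names are
#'   subject ids; correlation uses the shared subjects)
#' @param alpha retention threshold on p (1e-8 is the genome-wide default)
#' @param block_size rows per block
#' @param df_adjust extra degrees of freedom to drop from the n - 2 default,
#'   i.e. the covariate dimensions already projected out when the inputs are
#'   residuals (see [residualize_expression()]); 0 for raw matrices
#' @return a `ttc_result`: list(pairs = data.frame(geneA, geneB, rho, p),
#'   count, n_shared, n_skipped)
#' @export
ttc_pairs <- function(a, b, alpha = 1e-8, block_size = 512L, df_adjust = 0L) {
  stopifnot(is.matrix(a), is.matrix(b))
  if (is.null(rownames(a))) rownames(a) <- sprintf("geneA%04d", seq_len(nrow(a)))
  if (is.null(rownames(b))) rownames(b) <- sprintf("geneB%04d", seq_len(nrow(b)))
  shared <- intersect(colnames(a), colnames(b))
  n <- length(shared)
  if (n < 10) stop_cs("fewer than 10 shared subjects", "cs_config_error")
  if (n - 2 - df_adjust < 2)
    stop_cs("not enough residual degrees of freedom", "cs_config_error")
  A <- a[, shared, drop = FALSE]; B <- b[, shared, drop = FALSE]
  rank_rows <- function(M) t(apply(M, 1L, rank))
  RA <- rank_rows(A); RB <- rank_rows(B)
  okA <- apply(RA, 1L, function(x) var(x) > 0)
  okB <- apply(RB, 1L, function(x) var(x) > 0)
  n_skipped <- sum(!okA) * nrow(B) + sum(!okB) * nrow(A) -
    sum(!okA) * sum(!okB)
  RA <- RA[okA, , drop = FALSE]; RB <- RB[okB, , drop = FALSE]
  out <- vector("list", 0L)
  ai <- split(seq_len(nrow(RA)), ceiling(seq_len(nrow(RA)) / block_size))
  bi <- split(seq_len(nrow(RB)), ceiling(seq_len(nrow(RB)) / block_size))
  for (ia in ai) for (ib in bi) {
    C <- cor(t(RA[ia, , drop = FALSE]), t(RB[ib, , drop = FALSE]))
    P <- spearman_p(C, n, df_adjust)
    hit <- which(P < alpha, arr.ind = TRUE)
    if (nrow(hit)) {
      out[[length(out) + 1L]] <- data.frame(
        geneA = rownames(C)[hit[, 1]], geneB = colnames(C)[hit[, 2]],
        rho = C[hit], p = P[hit], stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(geneA = character(0), geneB = character(0),
               rho = numeric(0), p = numeric(0))
  pairs <- pairs[order(pairs$geneA, pairs$geneB), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, count = nrow(pairs), n_shared = n,
                 n_skipped = n_skipped, alpha = alpha),
            class = "ttc_result")
}

#' @export
print.ttc_result <- function(x, ...) {
  cat(sprintf("<ttc_result> %d significant gene pairs (alpha %.3g, n = %d shared subjects)\n",
              x$count, x$alpha, x$n_shared))
  invisible(x)
}

#' TTC results for every region pair
#'
#' @param set a (typically residualized) [region_expression_set()]
#' @param alpha,block_size passed to [ttc_pairs()]
#' @param df_adjust degrees of freedom dropped by residualization; defaults
#'   to the value recorded by [residualize_expression()]
#' @return named list of `ttc_result` keyed by canonical pair id
#'   ("regionA|regionB"); attribute "counts" is a data.frame of per-pair
#'   significant counts
#' @export
ttc_all_pairs <- function(set, alpha = 1e-8, block_size = 512L,
                          df_adjust = attr(set, "df_drop") %||% 0L) {
  regions <- set$regions
  combs <- utils::combn(regions, 2)
  res <- lapply(seq_len(ncol(combs)), function(i)
    ttc_pairs(set$expr[[combs[1, i]]], set$expr[[combs[2, i]]],
              alpha = alpha, block_size = block_size,
              df_adjust = df_adjust))
  ids <- canon_pair_id(combs[1, ], combs[2, ])
  names(res) <- ids
  counts <- data.frame(pair = ids, regionA = combs[1, ], regionB = combs[2, ],
                       count = vapply(res, `[[`, numeric(1), "count"),
                       n_shared = vapply(res, `[[`, numeric(1), "n_shared"),
                       stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "counts") <- counts
  res
}

#' Enrichment of tract binding among top-decile TTC region pairs
#'
#' Ranks region pairs by their significant TTC gene-pair count, marks the top
#' `ceiling(0.1 * N)` (ties broken by pair id), and tests whether membership
#' in the given binding class is over-represented among the top pairs with a
#' one-sided (greater) Fisher exact test.
#'
#' @param counts data.frame(pair, count) as produced by [ttc_all_pairs()]
#'   (attribute "counts")
#' @param classes classification data.frame from [classify_region_pairs()]
#' @param class_flag "bound" or "ad_bound": which flag defines the class
#' @param alternative Fisher sidedness (default "greater")
#' @return list(table 2x2, p, top_pairs, cut)
#' @export
top_decile_enrichment <- function(counts, classes, class_flag = c("bound", "ad_bound"),
                                  alternative = "greater") {
  class_flag <- match.arg(class_flag)
  m <- merge(counts, classes[, c("pair", "bound", "ad_bound")], by = "pair")
  if (nrow(m) != nrow(counts))
    stop_cs("counts and classes do not cover the same region pairs",
            "cs_mapping_error")
  N <- nrow(m)
  m <- m[order(-m$count, m$pair), ]
  cut <- ceiling(0.1 * N)
  top <- rep(FALSE, N); top[seq_len(cut)] <- TRUE
  cls <- m[[class_flag]]
  if (all(cls) || !any(cls)) {
    warning("degenerate class (all or no pairs in class); p set to 1")
    return(list(table = table(top, cls), p = 1, top_pairs = m$pair[top],
                cut = cut))
  }
  tab <- matrix(c(sum(top & cls), sum(top & !cls),
                  sum(!top & cls), sum(!top & !cls)), 2, byrow = TRUE,
                dimnames = list(top = c("top", "rest"),
                                class = c("in", "out")))
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  list(table = tab, p = p, top_pairs = m$pair[top], cut = cut)
}
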
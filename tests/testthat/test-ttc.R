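test_that("residualization zeroes covariate-explained structure", {
  cfg <- small_cfg(seed = 21)
  gx <- generate_region_expression(cfg)
  set <- gx$expression
  # a gene exactly linear in age has all-zero residuals
  set$expr[[1]][1, ] <- 2 * set$covariates$age - 5
  rs <- residualize_expression(set)
  expect_true(all(abs(rs$expr[[1]][1, ]) < 1e-8))
  # residual means are zero per gene
  expect_true(all(abs(rowMeans(rs$expr[[2]])) < 1e-8))
  # a gene orthogonal to the design is only centered
  n <- cfg$n_subjects
  X <- model.matrix(~ age + sex + pmi + ph + ethnicity + braak,
                    set$covariates)
  v <- residuals(lm.fit(X, rnorm(n)))     # orthogonal by construction
  set$expr[[1]][2, ] <- v + 100
  rs2 <- residualize_expression(set)
  expect_equal(unname(rs2$expr[[1]][2, ]), unname(v - mean(v)),
               tolerance = 1e-8)
})

test_that("a shared planted confounder is removed by residualization", {
  cfg <- small_cfg(seed = 22, planted_sync = list())
  gx <- generate_region_expression(cfg)
  set <- gx$expression
  z <- as.numeric(scale(set$covariates$age))
  # two genes in different regions driven by the same covariate
  set$expr[[1]][1, ] <- 2 * z + 0.3 * rnorm(cfg$n_subjects)
  set$expr[[2]][1, ] <- -1.5 * z + 0.3 * rnorm(cfg$n_subjects)
  raw_cor <- cor(set$expr[[1]][1, ], set$expr[[2]][1, ],
                 method = "spearman")
  expect_gt(abs(raw_cor), 0.5)
  rs <- residualize_expression(set)
  expect_lt(abs(cor(rs$expr[[1]][1, ], rs$expr[[2]][1, ],
                    method = "spearman")), 0.3)
})

test_that("identical genes correlate perfectly and are always retained", {
  set.seed(23)
  n <- 30
  A <- matrix(rnorm(3 * n), 3, n, dimnames = list(paste0("a", 1:3),
                                                  sprintf("s%02d", 1:n)))
  B <- A[1, , drop = FALSE]; rownames(B) <- "b1"
  res <- ttc_pairs(A, B, alpha = 0.5)
  hit <- res$pairs[res$pairs$geneA == "a1", ]
  expect_equal(hit$rho, 1)
  expect_equal(hit$p, 0)
})

test_that("null TTC counts are binomially consistent with alpha", {
  set.seed(24)
  n <- 40
  A <- matrix(rnorm(200 * n), 200, n)
  B <- matrix(rnorm(200 * n), 200, n)
  colnames(A) <- colnames(B) <- sprintf("s%02d", 1:n)
  res <- ttc_pairs(A, B, alpha = 1e-3)
  expected <- 200 * 200 * 1e-3
  s3 <- 3 * sqrt(200 * 200 * 1e-3 * (1 - 1e-3))
  expect_gt(res$count, expected - s3)
  expect_lt(res$count, expected + s3)
})

test_that("Spearman is invariant under monotone transforms; counts monotone in alpha; pairs symmetric", {
  set.seed(25)
  n <- 30
  A <- matrix(rnorm(10 * n), 10, n, dimnames = list(paste0("a", 1:10),
                                                    sprintf("s%02d", 1:n)))
  B <- matrix(rnorm(10 * n), 10, n, dimnames = list(paste0("b", 1:10),
                                                    sprintf("s%02d", 1:n)))
  r1 <- ttc_pairs(A, B, alpha = 0.2)
  A2 <- A; A2[3, ] <- exp(A2[3, ])            # strictly monotone transform
  r2 <- ttc_pairs(A2, B, alpha = 0.2)
  expect_equal(r1$pairs, r2$pairs)
  # alpha monotonicity
  expect_lte(ttc_pairs(A, B, alpha = 0.01)$count,
             ttc_pairs(A, B, alpha = 0.10)$count)
  # symmetry: swapping regions transposes the list
  r3 <- ttc_pairs(B, A, alpha = 0.2)
  expect_equal(r3$count, r1$count)
  got <- r3$pairs[order(r3$pairs$geneB, r3$pairs$geneA), ]
  want <- r1$pairs[order(r1$pairs$geneA, r1$pairs$geneB), ]
  expect_equal(got$rho, want$rho)
  expect_equal(paste(got$geneB, got$geneA), paste(want$geneA, want$geneB))
})

test_that("constant genes are skipped and logged, small block sizes stream correctly", {
  set.seed(26)
  n <- 20
  A <- matrix(rnorm(5 * n), 5, n, dimnames = list(paste0("a", 1:5),
                                                  sprintf("s%02d", 1:n)))
  A[2, ] <- 7
  B <- matrix(rnorm(6 * n), 6, n, dimnames = list(paste0("b", 1:6),
                                                  sprintf("s%02d", 1:n)))
  res <- ttc_pairs(A, B, alpha = 1)
  expect_equal(res$n_skipped, 6)
  expect_equal(res$count, 4 * 6)
  # blocked result identical to unblocked
  res2 <- ttc_pairs(A, B, alpha = 1, block_size = 2L)
  expect_equal(res$pairs, res2$pairs)
  expect_error(ttc_pairs(A[, 1:5], B[, 1:5], alpha = 1),
               class = "cs_config_error")
})

test_that("planted synchronized block dominates the pair ranking", {
  cfg <- synth_config(seed = 27, n_regions = 5, n_genes_per_region = 120,
                      n_subjects = 40,
                      planted_sync = list(list(regions = c(2L, 4L),
                                               size = c(50L, 50L),
                                               rho = 0.9)))
  gx <- generate_region_expression(cfg)
  rs <- residualize_expression(gx$expression)
  tt <- ttc_all_pairs(rs, alpha = 1e-8)
  counts <- attr(tt, "counts")
  top <- counts$pair[which.max(counts$count)]
  blk <- gx$truth$sync_blocks[[1]]
  expect_equal(top, pair_id(blk$regionA, blk$regionB))
  # the dominant pair count is driven by the planted block
  planted_res <- tt[[top]]
  in_block <- planted_res$pairs$geneA %in% blk$genesA &
    planted_res$pairs$geneB %in% blk$genesB
  expect_gt(mean(in_block), 0.95)
})

test_that("a correlated gene block at rho 0.9 is retained at the genome-wide threshold", {
  # expected retention rate over replicated plantings (n = 40, 50x50 block)
  fr <- vapply(1:5, function(s) {
    set.seed(900 + s)
    n <- 40
    f <- rnorm(n)
    mk <- function() sqrt(0.9) * matrix(rep(f, 50), 50, n, byrow = TRUE) +
      sqrt(0.1) * matrix(rnorm(50 * n), 50, n)
    A <- mk(); B <- mk()
    colnames(A) <- colnames(B) <- sprintf("s%02d", 1:n)
    ttc_pairs(A, B, alpha = 1e-8)$count / 2500
  }, numeric(1))
  expect_gte(mean(fr), 0.9)
})

test_that("top-decile Fisher test matches the hypergeometric tail oracle", {
  # table [[10, 4], [54, 68]]: 14 top pairs, 64 in class, N = 136
  p_oracle <- hyper_tail_oracle(10, K = 64, N = 136, n = 14)
  counts <- data.frame(pair = sprintf("p%03d", 1:136),
                       count = c(rep(100, 14), rep(1, 122)))
  bound <- c(rep(TRUE, 10), rep(FALSE, 4),
             rep(TRUE, 54), rep(FALSE, 68))
  classes <- data.frame(pair = counts$pair, bound = bound,
                        ad_bound = FALSE)
  # make the top-14 counts distinct so ties cannot reorder
  counts$count[1:14] <- 200:187
  enr <- top_decile_enrichment(counts, classes, "bound")
  expect_equal(enr$cut, 14)
  expect_equal(enr$p, p_oracle, tolerance = 1e-12)
  # extreme table: all top pairs in class, none elsewhere
  classes2 <- data.frame(pair = counts$pair,
                         bound = c(rep(TRUE, 14), rep(FALSE, 122)),
                         ad_bound = FALSE)
  enr2 <- top_decile_enrichment(counts, classes2, "bound")
  expect_equal(enr2$p, hyper_tail_oracle(14, 14, 136, 14), tolerance = 1e-12)
  # degenerate class
  classes3 <- data.frame(pair = counts$pair, bound = TRUE, ad_bound = FALSE)
  expect_warning(res3 <- top_decile_enrichment(counts, classes3, "bound"))
  expect_equal(res3$p, 1)
})
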
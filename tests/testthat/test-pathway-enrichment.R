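toy_db <- function(n_pathways = 10, universe = sprintf("g%03d", 1:300),
                   seed = 1, categories = NULL) {
  set.seed(seed)
  ids <- sprintf("PW%02d", seq_len(n_pathways))
  sets <- lapply(seq_len(n_pathways), function(i) sample(universe, 20))
  names(sets) <- ids
  if (is.null(categories))
    categories <- rep(c("signaling", "metabolism"),
                      length.out = n_pathways)
  pathway_db(sets, data.frame(
    pathway_id = ids, name = ids, category = categories,
    signaling_subtype = ifelse(categories == "signaling", "immune", "none"),
    stringsAsFactors = FALSE), background_n = length(universe))
}

test_that("Fisher enrichment equals direct hypergeometric tail summation", {
  # canonical example: N = 100, pathway 10, list 5, overlap 3
  r <- fisher_enrichment(paste0("g", 1:5),
                         c(paste0("g", 1:3), paste0("h", 1:7)), 100)
  expect_equal(r$overlap, 3)
  expect_equal(r$p, hyper_tail_oracle(3, 10, 100, 5), tolerance = 1e-12)
  expect_equal(r$p, 6.64e-3, tolerance = 5e-3)
  # random tables with N <= 200: matches the oracle and fisher.test
  set.seed(51)
  for (rep in 1:25) {
    N <- sample(20:200, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    a <- sample(max(0, n - (N - K)):min(K, n), 1)
    genes <- paste0("x", seq_len(N))
    lst <- c(paste0("x", seq_len(a), recycle0 = TRUE),
             paste0("y", seq_len(n - a), recycle0 = TRUE))          # n - a outside pathway
    pw <- c(paste0("x", seq_len(a), recycle0 = TRUE), paste0("z", seq_len(K - a), recycle0 = TRUE))
    r <- fisher_enrichment(lst, pw, N)
    expect_equal(r$p, hyper_tail_oracle(a, K, N, n), tolerance = 1e-10)
    ft <- fisher.test(matrix(c(a, n - a, K - a, N - K - (n - a)), 2,
                             byrow = TRUE), alternative = "greater")
    expect_equal(r$p, ft$p.value, tolerance = 1e-8)
  }
})

test_that("degenerate enrichment inputs behave as specified", {
  # list equal to the pathway with a barely larger background: minimal p
  r <- fisher_enrichment(paste0("g", 1:5), paste0("g", 1:5), 6)
  expect_equal(r$p, hyper_tail_oracle(5, 5, 6, 5), tolerance = 1e-12)
  # proportional overlap carries no evidence of enrichment
  r2 <- fisher_enrichment(c("x1", paste0("y", 1:9)),
                          c("x1", paste0("z", 1:9)), 100)
  expect_gte(r2$p, 0.5)
  expect_warning(r3 <- fisher_enrichment(character(0), "g1", 10))
  expect_equal(r3$p, 1)
})

test_that("enrich_all records tests, keeps totals coherent, and controls the null", {
  db <- toy_db(n_pathways = 50, seed = 52)
  set.seed(53)
  pooled <- lapply(1:8, function(i)
    list(ROI1 = sample(sprintf("g%03d", 1:300), 25),
         ROI2 = sample(sprintf("g%03d", 1:300), 25)))
  names(pooled) <- sprintf("r%d|s%d", 1:8, 1:8)
  em <- enrich_all(pooled, db)
  expect_equal(em$totals$tests, 50 * 8)
  expect_lte(em$totals$significant, em$totals$tests)
  expect_lte(em$totals$covered_pathways, 50)
  # random draws from the background: significant fraction bounded
  expect_lte(em$totals$significant / em$totals$tests,
             0.05 + 3 * sqrt(0.05 * 0.95 / em$totals$tests))
  # planted pathway-loaded module: significant on both sides
  pooled2 <- list("a|b" = list(ROI1 = db$sets[["PW01"]],
                               ROI2 = db$sets[["PW01"]]))
  em2 <- enrich_all(pooled2, db)
  w <- em2$long[em2$long$pathway == "PW01", ]
  expect_true(all(w$sig))
})

test_that("synchronization typing distinguishes one-sided from two-sided enrichment", {
  db <- toy_db(n_pathways = 6, seed = 54)
  pooled <- list("a|b" = list(ROI1 = db$sets[["PW01"]],
                              ROI2 = db$sets[["PW02"]]))
  em <- enrich_all(pooled, db)
  st <- synchronization_type(em)
  get <- function(pw) st$type[st$pair == "a|b" & st$pathway == pw]
  expect_equal(get("PW01"), "asymmetric")
  expect_equal(get("PW02"), "asymmetric")
  sym_pooled <- list("a|b" = list(ROI1 = db$sets[["PW03"]],
                                  ROI2 = db$sets[["PW03"]]))
  st2 <- synchronization_type(enrich_all(sym_pooled, db))
  expect_equal(st2$type[st2$pathway == "PW03"], "symmetric")
  expect_true(all(st2$type[st2$pathway == "PW06"] == "none"))
})

test_that("category fraction reproduces printed-ratio arithmetic and the catalog edge case", {
  # 83 enriched pathways, 51 of them signaling, catalog of 169
  cats <- c(rep("signaling", 80), rep("metabolism", 89))
  db <- toy_db(n_pathways = 169, seed = 55, categories = cats)
  ids <- db$info$pathway_id
  enriched <- c(ids[1:51], ids[81:112])    # 51 signaling + 32 others = 83
  long <- data.frame(pair = "a|b", side = "ROI1", pathway = ids,
                     p = 1, q = 1, sig = ids %in% enriched,
                     stringsAsFactors = FALSE)
  em <- structure(list(long = long,
                       totals = list(tests = 169, significant = 83,
                                     pct_significant = 100 * 83 / 169,
                                     covered_pathways = 83,
                                     covered_pairs = 1),
                       fdr = 0.05, pathways = ids, pairs = "a|b"),
                  class = "enrichment_matrix")
  cf <- category_fraction_test(em, db, "signaling")
  expect_equal(cf$n_enriched, 83)
  expect_equal(cf$n_in_category, 51)
  expect_equal(cf$pct, 100 * 51 / 83, tolerance = 1e-12)
  expect_equal(round(cf$pct, 1), 61.4)
  # enriched set = the entire catalog: fraction is the catalog share, p = 1
  long2 <- long; long2$sig <- TRUE
  em2 <- em; em2$long <- long2
  cf2 <- category_fraction_test(em2, db, "signaling")
  expect_equal(cf2$fraction, 80 / 169)
  expect_equal(cf2$p, 1)
  expect_error(category_fraction_test(em, db, "astrology"),
               class = "cs_lookup_error")
})

test_that("pathway DB round-trips through GMT and category TSV with exclusion filter", {
  db <- toy_db(n_pathways = 12, seed = 56)
  gmt <- tempfile(fileext = ".gmt"); cat_f <- tempfile(fileext = ".tsv")
  write_pathway_db(db, gmt, cat_f)
  back <- read_pathway_db(gmt, cat_f, background_n = db$background_n,
                          exclude = "PW02")
  expect_setequal(names(back$sets), setdiff(names(db$sets), "PW02"))
  expect_identical(back$sets[["PW05"]], db$sets[["PW05"]])
  expect_equal(back$info$category[back$info$pathway_id == "PW03"],
               db$info$category[db$info$pathway_id == "PW03"])
})
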
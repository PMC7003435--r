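#' Pathway catalog with category annotations
#'
#' @param sets named list of gene-id character vectors
#' @param info data.frame(pathway_id, name, category, signaling_subtype);
#'   categories come from the eight-way scheme (biosynthesis, signaling,
#'   disease, physiology, development, gene regulation, metabolism,
#'   catabolism); `signaling_subtype` is "none" for non-signaling pathways
#'   except the documented ligand-producing exceptions
#' @param background_n background gene-universe size for enrichment (20996,
#'   the human protein-coding default)
#' @return a `pathway_db`
#' @export
pathway_db <- function(sets, info, background_n = 20996L) {
  stopifnot(is.list(sets), length(sets) == nrow(info),
            all(names(sets) == info$pathway_id))
  if (any(lengths(sets) == 0))
    stop_cs("pathway gene sets must be non-empty", "cs_config_error")
  structure(list(sets = sets, info = info,
                 background_n = as.integer(background_n)),
            class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("<pathway_db> %d pathways (background %d genes)\n",
              length(x$sets), x$background_n))
  print(table(x$info$category))
  invisible(x)
}

# Drosophila-specific pathway ids excluded from the curated catalog at load
drosophila_pathways <- c("P06209", "P06211", "P06212", "P06213", "P06214",
                         "P06215", "P06216", "P06217")

#' Read a pathway catalog from GMT + category table
#'
#' @param gmt_file GMT gene-set file
#' @param category_file TSV with columns pathway_id, category,
#'   signaling_subtype (and optionally name)
#' @param background_n background universe size
#' @param exclude pathway ids dropped at load (defaults to the
#'   Drosophila-specific set)
#' @return a [pathway_db()]
#' @export
read_pathway_db <- function(gmt_file, category_file,
                            background_n = 20996L,
                            exclude = drosophila_pathways) {
  sets <- fgsea::gmtPathways(gmt_file)
  info <- data.table::fread(category_file, data.table = FALSE)
  stopifnot(all(c("pathway_id", "category") %in% names(info)))
  if (!"signaling_subtype" %in% names(info)) info$signaling_subtype <- "none"
  if (!"name" %in% names(info)) info$name <- info$pathway_id
  keep <- setdiff(intersect(names(sets), info$pathway_id), exclude)
  info <- info[match(keep, info$pathway_id),
               c("pathway_id", "name", "category", "signaling_subtype")]
  pathway_db(sets[keep], info, background_n)
}

#' Write a pathway catalog to GMT + category TSV
#'
#' @param db a [pathway_db()]
#' @param gmt_file,category_file output paths
#' @export
write_pathway_db <- function(db, gmt_file, category_file) {
  lines <- vapply(names(db$sets), function(id)
    paste(c(id, id, db$sets[[id]]), collapse = "\t"), character(1))
  writeLines(lines, gmt_file)
  data.table::fwrite(db$info, category_file, sep = "\t")
  invisible(NULL)
}

#' One-sided Fisher over-representation test
#'
#' Tests over-representation of `gene_list` in `pathway_genes` against a
#' background universe of `background_n` genes via the hypergeometric upper
#' tail (equivalent to the one-sided greater Fisher exact test on the 2x2
#' in-list x in-pathway table).
#'
#' @param gene_list character vector of query genes
#' @param pathway_genes character vector of pathway member genes
#' @param background_n background universe size
#' @return list(p, odds_ratio, overlap, table)
#' @export
fisher_enrichment <- function(gene_list, pathway_genes, background_n) {
  gene_list <- unique(gene_list); pathway_genes <- unique(pathway_genes)
  if (!length(gene_list)) {
    warning("empty gene list; p set to 1")
    return(list(p = 1, odds_ratio = NA_real_, overlap = 0L, table = NULL))
  }
  if (background_n < length(gene_list))
    stop_cs("background smaller than the gene list", "cs_config_error")
  a <- length(intersect(gene_list, pathway_genes))
  b <- length(gene_list) - a
  c_ <- length(pathway_genes) - a
  d <- background_n - a - b - c_
  p <- phyper(a - 1, length(pathway_genes), background_n - length(pathway_genes),
              length(gene_list), lower.tail = FALSE)
  or <- (a * d) / (b * c_)
  list(p = p, odds_ratio = or, overlap = a,
       table = matrix(c(a, b, c_, d), 2, byrow = TRUE,
                      dimnames = list(list = c("in", "out"),
                                      pathway = c("in", "out"))))
}

# vectorized hypergeometric upper-tail p for one gene list over all pathways
enrich_one_list <- function(genes, db) {
  genes <- unique(genes)
  K <- lengths(db$sets)
  a <- vapply(db$sets, function(s) length(intersect(genes, s)), integer(1))
  phyper(a - 1, K, db$background_n - K, length(genes), lower.tail = FALSE)
}

#' Pathway over-representation across all region pairs
#'
#' Tests every pathway against the pooled module gene list of each side of
#' each region pair, applies Benjamini-Hochberg FDR within each list (across
#' pathways), and binarizes at `q < fdr`.
#'
#' @param pooled named list keyed by region-pair id; each element is
#'   list(ROI1 = genes, ROI2 = genes) (e.g. a [select_modules()] `pooled`
#'   element, bottom -> ROI1, top -> ROI2)
#' @param db a [pathway_db()]
#' @param fdr binarization threshold on q
#' @return an `enrichment_matrix`: list(long = data.frame(pair, side,
#'   pathway, p, q, sig), totals)
#' @export
enrich_all <- function(pooled, db, fdr = 0.05) {
  stopifnot(inherits(db, "pathway_db"))
  ids <- names(db$sets)
  rows <- lapply(names(pooled), function(pr) {
    do.call(rbind, lapply(c("ROI1", "ROI2"), function(side) {
      genes <- pooled[[pr]][[side]]
      p <- if (length(genes)) enrich_one_list(genes, db)
           else rep(1, length(ids))
      q <- p.adjust(p, method = "BH")
      data.frame(pair = pr, side = side, pathway = ids, p = p, q = q,
                 sig = q < fdr, stringsAsFactors = FALSE, row.names = NULL)
    }))
  })
  long <- do.call(rbind, rows)
  pair_sig <- with(long, tapply(sig, list(pair, pathway), any))
  n_sig <- sum(pair_sig, na.rm = TRUE)
  totals <- list(
    tests = length(ids) * length(pooled),
    significant = n_sig,
    pct_significant = 100 * n_sig / (length(ids) * length(pooled)),
    covered_pathways = length(unique(long$pathway[long$sig])),
    covered_pairs = length(unique(long$pair[long$sig])))
  structure(list(long = long, totals = totals, fdr = fdr,
                 pathways = ids, pairs = names(pooled)),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  t <- x$totals
  cat(sprintf("<enrichment_matrix> %d tests, %d significant (%.1f%%), %d pathways x %d pairs covered\n",
              t$tests, t$significant, t$pct_significant,
              t$covered_pathways, t$covered_pairs))
  invisible(x)
}

#' Classify pathway-by-pair synchronization symmetry
#'
#' A pathway is symmetrically synchronized in a region pair when it is
#' enriched on both sides, asymmetrically when on exactly one.
#'
#' @param em an [enrich_all()] result
#' @return data.frame(pair, pathway, type) with type in none / asymmetric /
#'   symmetric
#' @export
synchronization_type <- function(em) {
  stopifnot(inherits(em, "enrichment_matrix"))
  w <- em$long
  s1 <- w[w$side == "ROI1", c("pair", "pathway", "sig")]
  s2 <- w[w$side == "ROI2", c("pair", "pathway", "sig")]
  m <- merge(s1, s2, by = c("pair", "pathway"), suffixes = c("1", "2"))
  m$type <- ifelse(m$sig1 & m$sig2, "symmetric",
                   ifelse(m$sig1 | m$sig2, "asymmetric", "none"))
  m[, c("pair", "pathway", "type")]
}

#' Category share of enriched pathways
#'
#' Fraction of distinct enriched pathways falling in a category, with a
#' one-sided Fisher exact test of category over-representation among
#' enriched pathways relative to the full catalog.
#'
#' @param em an [enrich_all()] result
#' @param db the matching [pathway_db()]
#' @param category category name (e.g. "signaling")
#' @param alternative Fisher sidedness
#' @return list(fraction, pct, n_enriched, n_in_category, p, table)
#' @export
category_fraction_test <- function(em, db, category = "signaling",
                                   alternative = "greater") {
  stopifnot(inherits(em, "enrichment_matrix"), inherits(db, "pathway_db"))
  if (!category %in% db$info$category)
    stop_cs(sprintf("category '%s' absent from the pathway DB", category),
            "cs_lookup_error")
  enriched <- unique(em$long$pathway[em$long$sig])
  if (!length(enriched))
    stop_cs("no enriched pathways", "cs_config_error")
  in_cat <- db$info$pathway_id[db$info$category == category]
  a <- length(intersect(enriched, in_cat))
  b <- length(enriched) - a
  c_ <- length(setdiff(in_cat, enriched))
  d <- nrow(db$info) - a - b - c_
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(enriched = c("yes", "no"),
                                category = c("in", "out")))
  p <- stats::fisher.test(tab, alternative = alternative)$p.value
  list(fraction = a / length(enriched), pct = 100 * a / length(enriched),
       n_enriched = length(enriched), n_in_category = a, p = p, table = tab)
}
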
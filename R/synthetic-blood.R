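gene_universe <- function(config) sprintf("gene%04d", seq_len(max(
  config$n_genes_per_region, config$n_blood_genes)))

pathway_categories <- c("biosynthesis", "signaling", "disease", "physiology",
                        "development", "gene regulation", "metabolism",
                        "catabolism")
signaling_subtypes <- c("synaptic", "immune", "synaptic-immune", "endocrine",
                        "unclassified")

#' Generate a synthetic curated-pathway catalog
#'
#' Pathway gene sets are sampled from the synthetic gene universe; each
#' pathway carries one of eight categories, and signaling pathways carry a
#' signaling subtype. The blood target gene set (`config$geneset_effect$set`)
#' is always present as an immune-signaling pathway of `config$geneset_size`
#' genes drawn from the blood gene universe.
#'
#' @param config a [synth_config()]
#' @return a `pathway_db`: list(sets, info, background_n)
#' @export
generate_pathway_db <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(stream_seed(config$seed, 6L))
  universe <- gene_universe(config)
  n <- config$n_pathways
  ids <- sprintf("SYN%05d", seq_len(n))
  cats <- sample(pathway_categories, n, replace = TRUE,
                 prob = c(0.10, 0.35, 0.08, 0.08, 0.10, 0.09, 0.12, 0.08))
  subt <- ifelse(cats == "signaling",
                 sample(signaling_subtypes, n, replace = TRUE,
                        prob = c(0.30, 0.25, 0.10, 0.15, 0.20)), "none")
  sizes <- sample(10:60, n, replace = TRUE)
  sets <- lapply(sizes, function(s) sort(sample(universe, s)))
  # target set: fixed id, immune signaling, drawn from the blood universe
  ids[1] <- config$geneset_effect$set
  cats[1] <- "signaling"; subt[1] <- "immune"
  sets[[1]] <- sort(sample(universe[seq_len(config$n_blood_genes)],
                           config$geneset_size))
  names(sets) <- ids
  # background = synthetic gene universe, so null enrichment is calibrated
  pathway_db(sets,
             data.frame(pathway_id = ids, name = ids, category = cats,
                        signaling_subtype = subt, stringsAsFactors = FALSE),
             background_n = length(universe))
}

#' Generate a synthetic blood expression dataset with a planted gene-set
#' effect
#'
#' Produces a probe x subject matrix (several probes per gene plus a few
#' unmapped probes), a probe-to-gene map, subject covariates (sex, age, RIN,
#' plate), a pathway catalog containing the target gene set, and diffusion
#' measures for the same subjects in which the designated measure carries the
#' configured per-gene effect of the target set's summed expression.
#'
#' @param config a [synth_config()]
#' @param db optional `pathway_db`; generated from the config when NULL
#' @return list(probes, probe_map, covariates, measures, db, truth)
#' @export
generate_blood_dataset <- function(config, db = NULL) {
  stopifnot(inherits(config, "synth_config"))
  if (is.null(db)) db <- generate_pathway_db(config)
  ge <- config$geneset_effect
  if (!ge$set %in% names(db$sets))
    stop_cs(sprintf("target gene set '%s' is not in the pathway DB", ge$set),
            "cs_config_error")
  set.seed(stream_seed(config$seed, 5L))
  n <- config$n_blood_subjects
  genes <- gene_universe(config)[seq_len(config$n_blood_genes)]
  subjects <- sprintf("B%03d", seq_len(n))
  cov <- data.frame(
    subject = subjects,
    sex = factor(sample(c("F", "M"), n, replace = TRUE)),
    age = round(rnorm(n, 73.5, 6.8), 1),
    rin = round(rnorm(n, 7, 0.5), 2),
    plate = factor(sample(paste0("plate", 1:4), n, replace = TRUE)),
    stringsAsFactors = FALSE)
  if (nlevels(droplevels(cov$sex)) < 2) cov$sex[1] <- setdiff(c("F", "M"), cov$sex[1])
  if (length(unique(cov$plate)) < 2) cov$plate[1:2] <- paste0("plate", 1:2)
  cov$plate <- factor(as.character(cov$plate))

  zage <- as.numeric(scale(cov$age)); zsex <- as.numeric(cov$sex == "M")
  zrin <- as.numeric(scale(cov$rin))
  P <- model.matrix(~ plate, cov)[, -1, drop = FALSE]
  G <- length(genes)
  X <- matrix(rnorm(G * n), G, n, dimnames = list(genes, subjects))
  X <- X + outer(rnorm(G, 0, 0.1), zage) + outer(rnorm(G, 0, 0.1), zsex) +
    outer(rnorm(G, 0, 0.2), zrin) +
    matrix(rnorm(G * ncol(P), 0, 0.3), G, ncol(P)) %*% t(P)

  # probes: variable count per gene plus a handful of unmapped probes
  k <- sample(seq(config$probe_range[1], config$probe_range[2]), G,
              replace = TRUE)
  probe_gene <- rep(genes, k)
  n_unmapped <- 5L
  probe_gene <- c(probe_gene, rep(NA_character_, n_unmapped))
  probes <- sprintf("probe%05d", seq_along(probe_gene))
  pm <- matrix(rnorm(length(probes) * n, 0, 0.3), length(probes), n,
               dimnames = list(probes, subjects))
  mapped <- !is.na(probe_gene)
  pm[mapped, ] <- pm[mapped, ] + X[probe_gene[mapped], ]
  probe_map <- data.frame(probe = probes, gene = probe_gene,
                          stringsAsFactors = FALSE)

  # diffusion measures; the designated one carries the planted set effect
  set_genes <- db$sets[[ge$set]]
  score <- colSums(X[set_genes, , drop = FALSE]) / sqrt(length(set_genes))
  tracts <- union(ge$tract, head(config$tracts, 6))
  meas <- data.frame(subject = subjects, stringsAsFactors = FALSE)
  for (tr in tracts) for (ms in diffusion_measures) {
    val <- 0.2 * zage + 0.1 * zsex + rnorm(n, 0, config$noise_sd)
    if (tr == ge$tract && ms == ge$measure) val <- val + ge$effect * score
    meas[[paste(tr, ms, sep = ".")]] <- val
  }
  list(probes = pm, probe_map = probe_map, covariates = cov, measures = meas,
       db = db,
       truth = list(set = ge$set, tract = ge$tract, measure = ge$measure,
                    effect = ge$effect, set_genes = set_genes))
}
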
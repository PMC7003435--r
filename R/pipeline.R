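#' Default expression-region to atlas-ROI map for synthetic data
#'
#' Region index i maps to ROI label i + 1, mirroring how
#' [generate_label_volume()] assigns labels.
#'
#' @param config a [synth_config()]
#' @return data.frame(region, roi)
#' @export
default_region_map <- function(config) {
  data.frame(region = config$regions,
             roi = seq_len(config$n_regions) + 1L,
             stringsAsFactors = FALSE)
}

#' Run the full synthetic-to-results pipeline
#'
#' Generates every input from one config, then runs: reach-probability
#' matrix -> connection threshold -> region-pair classification -> TTC ->
#' bipartite modules -> pathway enrichment -> pathway interaction -> blood
#' gene-set association. Intended for smoke-level end-to-end runs at desk
#' scale; each stage is also exposed individually.
#'
#' @param config a [synth_config()]
#' @param ttc_alpha TTC retention threshold
#' @param min_edges module-size filter (strict >)
#' @param threshold_mode,cutoff passed to [connection_threshold()]
#' @param n_perm blood permutation count
#' @param out_dir when non-NULL, write volumes, tables and truth there
#' @return list with every intermediate stage
#' @export
run_pipeline <- function(config, ttc_alpha = 1e-8, min_edges = 100L,
                         threshold_mode = "ecdf_reflection", cutoff = NULL,
                         n_perm = 499L, out_dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  labels <- generate_label_volume(config)
  tracts <- generate_tract_volumes(config, labels)
  rm <- reach_matrix(tracts, labels)
  conn <- connection_threshold(rm, mode = threshold_mode, cutoff = cutoff)
  classes <- classify_region_pairs(conn, default_region_map(config))

  gx <- generate_region_expression(config)
  resid <- residualize_expression(gx$expression)
  ttc <- ttc_all_pairs(resid, alpha = ttc_alpha)
  counts <- attr(ttc, "counts")
  decile <- top_decile_enrichment(counts, classes, "bound")

  db <- generate_pathway_db(config)
  pooled <- lapply(ttc, function(res) {
    if (!nrow(res$pairs)) return(list(ROI1 = character(0),
                                      ROI2 = character(0)))
    g <- bipartite_graph(res$pairs)
    lab <- lpab_plus(g, n_restarts = 5L, seed = config$seed)
    ms <- select_modules(lab, g, min_edges = min_edges)
    list(ROI1 = ms$pooled$bottom, ROI2 = ms$pooled$top)
  })
  em <- enrich_all(pooled, db)
  props <- group_proportions(em, classes)
  chisq <- if (props[["tract-bound"]]$n >= 2 && props[["not-bound"]]$n >= 2)
    chisq_compare(props, "tract-bound") else NULL
  graph <- if (!is.null(chisq)) build_interaction_graph(chisq$p) else NULL

  blood <- generate_blood_dataset(config, db)
  collapsed <- mean_max_collapse(blood$probes, blood$probe_map)
  ge <- config$geneset_effect
  scan_col <- paste(ge$tract, ge$measure, sep = ".")
  perm <- sumchisq_permutation(
    collapsed[intersect(blood$truth$set_genes, rownames(collapsed)), ,
              drop = FALSE],
    blood$measures[[scan_col]], blood$covariates,
    n_perm = n_perm, seed = stream_seed(config$seed, 9L))

  out <- list(config = config, labels = labels, tracts = tracts,
              reach = rm, connections = conn, classes = classes,
              ttc = ttc, ttc_counts = counts, decile = decile,
              pooled = pooled, enrichment = em, proportions = props,
              chisq = chisq, interaction_graph = graph,
              blood = blood, collapsed = collapsed, blood_perm = perm)
  if (!is.null(out_dir)) write_pipeline_outputs(out, gx, out_dir)
  out
}

write_pipeline_outputs <- function(out, gx, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_label_volume(out$labels, file.path(out_dir, "labels.nii.gz"))
  for (tn in names(out$tracts))
    write_tract_volume(out$tracts[[tn]],
                       file.path(out_dir, paste0("tract_", gsub("[^A-Za-z0-9]", "_", tn), ".nii.gz")))
  write_matrix_tsv(unclass(out$reach), file.path(out_dir, "reach.tsv"))
  data.table::fwrite(out$ttc_counts, file.path(out_dir, "ttc_counts.tsv"),
                     sep = "\t")
  data.table::fwrite(out$classes, file.path(out_dir, "classes.tsv"),
                     sep = "\t")
  data.table::fwrite(out$enrichment$long,
                     file.path(out_dir, "enrichment.tsv"), sep = "\t")
  invisible(out_dir)
}
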
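#' Canonical tract and region catalogs
#'
#' The 18 major white-matter tracts produced by probabilistic tractography
#' and the 17 left-hemisphere post-mortem sampling regions used throughout
#' the package. `ad_tracts_default` lists the four tracts whose diffusion
#' measures replicate an association with diagnosis across cohorts.
#'
#' @format character vectors
#' @export
tract_names <- c(
  "FMajor", "FMinor", "L-ATR", "L-CAB", "L-CCG", "L-CST", "L-ILF", "L-SLFP",
  "L-SLFT", "L-UNC", "R-ATR", "R-CAB", "R-CCG", "R-CST", "R-ILF", "R-SLFP",
  "R-SLFT", "R-UNC")

#' @rdname tract_names
#' @export
region_names <- c(
  "FP", "OVC", "ITG", "MTG", "STG", "PCC", "ACC", "PHG", "TP", "PCG", "IFC",
  "DLPFC", "SPL", "PFC", "CN", "HIP", "PUT")

#' @rdname tract_names
#' @export
ad_tracts_default <- c("L-CAB", "L-ILF", "L-SLFT", "L-SLFP")

#' @rdname tract_names
#' @export
diffusion_measures <- c("volume", "length", "AxD", "RD", "MD", "FA")

# Default tract -> connected-region-index sets. The four disease-associated
# tracts bind 43 distinct region pairs; the six other connected tracts add 21
# more, so of the 136 pairs 64 are tract-bound and 72 are not-bound.
default_tract_regions <- function() {
  list(
    "L-CAB"  = 1:7,
    "L-ILF"  = 7:13,
    "L-SLFT" = c(1L, 8L),
    "L-SLFP" = c(1L, 2L),
    "FMajor" = 13:17,
    "FMinor" = c(1L, 2L, 3L, 14L),
    "L-ATR"  = c(4L, 5L, 15L),
    "L-CCG"  = c(6L, 16L, 17L),
    "L-CST"  = c(8L, 9L, 14L),
    "L-UNC"  = c(10L, 15L, 16L))
}

default_planted_connections <- function(n_rois, tracts) {
  sets <- default_tract_regions()
  sets <- sets[names(sets) %in% tracts]
  rows <- lapply(names(sets), function(tr) {
    regions <- sets[[tr]]
    rois <- regions + 1L              # region i maps to ROI label i + 1
    rois <- rois[rois <= n_rois + 1L]
    if (!length(rois)) return(NULL)
    data.frame(tract = tr, roi = rois,
               fraction = 0.6 / length(rois), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

default_diagnosis_effects <- function() {
  data.frame(
    tract = c("L-CAB", "L-ILF", "L-SLFT", "L-SLFP", "R-CAB", "R-SLFT",
              "L-CAB", "R-CAB", "L-CAB", "R-CAB", "L-CAB"),
    measure = c(rep("AxD", 6), "MD", "MD", "RD", "RD", "FA"),
    beta = c(rep(0.5, 10), -0.5),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic-data generators
#'
#' One object drives every generator so that a single master seed reproduces
#' the full set of inputs. Defaults mirror the study conditions the pipeline
#' was designed around: 18 tracts reaching 82 atlas ROIs, 17 expression
#' regions (136 region pairs), 30--51 shared post-mortem subjects (40 by
#' default), a 499-subject discovery imaging cohort with diagnosis mix
#' 347/118/34 (CN/MCI/Dementia), and a 102-subject blood cohort with a
#' 49-gene target set. Gene counts per region default to 200, a desk-scale
#' stand-in for a genome-wide panel.
#'
#' @param seed master integer seed; child seeds per dataset derive via
#'   [stream_seed()]
#' @param grid_shape 3 positive integers, voxel grid
#' @param n_rois number of grey-matter ROI labels (labels 2..n_rois+1)
#' @param n_tracts number of tracts (named from [tract_names])
#' @param planted_connections data.frame(tract, roi, fraction): fraction of a
#'   tract's path mass placed in that ROI's white-matter boundary mask
#' @param leak_rate fraction of tract mass leaked into each unplanted ROI mask
#' @param total_paths total streamline count per tract
#' @param n_regions number of expression regions (mapped to ROIs 2..)
#' @param n_genes_per_region genes simulated per region
#' @param n_subjects shared post-mortem subjects
#' @param planted_sync list of list(regions = c(a, b), size = c(gA, gB),
#'   rho): cross-region correlated gene block planted for that region pair
#' @param covariate_effects named numeric, per-covariate effect scale on
#'   expression
#' @param n_subjects_pheno imaging cohort size
#' @param diag_props named proportions for CN/MCI/Dementia
#' @param diagnosis_effects data.frame(tract, measure, beta) planted
#'   diagnosis effects on diffusion measures
#' @param pheno_covariate_effects named numeric, effects of age/sex/TBV on
#'   diffusion measures
#' @param n_blood_subjects blood cohort size
#' @param n_blood_genes blood gene universe size
#' @param geneset_size size of the planted target gene set
#' @param probe_range integer range of probes per gene
#' @param geneset_effect list(set, tract, measure, effect): per-gene effect of
#'   the target set on the designated diffusion measure
#' @param n_pathways synthetic pathway catalog size
#' @param background_n pathway-enrichment background gene universe size
#' @param noise_sd residual noise standard deviation
#' @return an object of class `synth_config`
#' @export
synth_config <- function(seed = 1L,
                         grid_shape = c(48L, 48L, 24L),
                         n_rois = 82L,
                         n_tracts = 18L,
                         planted_connections = NULL,
                         leak_rate = 0,
                         total_paths = 10000L,
                         n_regions = 17L,
                         n_genes_per_region = 200L,
                         n_subjects = 40L,
                         planted_sync = list(list(regions = c(7L, 8L),
                                                  size = c(50L, 50L),
                                                  rho = 0.9)),
                         covariate_effects = c(age = 0.3, sex = 0.3,
                                               pmi = 0.2, ph = 0.2,
                                               ethnicity = 0.3, braak = 0.3),
                         n_subjects_pheno = 499L,
                         diag_props = c(CN = 347, MCI = 118,
                                        Dementia = 34) / 499,
                         diagnosis_effects = default_diagnosis_effects(),
                         pheno_covariate_effects = c(age = 0.3, sex = 0.2,
                                                     tbv = 0.3),
                         n_blood_subjects = 102L,
                         n_blood_genes = 200L,
                         geneset_size = 49L,
                         probe_range = c(1L, 4L),
                         geneset_effect = list(set = "TOLL_RECEPTOR_SIGNALING",
                                               tract = "L-CAB",
                                               measure = "FA",
                                               effect = 0.5),
                         n_pathways = 169L,
                         background_n = 20996L,
                         noise_sd = 1) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1))
  n_tracts <- as.integer(n_tracts)
  tracts <- if (n_tracts <= length(tract_names)) tract_names[seq_len(n_tracts)]
            else c(tract_names, sprintf("tract%02d", seq_len(n_tracts - length(tract_names))))
  regions <- if (n_regions <= length(region_names)) region_names[seq_len(n_regions)]
             else c(region_names, sprintf("region%02d", seq_len(n_regions - length(region_names))))
  if (is.null(planted_connections))
    planted_connections <- default_planted_connections(n_rois, tracts)
  cfg <- structure(list(
    seed = as.integer(seed), grid_shape = as.integer(grid_shape),
    n_rois = as.integer(n_rois), n_tracts = n_tracts, tracts = tracts,
    planted_connections = planted_connections, leak_rate = leak_rate,
    total_paths = as.integer(total_paths),
    n_regions = as.integer(n_regions), regions = regions,
    n_genes_per_region = as.integer(n_genes_per_region),
    n_subjects = as.integer(n_subjects), planted_sync = planted_sync,
    covariate_effects = covariate_effects,
    n_subjects_pheno = as.integer(n_subjects_pheno),
    diag_props = diag_props, diagnosis_effects = diagnosis_effects,
    pheno_covariate_effects = pheno_covariate_effects,
    n_blood_subjects = as.integer(n_blood_subjects),
    n_blood_genes = as.integer(n_blood_genes),
    geneset_size = as.integer(geneset_size),
    probe_range = as.integer(probe_range),
    geneset_effect = geneset_effect,
    n_pathways = as.integer(n_pathways),
    background_n = as.integer(background_n),
    noise_sd = noise_sd), class = "synth_config")
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  pc <- cfg$planted_connections
  if (!is.null(pc) && nrow(pc)) {
    assert_fraction(pc$fraction, "planted connection fractions")
    bad <- !(pc$tract %in% cfg$tracts)
    if (any(bad))
      stop_cs(sprintf("planted connection references unknown tract '%s'",
                      pc$tract[bad][1]), "cs_config_error")
    if (any(pc$roi < 2 | pc$roi > cfg$n_rois + 1))
      stop_cs("planted connection references ROI label outside 2..n_rois+1",
              "cs_config_error")
    sums <- tapply(pc$fraction, pc$tract, sum)
    if (any(sums > 1 + 1e-12))
      stop_cs(sprintf("planted fractions for tract '%s' sum to %.3f > 1",
                      names(sums)[which.max(sums)], max(sums)),
              "cs_config_error")
  }
  assert_fraction(cfg$leak_rate, "leak_rate")
  for (ps in cfg$planted_sync) {
    if (ps$rho < 0 || ps$rho >= 1)
      stop_cs("planted within-block correlation must lie in [0, 1)",
              "cs_config_error")
    if (any(ps$size > cfg$n_genes_per_region))
      stop_cs("planted block sizes must not exceed n_genes_per_region",
              "cs_config_error")
    if (any(ps$regions < 1 | ps$regions > cfg$n_regions))
      stop_cs("planted sync references unknown region index",
              "cs_config_error")
  }
  if (cfg$noise_sd <= 0)
    stop_cs("noise_sd must be positive", "cs_config_error")
  if (abs(sum(cfg$diag_props) - 1) > 1e-8)
    stop_cs("diag_props must sum to 1", "cs_config_error")
  cfg
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config>\n")
  cat(sprintf("  seed %d | grid %s | %d tracts -> %d ROIs (%d planted connections)\n",
              x$seed, paste(x$grid_shape, collapse = "x"), x$n_tracts,
              x$n_rois, nrow(x$planted_connections %||% data.frame())))
  cat(sprintf("  %d regions x %d genes x %d subjects | %d sync blocks\n",
              x$n_regions, x$n_genes_per_region, x$n_subjects,
              length(x$planted_sync)))
  cat(sprintf("  imaging n=%d | blood n=%d (%d-gene set)\n",
              x$n_subjects_pheno, x$n_blood_subjects, x$geneset_size))
  invisible(x)
}
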
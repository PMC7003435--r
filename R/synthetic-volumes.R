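#' Generate a synthetic labeled brain segmentation
#'
#' Builds a deterministic integer label volume: a central white-matter slab
#' along the third axis, with grey-matter ROI patches tiled on the two layers
#' face-adjacent to the slab. Every ROI therefore has a non-empty
#' white-matter boundary mask by construction. Label 0 is background, 1 is
#' white matter, labels 2..n_rois+1 are ROIs.
#'
#' @param config a [synth_config()]
#' @return a [label_volume()]
#' @export
generate_label_volume <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  d <- config$grid_shape
  if (any(d < 8))
    stop_cs("grid_shape must be at least 8 voxels in every dimension",
            "cs_sizing_error")
  n_rois <- config$n_rois
  if (n_rois < 2) stop_cs("need at least 2 ROIs", "cs_config_error")
  arr <- array(0L, d)
  z1 <- floor(d[3] / 3) + 1L
  z2 <- floor(2 * d[3] / 3)
  arr[, , z1:z2] <- 1L
  # tile ROI patches on layers z1-1 and z2+1
  tile <- 2L
  nx <- d[1] %/% tile; ny <- d[2] %/% tile
  if (2L * nx * ny < n_rois) {
    tile <- 1L
    nx <- d[1]; ny <- d[2]
    if (2L * nx * ny < n_rois)
      stop_cs(sprintf("grid too small to place ROI label %d", n_rois + 1L),
              "cs_sizing_error")
  }
  layers <- c(z1 - 1L, z2 + 1L)
  for (r in seq_len(n_rois)) {
    idx <- r - 1L
    layer <- layers[idx %/% (nx * ny) + 1L]
    cell <- idx %% (nx * ny)
    ix <- (cell %% nx) * tile + 1L
    iy <- (cell %/% nx) * tile + 1L
    arr[ix:(ix + tile - 1L), iy:(iy + tile - 1L), layer] <- r + 1L
  }
  label_volume(arr, wm_label = 1L, roi_labels = seq_len(n_rois) + 1L)
}

#' Generate synthetic tract path-distribution volumes
#'
#' For each tract, a deterministic non-negative count volume supported on
#' white matter plus ROI boundary masks. For each planted (tract, roi,
#' fraction) row of `config$planted_connections`, that fraction of the
#' tract's total path mass is spread uniformly over the ROI's boundary mask;
#' `leak_rate` of the mass goes to each unplanted ROI mask (0 by default);
#' the remainder is spread over the white-matter voxels.
#'
#' @param config a [synth_config()]
#' @param labels a [label_volume()] from [generate_label_volume()]
#' @return named list of 3-D integer count arrays, one per tract
#' @export
generate_tract_volumes <- function(config, labels) {
  stopifnot(inherits(config, "synth_config"), inherits(labels, "label_volume"))
  pc <- config$planted_connections
  if (!is.null(pc) && nrow(pc)) {
    sums <- tapply(pc$fraction, pc$tract, sum)
    if (any(sums + config$leak_rate *
            (config$n_rois - table(pc$tract)[names(sums)]) > 1 + 1e-12))
      stop_cs("planted fractions plus leaks exceed total mass for a tract",
              "cs_config_error")
  }
  masks <- lapply(labels$roi_labels, function(r) which(boundary_mask(labels, r)))
  names(masks) <- as.character(labels$roi_labels)
  wm_idx <- which(labels$values == labels$wm_label)
  total <- config$total_paths

  spread <- function(arr, idx, mass) {
    if (mass <= 0 || !length(idx)) return(arr)
    base <- mass %/% length(idx)
    extra <- mass %% length(idx)
    arr[idx] <- arr[idx] + base
    if (extra > 0) arr[idx[seq_len(extra)]] <- arr[idx[seq_len(extra)]] + 1L
    arr
  }

  out <- lapply(config$tracts, function(tr) {
    arr <- array(0L, dim(labels$values))
    rows <- if (is.null(pc)) pc else pc[pc$tract == tr, , drop = FALSE]
    planted_rois <- character(0)
    used <- 0L
    if (!is.null(rows) && nrow(rows)) {
      for (i in seq_len(nrow(rows))) {
        m <- as.integer(round(rows$fraction[i] * total))
        arr <- spread(arr, masks[[as.character(rows$roi[i])]], m)
        used <- used + m
      }
      planted_rois <- as.character(rows$roi)
    }
    if (config$leak_rate > 0) {
      leak_mass <- as.integer(round(config$leak_rate * total))
      for (r in setdiff(names(masks), planted_rois)) {
        arr <- spread(arr, masks[[r]], leak_mass)
        used <- used + leak_mass
      }
    }
    spread(arr, wm_idx, total - used)
  })
  names(out) <- config$tracts
  out
}
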
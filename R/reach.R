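#' Label volumes
#'
#' A label volume is a 3-D integer array with label 0 = background, a white
#' matter label (1 by default) and grey-matter ROI labels. Constructed
#' directly or by [generate_label_volume()].
#'
#' @param values 3-D integer array
#' @param wm_label white-matter label value
#' @param roi_labels integer vector of grey-matter ROI labels
#' @return a `label_volume`
#' @export
label_volume <- function(values, wm_label = 1L, roi_labels = NULL) {
  stopifnot(length(dim(values)) == 3L)
  storage.mode(values) <- "integer"
  if (is.null(roi_labels))
    roi_labels <- setdiff(sort(unique(as.vector(values))), c(0L, wm_label))
  structure(list(values = values, wm_label = as.integer(wm_label),
                 roi_labels = as.integer(roi_labels)),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat(sprintf("<label_volume> %s, %d ROI labels, WM label %d\n",
              paste(dim(x$values), collapse = "x"), length(x$roi_labels),
              x$wm_label), ...)
  invisible(x)
}

# Logical array of face neighbors (6- or 26-connectivity) of `mask` voxels.
has_neighbor <- function(mask, connectivity = 6L) {
  d <- dim(mask)
  out <- array(FALSE, d)
  shifts6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                   c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  if (connectivity == 6L) {
    shifts <- shifts6
  } else if (connectivity == 26L) {
    shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    shifts <- shifts[rowSums(abs(shifts)) > 0, , drop = FALSE]
  } else stop_cs("connectivity must be 6 or 26", "cs_config_error")
  for (r in seq_len(nrow(shifts))) {
    s <- shifts[r, ]
    src_x <- seq_len(d[1]) - s[1]; src_y <- seq_len(d[2]) - s[2]
    src_z <- seq_len(d[3]) - s[3]
    okx <- src_x >= 1 & src_x <= d[1]; oky <- src_y >= 1 & src_y <= d[2]
    okz <- src_z >= 1 & src_z <= d[3]
    out[okx, oky, okz] <- out[okx, oky, okz] |
      mask[src_x[okx], src_y[oky], src_z[okz]]
  }
  out
}

#' One-voxel-deep ROI boundary mask facing white matter
#'
#' The mask contains exactly the voxels carrying the ROI label that have at
#' least one face-adjacent (6-connectivity by default) white-matter voxel.
#' This restriction to the white-matter border avoids inflating tract-ROI
#' connectivity through within-ROI streamline propagation.
#'
#' @param labels a [label_volume()]
#' @param roi ROI label to extract
#' @param connectivity 6 (faces) or 26 (faces, edges, corners)
#' @return logical 3-D array marking the boundary voxels
#' @export
boundary_mask <- function(labels, roi, connectivity = 6L) {
  stopifnot(inherits(labels, "label_volume"))
  if (!(roi %in% labels$roi_labels))
    stop_cs(sprintf("unknown ROI label %s", roi), "cs_lookup_error")
  wm_adjacent <- has_neighbor(labels$values == labels$wm_label, connectivity)
  (labels$values == roi) & wm_adjacent
}

#' Reach probability of tracts into ROI boundary masks
#'
#' For one tract: the path-count volume is trimmed to its support on white
#' matter plus the union of all ROI boundary masks, per-voxel counts are
#' normalized by the total count over the trimmed support, and the reach
#' probability for an ROI is the mean normalized count over that ROI's
#' boundary mask (zero-count mask voxels included; an empty mask gives 0).
#'
#' @param tract 3-D non-negative count array (paths per voxel)
#' @param labels a [label_volume()]
#' @param rois ROI labels to score (default: all)
#' @param connectivity passed to [boundary_mask()]
#' @return named numeric vector of reach probabilities, one per ROI
#' @export
reach_probability <- function(tract, labels, rois = labels$roi_labels,
                              connectivity = 6L) {
  stopifnot(inherits(labels, "label_volume"),
            identical(dim(tract), dim(labels$values)))
  if (any(tract < 0)) stop_cs("tract counts must be non-negative",
                              "cs_config_error")
  masks <- lapply(rois, function(r) boundary_mask(labels, r, connectivity))
  trim <- labels$values == labels$wm_label
  for (m in masks) trim <- trim | m
  total <- sum(as.numeric(tract[trim]))
  if (total == 0)
    stop_cs("tract has no path mass on the trimmed support (degenerate tract)",
            "cs_degenerate_tract")
  vals <- vapply(masks, function(m) {
    nv <- sum(m)
    if (nv == 0) return(0)
    sum(as.numeric(tract[m])) / total / nv
  }, numeric(1))
  names(vals) <- as.character(rois)
  vals
}

#' Reach-probability matrix over a set of tracts
#'
#' @param tracts named list of path-count arrays
#' @param labels a [label_volume()]
#' @param rois ROI labels (default all)
#' @param connectivity passed to [boundary_mask()]
#' @return tract x ROI numeric matrix of class `reach_matrix`
#' @export
reach_matrix <- function(tracts, labels, rois = labels$roi_labels,
                         connectivity = 6L) {
  rows <- lapply(names(tracts), function(tn) {
    tryCatch(reach_probability(tracts[[tn]], labels, rois, connectivity),
             cs_degenerate_tract = function(e)
               stop_cs(sprintf("tract '%s': %s", tn, conditionMessage(e)),
                       "cs_degenerate_tract"))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(tracts)
  class(m) <- c("reach_matrix", class(m))
  m
}

# Elbow of the sorted non-zero-value ECDF: the point maximizing perpendicular
# distance to the chord joining (0, 0) to (max value, 1). Ties go to the
# smallest abscissa.
ecdf_reflection_point <- function(values) {
  x <- sort(values[values > 0])
  k <- length(x)
  if (k == 0) stop_cs("all entries are zero; no threshold defined",
                      "cs_threshold_error")
  y <- seq_len(k) / k
  cx <- x[k]; cy <- 1
  d <- abs(y * cx - x * cy) / sqrt(cx^2 + cy^2)
  x[which.max(d)]
}

# Method-of-moments Gumbel fit (location mu, scale beta) as a distributional
# diagnostic for the non-zero reach probabilities.
gumbel_fit <- function(values) {
  x <- values[values > 0]
  if (length(x) < 2) return(c(location = NA_real_, scale = NA_real_))
  beta <- sd(x) * sqrt(6) / pi
  c(location = mean(x) - 0.5772156649015329 * beta, scale = beta)
}

#' Threshold a reach-probability matrix into a binary connection set
#'
#' `mode = "ecdf_reflection"` derives the cutoff from the non-zero entries as
#' the elbow of their empirical cumulative distribution (maximum
#' perpendicular distance between the ECDF curve and its chord); `mode =
#' "fixed"` uses the supplied cutoff (0.002 is the reproduction default for
#' real data). Entries `>= cutoff` are connections. A Gumbel (extreme value)
#' fit of the non-zero entries is attached as a diagnostic.
#'
#' @param matrix a [reach_matrix()] (tract x ROI)
#' @param mode "fixed" or "ecdf_reflection"
#' @param cutoff required when `mode = "fixed"`
#' @return a `connection_set`: list(cutoff, connected = binary matrix,
#'   gumbel = c(location, scale))
#' @export
connection_threshold <- function(matrix,
                                 mode = c("ecdf_reflection", "fixed"),
                                 cutoff = NULL) {
  mode <- match.arg(mode)
  if (all(matrix == 0))
    stop_cs("all reach probabilities are zero; cannot threshold",
            "cs_threshold_error")
  if (mode == "fixed") {
    if (is.null(cutoff)) stop_cs("fixed mode requires a cutoff",
                                 "cs_config_error")
  } else {
    cutoff <- ecdf_reflection_point(matrix)
  }
  conn <- (unclass(matrix) >= cutoff) * 1L
  structure(list(cutoff = cutoff, connected = conn,
                 gumbel = gumbel_fit(matrix), mode = mode),
            class = "connection_set")
}

#' @export
print.connection_set <- function(x, ...) {
  cat(sprintf("<connection_set> cutoff %.4g (%s): %d of %d tract-ROI pairs connected\n",
              x$cutoff, x$mode, sum(x$connected), length(x$connected)))
  invisible(x)
}

#' Classify expression-region pairs by white-matter tract binding
#'
#' A region pair (A, B) is tract-bound iff some tract is connected (per the
#' thresholded reach matrix) to an ROI of A and an ROI of B; it is
#' additionally AD-tract-bound when such a tract belongs to `ad_tracts`.
#' AD-tract-bound pairs are a subset of tract-bound pairs; `class` holds the
#' not-bound / tract-bound partition and `ad_bound` the subset flag.
#'
#' @param conn a `connection_set` from [connection_threshold()]
#' @param region_map data.frame(region, roi): expression region to atlas ROI
#'   label; a region may map to several ROIs
#' @param ad_tracts character vector of disease-associated tract ids
#' @return data.frame, one row per unordered region pair, with columns
#'   pair, regionA, regionB, bound, ad_bound, class; attribute "counts" holds
#'   the per-class totals
#' @export
classify_region_pairs <- function(conn, region_map,
                                  ad_tracts = ad_tracts_default) {
  stopifnot(inherits(conn, "connection_set"),
            all(c("region", "roi") %in% names(region_map)))
  regions <- sort(unique(as.character(region_map$region)))
  if (length(regions) < 2)
    stop_cs("need at least two mapped regions", "cs_mapping_error")
  bad_ad <- setdiff(ad_tracts, rownames(conn$connected))
  rois_of <- split(region_map$roi, as.character(region_map$region))
  cm <- conn$connected
  roi_cols <- colnames(cm) %||% as.character(seq_len(ncol(cm)))
  tract_hits <- lapply(regions, function(rg) {
    cols <- match(as.character(rois_of[[rg]]), roi_cols)
    cols <- cols[!is.na(cols)]
    if (!length(cols)) stop_cs(sprintf(
      "region '%s' has no ROI present in the reach matrix", rg),
      "cs_mapping_error")
    rownames(cm)[rowSums(cm[, cols, drop = FALSE]) > 0]
  })
  names(tract_hits) <- regions
  combs <- utils::combn(regions, 2)
  res <- data.frame(
    regionA = combs[1, ], regionB = combs[2, ], stringsAsFactors = FALSE)
  res$pair <- canon_pair_id(res$regionA, res$regionB)
  binding <- mapply(function(a, b) {
    shared <- intersect(tract_hits[[a]], tract_hits[[b]])
    c(bound = length(shared) > 0,
      ad = length(intersect(shared, ad_tracts)) > 0)
  }, res$regionA, res$regionB)
  res$bound <- as.logical(binding["bound", ])
  res$ad_bound <- as.logical(binding["ad", ])
  res$class <- ifelse(res$bound, "tract-bound", "not-bound")
  counts <- c(`not-bound` = sum(!res$bound),
              `tract-bound` = sum(res$bound),
              `AD-tract-bound` = sum(res$ad_bound))
  attr(res, "counts") <- counts
  attr(res, "ad_tracts") <- intersect(ad_tracts, rownames(cm))
  res
}
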
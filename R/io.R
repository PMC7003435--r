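#' Read and write volumes and tables
#'
#' Label and tract volumes travel as NIfTI; matrices and tables as TSV
#' (genes/probes as rows, subjects as columns, header row of ids); the
#' planted-truth record as JSON. Truth files are written separately from
#' data files and no pipeline stage reads them.
#'
#' @param labels a [label_volume()]
#' @param path file path (`.nii` / `.nii.gz` for volumes)
#' @name connectosync-io
NULL

#' @rdname connectosync-io
#' @export
write_label_volume <- function(labels, path) {
  stopifnot(inherits(labels, "label_volume"))
  RNifti::writeNifti(labels$values, path)
  invisible(path)
}

#' @rdname connectosync-io
#' @param wm_label,roi_labels label catalog for the volume being read
#' @export
read_label_volume <- function(path, wm_label = 1L, roi_labels = NULL) {
  v <- RNifti::readNifti(path)
  label_volume(array(as.integer(round(v)), dim(v)), wm_label, roi_labels)
}

#' @rdname connectosync-io
#' @param tract 3-D count array
#' @export
write_tract_volume <- function(tract, path) {
  RNifti::writeNifti(tract, path)
  invisible(path)
}

#' @rdname connectosync-io
#' @export
read_tract_volume <- function(path) {
  v <- RNifti::readNifti(path)
  array(as.numeric(v), dim(v))
}

#' @rdname connectosync-io
#' @param m numeric matrix with dimnames
#' @export
write_matrix_tsv <- function(m, path) {
  d <- data.table::as.data.table(m, keep.rownames = "id")
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

#' @rdname connectosync-io
#' @export
read_matrix_tsv <- function(path) {
  d <- data.table::fread(path, data.table = FALSE, header = TRUE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d[[1]]
  m
}

#' @rdname connectosync-io
#' @param x any JSON-serializable list (e.g. a planted-truth record)
#' @export
write_truth_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
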
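`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed for a named generator stream
#'
#' A single master seed fans out to per-dataset child seeds so that each
#' synthetic dataset is reproducible on its own. The derivation is
#' `master + 97 * stream_index` (kept below 2^31).
#'
#' @param seed master integer seed
#' @param stream integer stream index (>= 1)
#' @return an integer seed
#' @export
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  as.integer((as.numeric(seed) + 97 * as.numeric(stream)) %% .Machine$integer.max)
}

stop_cs <- function(msg, class) {
  stop(structure(class = c(class, "connectosync_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

assert_fraction <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop_cs(sprintf("%s must lie in [0, 1]", what), "cs_config_error")
  invisible(x)
}

canon_pair_id <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Normalized mutual information between two labelings
#'
#' Used to score recovery of planted module structure by community detection.
#' Normalization is by the arithmetic mean of the two label entropies.
#'
#' @param a,b label vectors of equal length
#' @return NMI in [0, 1]; defined as 1 when both labelings are constant
#' @export
nmi <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  ct <- table(a, b)
  pj <- rowSums(ct) / n
  pk <- colSums(ct) / n
  pjk <- ct / n
  hx <- -sum(pj[pj > 0] * log(pj[pj > 0]))
  hy <- -sum(pk[pk > 0] * log(pk[pk > 0]))
  nz <- pjk > 0
  mi <- sum(pjk[nz] * log(pjk[nz] / outer(pj, pk)[nz]))
  denom <- (hx + hy) / 2
  if (denom == 0) return(1)
  mi / denom
}
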
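# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# Benjamini-Hochberg step-up, written from the definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# hypergeometric upper tail P(X >= a) by direct summation with choose()
hyper_tail_oracle <- function(a, K, N, n) {
  ks <- a:min(K, n)
  if (!length(ks) || a > min(K, n)) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# reach probability by naive voxel loops
reach_oracle <- function(tract, labels, roi, connectivity = 6L) {
  d <- dim(labels$values)
  stopifnot(connectivity == 6L)
  is_wm <- function(x, y, z) {
    x >= 1 && x <= d[1] && y >= 1 && y <= d[2] && z >= 1 && z <= d[3] &&
      labels$values[x, y, z] == labels$wm_label
  }
  mask <- array(FALSE, d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    if (labels$values[x, y, z] == roi &&
        (is_wm(x - 1, y, z) || is_wm(x + 1, y, z) || is_wm(x, y - 1, z) ||
         is_wm(x, y + 1, z) || is_wm(x, y, z - 1) || is_wm(x, y, z + 1)))
      mask[x, y, z] <- TRUE
  }
  trim <- labels$values == labels$wm_label
  for (r in labels$roi_labels) {
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      if (labels$values[x, y, z] == r &&
          (is_wm(x - 1, y, z) || is_wm(x + 1, y, z) || is_wm(x, y - 1, z) ||
           is_wm(x, y + 1, z) || is_wm(x, y, z - 1) || is_wm(x, y, z + 1)))
        trim[x, y, z] <- TRUE
    }
  }
  total <- sum(tract[trim])
  if (total == 0) stop("degenerate tract")
  nv <- sum(mask)
  if (nv == 0) return(0)
  mean(tract[mask] / total)
}

# Barber modularity by the literal double sum over bottom x top node pairs
barber_oracle <- function(graph, labels) {
  nb <- length(graph$bottom); nt <- length(graph$top)
  A <- matrix(0, nb, nt)
  A[graph$edges] <- 1
  lb <- labels[seq_len(nb)]; lt <- labels[nb + seq_len(nt)]
  q <- 0
  for (i in seq_len(nb)) for (j in seq_len(nt)) {
    if (lb[i] == lt[j])
      q <- q + A[i, j] - graph$kbot[i] * graph$ktop[j] / graph$m
  }
  q / graph$m
}

# exhaustive maximum of Q_B over all set partitions (restricted growth)
exhaust_qb <- function(graph) {
  nn <- length(graph$bottom) + length(graph$top)
  best <- -Inf
  rec <- function(labels, i, kmax) {
    if (i > nn) {
      q <- barber_modularity(graph, labels)
      if (q > best) best <<- q
      return()
    }
    for (l in seq_len(kmax + 1)) {
      labels[i] <- l
      rec(labels, i + 1L, max(kmax, l))
    }
  }
  rec(integer(nn), 1L, 0L)
  best
}

# planted bipartite block-model edge list plus ground-truth labels
gen_planted_bipartite <- function(seed, nb = 30, k = 3, pin = 0.3,
                                  pout = 0.01) {
  set.seed(seed)
  n <- nb * k
  A <- matrix(rbinom(n * n, 1, pout), n, n)
  for (b in seq_len(k)) {
    i <- ((b - 1) * nb + 1):(b * nb)
    A[i, i] <- matrix(rbinom(nb * nb, 1, pin), nb, nb)
  }
  e <- which(A == 1, arr.ind = TRUE)
  list(pairs = data.frame(geneA = sprintf("a%03d", e[, 1]),
                          geneB = sprintf("b%03d", e[, 2]),
                          stringsAsFactors = FALSE),
       truth_bottom = rep(seq_len(k), each = nb),
       truth_top = rep(seq_len(k), each = nb),
       node_names = list(bottom = sprintf("a%03d", seq_len(n)),
                         top = sprintf("b%03d", seq_len(n))))
}

# randomized p-value for a one-sided hypergeometric test: exactly U(0, 1)
# under the null, removing the conservativeness of the discrete p
randomized_hyper_p <- function(x, K, N, n) {
  p_gt <- hyper_tail_oracle(x + 1, K, N, n)
  p_eq <- hyper_tail_oracle(x, K, N, n) - p_gt
  p_gt + runif(1) * p_eq
}

pair_id <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

# small label volume fixture: WM plane z = 1, two ROI slabs above
toy_labels <- function() {
  arr <- array(0L, c(3, 3, 3))
  arr[, , 1] <- 1L
  arr[, , 2] <- 2L
  arr[, , 3] <- 3L
  label_volume(arr, wm_label = 1L, roi_labels = c(2L, 3L))
}

small_cfg <- function(seed = 1, ...) {
  args <- list(
    seed = seed, grid_shape = c(16, 16, 9), n_rois = 4, n_tracts = 3,
    planted_connections = data.frame(
      tract = c("FMajor", "FMajor", "FMinor"),
      roi = c(2L, 3L, 4L), fraction = c(0.3, 0.2, 0.4)),
    n_regions = 4, n_genes_per_region = 60, n_subjects = 30,
    planted_sync = list(list(regions = c(1L, 2L), size = c(20L, 20L),
                             rho = 0.9)),
    n_blood_subjects = 50, n_blood_genes = 60, geneset_size = 12,
    n_pathways = 30)
  over <- list(...)
  args[names(over)] <- over
  do.call(synth_config, args)
}
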
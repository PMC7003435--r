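#' Bipartite graph of significant TTC gene pairs
#'
#' Bottom nodes are genes of the first region, top nodes genes of the second;
#' each retained TTC gene pair contributes one binary edge. Duplicate edges
#' are collapsed.
#'
#' @param pairs data.frame with columns geneA, geneB (e.g. the `pairs`
#'   element of a [ttc_pairs()] result)
#' @return a `bipartite_graph`: list(bottom, top, edges, m, kbot, ktop,
#'   adj_bottom, adj_top)
#' @export
bipartite_graph <- function(pairs) {
  stopifnot(all(c("geneA", "geneB") %in% names(pairs)))
  if (!nrow(pairs)) stop_cs("graph has no edges", "cs_config_error")
  bottom <- sort(unique(pairs$geneA))
  top <- sort(unique(pairs$geneB))
  e <- unique(cbind(match(pairs$geneA, bottom), match(pairs$geneB, top)))
  nb <- length(bottom); nt <- length(top)
  structure(list(
    bottom = bottom, top = top, edges = e, m = nrow(e),
    kbot = tabulate(e[, 1], nb), ktop = tabulate(e[, 2], nt),
    adj_bottom = split(e[, 2], factor(e[, 1], levels = seq_len(nb))),
    adj_top = split(e[, 1], factor(e[, 2], levels = seq_len(nt)))),
    class = "bipartite_graph")
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat(sprintf("<bipartite_graph> %d x %d nodes, %d edges\n",
              length(x$bottom), length(x$top), x$m))
  invisible(x)
}

#' Barber bipartite modularity
#'
#' `Q_B = (1/m) * sum_{i,j} (A_ij - k_i d_j / m) * delta(label_i, label_j)`
#' where i runs over bottom nodes, j over top nodes, k and d are the
#' side-specific degrees and m the edge count. Compares within-module edges
#' against a degree-preserving bipartite null.
#'
#' @param graph a [bipartite_graph()]
#' @param labels integer module labels over c(bottom, top) nodes
#' @return Q_B in [-1, 1]
#' @export
barber_modularity <- function(graph, labels) {
  stopifnot(inherits(graph, "bipartite_graph"))
  nb <- length(graph$bottom); nt <- length(graph$top)
  if (length(labels) != nb + nt)
    stop_cs("labels must cover all nodes", "cs_config_error")
  if (graph$m == 0) stop_cs("modularity undefined for an empty graph",
                            "cs_config_error")
  lb <- labels[seq_len(nb)]; lt <- labels[nb + seq_len(nt)]
  within <- sum(lb[graph$edges[, 1]] == lt[graph$edges[, 2]])
  K <- rowsum(graph$kbot, lb)
  D <- rowsum(graph$ktop, lt)
  shared <- intersect(rownames(K), rownames(D))
  null_term <- if (length(shared))
    sum(K[shared, 1] * D[shared, 1]) / graph$m else 0
  (within - null_term) / graph$m
}

# sparse module-pair cross-edge counts for the merge stage
module_cross_edges <- function(graph, labels) {
  nb <- length(graph$bottom)
  la <- labels[graph$edges[, 1]]
  lb <- labels[nb + graph$edges[, 2]]
  agg <- rowsum(rep(1L, graph$m), paste(la, lb, sep = "\r"))
  key <- strsplit(rownames(agg), "\r", fixed = TRUE)
  data.frame(from = as.integer(vapply(key, `[`, "", 1L)),
             to = as.integer(vapply(key, `[`, "", 2L)),
             n = as.integer(agg[, 1]))
}

#' Two-stage LPAb+ label propagation maximizing Barber modularity
#'
#' Stage 1 ("bottom-up") initializes each node with a unique label and sweeps
#' nodes in seeded random order; each node adopts the neighbor label that
#' maximizes its own contribution to Q_B (ties to the smallest label id;
#' moves are accepted only when the contribution strictly increases, so Q_B
#' never decreases). Sweeps repeat until one changes nothing. Stage 2
#' ("top-down") greedily merges module pairs that share at least one edge
#' while any merge increases Q_B. The whole procedure runs `n_restarts`
#' times with child seeds `stream_seed(seed, restart)` and the labeling with
#' maximum Q_B wins (ties to the earliest restart).
#'
#' @param graph a [bipartite_graph()]
#' @param n_restarts random restarts (default 5)
#' @param seed master seed
#' @param max_sweeps stage-1 sweep cap (warning when hit)
#' @param trace when TRUE, record Q_B after every sweep and merge (per
#'   restart) in the `q_trace` element; accepted steps never decrease it
#' @return a `bipartite_labeling`: list(labels named by prefixed node id,
#'   q, n_modules, restart_q, q_trace)
#' @export
lpab_plus <- function(graph, n_restarts = 5L, seed = 1L, max_sweeps = 100L,
                      trace = FALSE) {
  stopifnot(inherits(graph, "bipartite_graph"), graph$m >= 1)
  nb <- length(graph$bottom); nt <- length(graph$top)
  nn <- nb + nt
  m <- graph$m
  best <- NULL
  restart_q <- numeric(n_restarts)
  q_trace <- if (trace) vector("list", n_restarts) else NULL
  for (r in seq_len(n_restarts)) {
    set.seed(stream_seed(seed, r))
    labels <- seq_len(nn)
    K <- numeric(nn); D <- numeric(nn)      # per-label degree sums
    K[seq_len(nb)] <- graph$kbot
    D[nb + seq_len(nt)] <- graph$ktop
    for (sweep in seq_len(max_sweeps)) {
      changed <- 0L
      for (node in sample.int(nn)) {
        if (node <= nb) {
          nbrs <- graph$adj_bottom[[node]]
          if (!length(nbrs)) next
          nl <- labels[nb + nbrs]
          cnt <- rowsum(rep(1L, length(nl)), nl)
          cand <- as.integer(rownames(cnt))
          cur <- labels[node]
          e_cur <- if (cur %in% cand) cnt[match(cur, cand), 1] else 0
          sc <- cnt[, 1] - graph$kbot[node] * D[cand] / m
          sc_cur <- e_cur - graph$kbot[node] * D[cur] / m
          bi <- which(sc == max(sc))
          bestl <- cand[bi][which.min(cand[bi])]
          if (max(sc) > sc_cur + 1e-12 && bestl != cur) {
            K[cur] <- K[cur] - graph$kbot[node]
            K[bestl] <- K[bestl] + graph$kbot[node]
            labels[node] <- bestl
            changed <- changed + 1L
          }
        } else {
          j <- node - nb
          nbrs <- graph$adj_top[[j]]
          if (!length(nbrs)) next
          nl <- labels[nbrs]
          cnt <- rowsum(rep(1L, length(nl)), nl)
          cand <- as.integer(rownames(cnt))
          cur <- labels[node]
          e_cur <- if (cur %in% cand) cnt[match(cur, cand), 1] else 0
          sc <- cnt[, 1] - graph$ktop[j] * K[cand] / m
          sc_cur <- e_cur - graph$ktop[j] * K[cur] / m
          bi <- which(sc == max(sc))
          bestl <- cand[bi][which.min(cand[bi])]
          if (max(sc) > sc_cur + 1e-12 && bestl != cur) {
            D[cur] <- D[cur] - graph$ktop[j]
            D[bestl] <- D[bestl] + graph$ktop[j]
            labels[node] <- bestl
            changed <- changed + 1L
          }
        }
      }
      if (trace) q_trace[[r]] <- c(q_trace[[r]],
                                   barber_modularity(graph, labels))
      if (changed == 0L) break
      if (sweep == max_sweeps)
        warning(sprintf("LPAb+ stage 1 hit the sweep cap (%d)", max_sweeps))
    }
    labels <- merge_modules(graph, labels, K, D,
                            on_merge = if (trace) function(l)
                              q_trace[[r]] <<- c(q_trace[[r]],
                                                 barber_modularity(graph, l)))
    q <- barber_modularity(graph, labels)
    restart_q[r] <- q
    if (is.null(best) || q > best$q + 1e-12)
      best <- list(labels = labels, q = q)
  }
  labels <- relabel_compact(best$labels)
  names(labels) <- c(paste0("A:", graph$bottom), paste0("B:", graph$top))
  structure(list(labels = labels, q = best$q,
                 n_modules = length(unique(labels)),
                 restart_q = restart_q, q_trace = q_trace),
            class = "bipartite_labeling")
}

relabel_compact <- function(labels) {
  as.integer(factor(labels, levels = unique(labels)))
}

# stage 2: greedy best-gain-first merging of edge-sharing module pairs
merge_modules <- function(graph, labels, K, D, on_merge = NULL) {
  m <- graph$m
  repeat {
    ce <- module_cross_edges(graph, labels)
    und <- ce
    flip <- und$from > und$to
    tmp <- und$from[flip]; und$from[flip] <- und$to[flip]; und$to[flip] <- tmp
    und <- und[und$from != und$to, , drop = FALSE]
    if (!nrow(und)) break
    agg <- rowsum(und$n, paste(und$from, und$to, sep = "\r"))
    key <- strsplit(rownames(agg), "\r", fixed = TRUE)
    a <- as.integer(vapply(key, `[`, "", 1L))
    b <- as.integer(vapply(key, `[`, "", 2L))
    gain <- (agg[, 1] - (K[a] * D[b] + K[b] * D[a]) / m) / m
    i <- which.max(gain)
    if (gain[i] <= 1e-12) break
    keep <- min(a[i], b[i]); drop <- max(a[i], b[i])
    labels[labels == drop] <- keep
    K[keep] <- K[keep] + K[drop]; K[drop] <- 0
    D[keep] <- D[keep] + D[drop]; D[drop] <- 0
    if (!is.null(on_merge)) on_merge(labels)
  }
  labels
}

#' @export
print.bipartite_labeling <- function(x, ...) {
  cat(sprintf("<bipartite_labeling> %d modules, Q_B = %.4f\n",
              x$n_modules, x$q))
  invisible(x)
}

#' Select large bipartite modules and pool member genes per tissue
#'
#' Keeps modules whose internal edge count strictly exceeds `min_edges`
#' (default 1000, the reproduction-scale choice) and pools the member genes
#' of kept modules per side, deduplicated.
#'
#' @param labeling a [lpab_plus()] result
#' @param graph the matching [bipartite_graph()]
#' @param min_edges strict lower bound on internal TTC gene-pair count
#' @return a `module_set`: list(modules, pooled = list(bottom, top))
#' @export
select_modules <- function(labeling, graph, min_edges = 1000L) {
  stopifnot(inherits(labeling, "bipartite_labeling"),
            inherits(graph, "bipartite_graph"))
  nb <- length(graph$bottom)
  labels <- labeling$labels
  lb <- labels[graph$edges[, 1]]
  lt <- labels[nb + graph$edges[, 2]]
  internal <- table(lb[lb == lt])
  keep <- as.integer(names(internal)[internal > min_edges])
  modules <- lapply(keep, function(l) {
    list(label = l,
         bottom = graph$bottom[labels[seq_len(nb)] == l],
         top = graph$top[labels[nb + seq_along(graph$top)] == l],
         internal_edges = as.integer(internal[as.character(l)]))
  })
  pooled <- list(
    bottom = sort(unique(unlist(lapply(modules, `[[`, "bottom")))),
    top = sort(unique(unlist(lapply(modules, `[[`, "top")))))
  structure(list(modules = modules, pooled = pooled, min_edges = min_edges),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("<module_set> %d modules kept (> %d internal edges); pooled %d + %d genes\n",
              length(x$modules), x$min_edges, length(x$pooled$bottom),
              length(x$pooled$top)))
  invisible(x)
}
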
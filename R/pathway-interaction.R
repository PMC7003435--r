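#' Pathway-interaction adjacency matrix for one region pair
#'
#' `M[p, q] = 1` iff pathway p is enriched on side ROI1 and q on side ROI2
#' of the pair; the matrix is then symmetrized by element-wise max with its
#' transpose because the ordering of a region pair is arbitrary. The diagonal
#' `M[p, p] = 1` iff p is enriched on both sides (symmetric
#' synchronization).
#'
#' @param em an [enrich_all()] result
#' @param pair region-pair id
#' @return binary pathway x pathway matrix
#' @export
interaction_adjacency <- function(em, pair) {
  stopifnot(inherits(em, "enrichment_matrix"))
  w <- em$long[em$long$pair == pair, ]
  if (!nrow(w)) stop_cs(sprintf("unknown region pair '%s'", pair),
                        "cs_lookup_error")
  ids <- em$pathways
  a1 <- w$sig[w$side == "ROI1"][match(ids, w$pathway[w$side == "ROI1"])]
  a2 <- w$sig[w$side == "ROI2"][match(ids, w$pathway[w$side == "ROI2"])]
  M <- outer(as.numeric(a1), as.numeric(a2))
  M <- pmax(M, t(M))
  dimnames(M) <- list(ids, ids)
  M
}

#' Per-class pathway-interaction proportions
#'
#' Element-wise mean of member region pairs' interaction adjacency matrices,
#' for each binding group: not-bound, tract-bound (all bound pairs) and
#' AD-tract-bound (the subset bound by disease-associated tracts).
#'
#' @param em an [enrich_all()] result
#' @param classes classification from [classify_region_pairs()]
#' @return an `interaction_proportions`: list(prop, count, n) per group
#' @export
group_proportions <- function(em, classes) {
  stopifnot(inherits(em, "enrichment_matrix"))
  classes <- classes[classes$pair %in% em$pairs, ]
  groups <- list(
    `not-bound` = classes$pair[!classes$bound],
    `tract-bound` = classes$pair[classes$bound],
    `AD-tract-bound` = classes$pair[classes$ad_bound])
  ids <- em$pathways
  out <- lapply(names(groups), function(g) {
    prs <- groups[[g]]
    if (!length(prs)) {
      warning(sprintf("empty group '%s'; proportions undefined", g))
      return(list(prop = NULL, count = NULL, n = 0L))
    }
    acc <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (pr in prs) acc <- acc + interaction_adjacency(em, pr)
    list(prop = acc / length(prs), count = acc, n = length(prs))
  })
  names(out) <- names(groups)
  structure(out, class = "interaction_proportions")
}

# closed-form 2x2 chi-square without continuity correction, vectorized
chisq2x2 <- function(x1, n1, x0, n0) {
  a <- x1; b <- n1 - x1; c_ <- x0; d <- n0 - x0
  n <- n1 + n0
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  stat <- ifelse(denom > 0, n * (a * d - b * c_)^2 / denom, 0)
  p <- ifelse(denom > 0, pchisq(stat, df = 1, lower.tail = FALSE), 1)
  list(stat = stat, p = p)
}

#' Chi-square comparison of pathway-interaction proportions against the
#' not-bound reference
#'
#' For every pathway-pathway cell, compares the count of region pairs
#' showing that interaction in the group versus the reference group with a
#' 2x2 chi-square test (no continuity correction). Cells absent from both
#' groups get p = 1.
#'
#' @param props an [group_proportions()] result
#' @param group "tract-bound" or "AD-tract-bound"
#' @param reference reference group (default "not-bound")
#' @return list(p, neglog10, stat) matrices
#' @export
chisq_compare <- function(props, group, reference = "not-bound") {
  stopifnot(inherits(props, "interaction_proportions"))
  g <- props[[group]]; r <- props[[reference]]
  if (g$n < 2 || r$n < 2)
    stop_cs("group sizes must be at least 2", "cs_config_error")
  res <- chisq2x2(g$count, g$n, r$count, r$n)
  p <- res$p; stat <- res$stat
  dimnames(p) <- dimnames(stat) <- dimnames(g$count)
  list(p = p, neglog10 = -log10(p), stat = stat, group = group,
       reference = reference, n = c(group = g$n, reference = r$n))
}

#' Pathway-interaction graph with degree ranking
#'
#' Edges are pathway-pathway cells with `p < alpha`; diagonal cells become
#' self-loops contributing 1 to the degree.
#'
#' @param pmat symmetric p-value matrix from [chisq_compare()] (`p` element)
#' @param alpha edge significance threshold
#' @return an `interaction_graph`: list(edges, degree (sorted), alpha)
#' @export
build_interaction_graph <- function(pmat, alpha = 0.05) {
  stopifnot(is.matrix(pmat), nrow(pmat) == ncol(pmat))
  if (max(abs(pmat - t(pmat))) > 1e-12)
    stop_cs("p matrix must be symmetric", "cs_config_error")
  ids <- rownames(pmat) %||% as.character(seq_len(nrow(pmat)))
  hit <- which(upper.tri(pmat, diag = TRUE) & pmat < alpha, arr.ind = TRUE)
  edges <- data.frame(from = ids[hit[, 1]], to = ids[hit[, 2]],
                      p = pmat[hit], stringsAsFactors = FALSE)
  deg <- setNames(numeric(length(ids)), ids)
  for (i in seq_len(nrow(edges))) {
    deg[edges$from[i]] <- deg[edges$from[i]] + 1
    if (edges$to[i] != edges$from[i])
      deg[edges$to[i]] <- deg[edges$to[i]] + 1
  }
  structure(list(edges = edges, degree = sort(deg, decreasing = TRUE),
                 alpha = alpha),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("<interaction_graph> %d edges at p < %g; top degree: %s (%d)\n",
              nrow(x$edges), x$alpha,
              if (length(x$degree)) names(x$degree)[1] else "-",
              if (length(x$degree)) x$degree[1] else 0L))
  invisible(x)
}

#' Fisher test for symmetric gene synchronization per pathway
#'
#' For each pathway, tests whether symmetric synchronization (enrichment on
#' both sides of a pair) occurs more often among group pairs than among
#' not-bound reference pairs, with a one-sided (greater) Fisher exact test.
#' A pathway never symmetric in either group gets p = 1.
#'
#' @param em an [enrich_all()] result
#' @param classes classification from [classify_region_pairs()]
#' @param group "tract-bound" or "AD-tract-bound"
#' @param reference reference group
#' @return data.frame(pathway, n_sym_group, n_group, n_sym_ref, n_ref, p)
#' @export
symmetric_sync_test <- function(em, classes, group = "tract-bound",
                                reference = "not-bound") {
  stopifnot(inherits(em, "enrichment_matrix"))
  sync <- synchronization_type(em)
  classes <- classes[classes$pair %in% em$pairs, ]
  sel <- switch(group,
                `tract-bound` = classes$pair[classes$bound],
                `AD-tract-bound` = classes$pair[classes$ad_bound],
                stop_cs(sprintf("unknown group '%s'", group),
                        "cs_lookup_error"))
  ref <- switch(reference,
                `not-bound` = classes$pair[!classes$bound],
                stop_cs(sprintf("unknown reference '%s'", reference),
                        "cs_lookup_error"))
  if (!length(sel)) warning(sprintf("empty group '%s'; p = 1", group))
  out <- lapply(em$pathways, function(pw) {
    s <- sync[sync$pathway == pw, ]
    sym_pairs <- s$pair[s$type == "symmetric"]
    x1 <- length(intersect(sym_pairs, sel)); n1 <- length(sel)
    x0 <- length(intersect(sym_pairs, ref)); n0 <- length(ref)
    p <- if (n1 == 0 || (x1 + x0) == 0) 1 else
      phyper(x1 - 1, x1 + x0, n1 + n0 - x1 - x0, n1, lower.tail = FALSE)
    data.frame(pathway = pw, n_sym_group = x1, n_group = n1,
               n_sym_ref = x0, n_ref = n0, p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
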
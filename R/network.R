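# Target-rooted neighborhood graphs and their refinement. Two stages:
# (1) pruning of topologically non-essential neighbors (bridge / fjord /
# shore proteins), (2) two-pass filtering of edges by edge clustering
# coefficient (ECC) and then edge weight, each against an adaptive
# mean-plus-k-sigma threshold.

#' Level-2 neighborhood graph of a target
#'
#' Induced subgraph on the target, its direct (level-1) neighbors and their
#' neighbors (level-2), with BFS level tags. All induced edges are retained,
#' including level-2 to level-2 edges.
#'
#' @param net undirected weighted `igraph` PPI graph.
#' @param target protein ID, must be a vertex of `net`.
#' @param depth neighborhood depth (default 2).
#' @return object of class `neighborhood_graph`: list with `target`, `graph`
#'   (induced `igraph` subgraph) and `level` (named integer vector, target
#'   has level 0).
#' @export
neighborhood <- function(net, target, depth = 2) {
  if (!(target %in% igraph::V(net)$name)) {
    stopf("neighborhood: target '%s' not in network", target)
  }
  dmat <- igraph::distances(net, v = target, weights = NA)
  dist <- stats::setNames(as.numeric(dmat[1, ]), colnames(dmat))
  keep <- names(dist)[is.finite(dist) & dist <= depth]
  sub <- igraph::induced_subgraph(net, keep)
  level <- stats::setNames(as.integer(dist[keep]), keep)
  structure(list(target = target, graph = sub, level = level),
            class = "neighborhood_graph")
}

#' @export
print.neighborhood_graph <- function(x, ...) {
  cat(sprintf("neighborhood of %s: %d node(s), %d edge(s), levels: %s\n",
              x$target, igraph::vcount(x$graph), igraph::ecount(x$graph),
              paste(table(x$level), collapse = "/")))
  invisible(x)
}

#' Edge clustering coefficient
#'
#' ECC of an edge (u, v) is the number of triangles through it divided by the
#' maximum possible: `|N(u) n N(v)| / min(deg(u) - 1, deg(v) - 1)`. Edges
#' with a degree-1 endpoint get ECC 0, so leaves never look cohesive.
#'
#' @param g undirected `igraph` graph.
#' @param u,v endpoint vertex names of an existing edge.
#' @return ECC in `[0, 1]`.
#' @export
edge_clustering_coefficient <- function(g, u, v) {
  if (!igraph::are_adjacent(g, u, v)) stopf("ECC: no edge %s-%s", u, v)
  nu <- igraph::neighbors(g, u)$name
  nv <- igraph::neighbors(g, v)$name
  denom <- min(length(nu) - 1L, length(nv) - 1L)
  if (denom <= 0L) return(0)
  length(intersect(nu, nv)) / denom
}

#' ECC of every edge
#' @param g undirected `igraph` graph.
#' @return numeric vector of ECC values, one per edge in `igraph::E(g)`
#'   order.
#' @export
ecc_all <- function(g) {
  m <- igraph::ecount(g)
  if (m == 0L) return(numeric(0))
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  A@x[] <- 1
  common <- A %*% A                      # common-neighbor counts
  deg <- igraph::degree(g)
  el <- igraph::as_edgelist(g, names = TRUE)
  cn <- common[cbind(match(el[, 1], rownames(A)), match(el[, 2], rownames(A)))]
  denom <- pmin(deg[el[, 1]], deg[el[, 2]]) - 1
  unname(ifelse(denom <= 0, 0, cn / denom))
}

#' Classify a neighborhood protein as topologically non-essential
#'
#' Evaluated in priority order on the neighborhood subgraph:
#' * `bridge` — articulation vertex (its removal disconnects the subgraph);
#' * `fjord` — degree >= 2 with no triangle through it (local clustering 0);
#' * `shore` — leaf (degree 1);
#' * `none` — otherwise (essential, kept).
#'
#' @param ng a [neighborhood()] graph.
#' @param node vertex name; classifying the target is an error.
#' @return one of `"bridge"`, `"fjord"`, `"shore"`, `"none"`.
#' @export
classify_nonessential <- function(ng, node) {
  if (identical(node, ng$target)) {
    stopf("classify_nonessential: cannot classify the target itself")
  }
  if (!(node %in% igraph::V(ng$graph)$name)) {
    stopf("classify_nonessential: node '%s' not in neighborhood", node)
  }
  g <- ng$graph
  if (node %in% igraph::articulation_points(g)$name) return("bridge")
  deg <- igraph::degree(g, node)
  tri <- igraph::count_triangles(g, node)
  if (deg >= 2 && tri == 0) return("fjord")
  if (deg == 1) return("shore")
  "none"
}

#' Prune non-essential neighborhood proteins
#'
#' Single pass: every non-target node is classified on the original graph,
#' then all labelled nodes are removed simultaneously with their incident
#' edges. The target is never removed. Removal counts per label are attached
#' as attribute `removed`.
#'
#' @param ng a [neighborhood()] graph.
#' @return pruned `neighborhood_graph`.
#' @export
prune_nonessential <- function(ng) {
  nodes <- setdiff(igraph::V(ng$graph)$name, ng$target)
  labels <- vapply(nodes, function(n) classify_nonessential(ng, n), "")
  drop <- nodes[labels != "none"]
  g2 <- igraph::delete_vertices(ng$graph, drop)
  removed <- table(factor(labels[labels != "none"],
                          levels = c("bridge", "fjord", "shore")))
  out <- structure(list(target = ng$target, graph = g2,
                        level = ng$level[igraph::V(g2)$name]),
                   class = "neighborhood_graph")
  attr(out, "removed") <- stats::setNames(as.integer(removed), names(removed))
  out
}

#' Adaptive high-cutoff threshold
#'
#' `alpha + k * sigma * (1 - 1 / (1 + sigma^2))` where `alpha` and `sigma`
#' are the mean and population standard deviation of `values`. With `k = 3`
#' this is a high cutoff; for a constant population (`sigma = 0`) it
#' collapses to the mean.
#'
#' @param values numeric vector (at least one value).
#' @param k cutoff multiplier (default 3).
#' @return the threshold.
#' @export
adaptive_threshold <- function(values, k = 3) {
  if (length(values) == 0L) stopf("adaptive_threshold: empty value set")
  alpha <- mean(values)
  sigma <- pop_sd(values)
  alpha + k * sigma * (1 - 1 / (1 + sigma^2))
}

#' Two-pass ECC / edge-weight filtering
#'
#' Pass 1 drops edges whose ECC is strictly below the adaptive threshold of
#' all ECC values; pass 2 drops surviving edges whose weight is strictly
#' below the adaptive threshold of the surviving weights. Nodes left
#' isolated are then dropped (never the target). ECC is not recomputed after
#' the weight pass; the ECC-then-weight order is fixed.
#'
#' @param ng a (pruned) [neighborhood()] graph.
#' @param k threshold multiplier (default 3).
#' @return filtered `neighborhood_graph`; attribute `filtered` records the
#'   number of edges removed by each pass and isolated nodes dropped.
#' @export
double_filter <- function(ng, k = 3) {
  g <- ng$graph
  n_ecc <- 0L
  n_w <- 0L
  if (igraph::ecount(g) > 0L) {
    ecc <- ecc_all(g)
    thr1 <- adaptive_threshold(ecc, k)
    g <- igraph::delete_edges(g, igraph::E(g)[ecc < thr1])
    n_ecc <- length(ecc) - igraph::ecount(g)
  }
  if (igraph::ecount(g) > 0L) {
    w <- igraph::E(g)$weight
    thr2 <- adaptive_threshold(w, k)
    m0 <- igraph::ecount(g)
    g <- igraph::delete_edges(g, igraph::E(g)[w < thr2])
    n_w <- m0 - igraph::ecount(g)
  }
  isolated <- setdiff(igraph::V(g)$name[igraph::degree(g) == 0], ng$target)
  g <- igraph::delete_vertices(g, isolated)
  out <- structure(list(target = ng$target, graph = g,
                        level = ng$level[igraph::V(g)$name]),
                   class = "neighborhood_graph")
  attr(out, "filtered") <- c(ecc_edges = n_ecc, weight_edges = n_w,
                             isolated_nodes = length(isolated))
  out
}

#' Refine a target neighborhood
#'
#' Convenience wrapper: [neighborhood()] then [prune_nonessential()] then
#' [double_filter()].
#'
#' @inheritParams neighborhood
#' @param k threshold multiplier for [double_filter()].
#' @return refined `neighborhood_graph`.
#' @export
refine_neighborhood <- function(net, target, depth = 2, k = 3) {
  double_filter(prune_nonessential(neighborhood(net, target, depth)), k = k)
}
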
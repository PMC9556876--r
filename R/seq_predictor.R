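# Sequence-based GO prediction. Neighbors of the refined target neighborhood
# are clustered in the 7-dimensional standardized physico-chemical space by
# degree-seeded agglomeration: the unassigned node of highest degree seeds a
# cluster and absorbs its direct graph neighbors lying within a distance
# threshold. The target is assigned to the nearest cluster and inherits the
# GO terms of its closest member.

euclid <- function(a, b) sqrt(sum((a - b)^2))

#' Degree-seeded clusters in physico-chemical space
#'
#' Repeatedly takes the unassigned non-target node of highest degree in the
#' refined graph (ties by ID ascending) as a seed, and admits every
#' unassigned node directly connected to the seed whose Euclidean distance
#' in z-scored property space is strictly below the threshold. Singleton
#' clusters are permitted. The default threshold is the adaptive high cutoff
#' ([adaptive_threshold()]) over all pairwise neighbor distances.
#'
#' @param ng refined [neighborhood()] graph.
#' @param props numeric matrix of raw property vectors with one named row
#'   per non-target node (see [property_matrix()]).
#' @param dist_threshold optional fixed admission threshold.
#' @param k multiplier for the default adaptive threshold (default 3).
#' @return object of class `cluster_set`: list of clusters (each with
#'   `seed`, `members` (seed first), `score_vector`, `score_scalar`), with
#'   attributes `zmat` (the standardized neighbor matrix) and `threshold`.
#' @export
build_clusters <- function(ng, props, dist_threshold = NULL, k = 3) {
  nodes <- sort(setdiff(igraph::V(ng$graph)$name, ng$target))
  missing <- setdiff(nodes, rownames(props))
  if (length(missing) > 0L) {
    stopf("build_clusters: missing property vector for node '%s'", missing[1])
  }
  if (length(nodes) == 0L) {
    return(structure(list(), zmat = NULL, threshold = NA_real_,
                     class = "cluster_set"))
  }
  pop <- props[nodes, , drop = FALSE]
  zmat <- if (length(nodes) >= 2L) zscore_against(pop, pop) else
    matrix(0, 1, ncol(pop), dimnames = list(nodes, colnames(pop)))
  rownames(zmat) <- nodes
  if (is.null(dist_threshold)) {
    if (length(nodes) >= 2L) {
      d <- stats::dist(zmat)
      dist_threshold <- adaptive_threshold(as.numeric(d), k)
    } else {
      dist_threshold <- Inf
    }
  }
  deg <- igraph::degree(ng$graph)[nodes]
  pool <- nodes
  clusters <- list()
  while (length(pool) > 0L) {
    # highest degree first, ties by ID ascending (pool is ID-sorted)
    seed <- pool[order(-deg[pool], pool)][1]
    nbrs <- intersect(igraph::neighbors(ng$graph, seed)$name, pool)
    nbrs <- setdiff(nbrs, seed)
    dists <- vapply(nbrs, function(n) euclid(zmat[seed, ], zmat[n, ]),
                    numeric(1))
    admitted <- sort(nbrs[dists < dist_threshold])
    members <- c(seed, admitted)
    clusters[[length(clusters) + 1L]] <- list(
      seed = seed,
      members = members,
      score_vector = colMeans(zmat[members, , drop = FALSE]),
      score_scalar = mean(rowMeans(zmat[members, , drop = FALSE]))
    )
    pool <- setdiff(pool, members)
  }
  structure(clusters, zmat = zmat, threshold = dist_threshold,
            class = "cluster_set")
}

#' Validate cluster separation
#'
#' Computes the maximum intra-cluster member distance per cluster and the
#' minimum inter-cluster centroid distance, and warns (never fails) about
#' clusters whose spread reaches the inter-centroid separation — the
#' explicit form of the "no misclassification or overlap" criterion.
#'
#' @param clusters a [build_clusters()] result.
#' @return list with `max_intra` (named numeric per cluster),
#'   `min_inter_centroid` and `warnings` (character vector of seed IDs).
#' @export
validate_clusters <- function(clusters) {
  zmat <- attr(clusters, "zmat")
  max_intra <- vapply(clusters, function(cl) {
    if (length(cl$members) < 2L) return(0)
    max(stats::dist(zmat[cl$members, , drop = FALSE]))
  }, numeric(1))
  names(max_intra) <- vapply(clusters, `[[`, "", "seed")
  min_inter <- if (length(clusters) >= 2L) {
    cent <- do.call(rbind, lapply(clusters, `[[`, "score_vector"))
    min(stats::dist(cent))
  } else {
    Inf
  }
  flag <- names(max_intra)[max_intra >= min_inter]
  for (s in flag) {
    warning(sprintf("cluster seeded at %s overlaps: max intra %.3g >= min inter %.3g",
                    s, max_intra[s], min_inter), call. = FALSE)
  }
  list(max_intra = max_intra, min_inter_centroid = min_inter,
       warnings = flag)
}

#' Assign the target to its nearest cluster
#'
#' Nearest by Euclidean distance between the target's z-scored property
#' vector and each cluster's mean vector; ties go to the cluster with the
#' lexicographically smallest seed ID.
#'
#' @param target_z the target's z-scored 7-vector (or a `property_score`).
#' @param clusters a [build_clusters()] result (non-empty).
#' @return the chosen cluster (list element of `clusters`).
#' @export
assign_target <- function(target_z, clusters) {
  if (length(clusters) == 0L) stopf("assign_target: no clusters")
  if (inherits(target_z, "property_score")) target_z <- target_z$vector
  d <- vapply(clusters, function(cl) euclid(target_z, cl$score_vector),
              numeric(1))
  seeds <- vapply(clusters, `[[`, "", "seed")
  clusters[[order(d, seeds)[1]]]
}

#' Sequence-based GO prediction for one target
#'
#' Clusters the refined neighborhood in property space, assigns the target
#' to the nearest cluster, selects the annotated member closest to the
#' target (ties by ID; members without any GO annotation cannot serve as a
#' function-transfer source and are skipped) and transfers that member's GO
#' terms, each scored `1 / (1 + d)` where `d` is the member-target distance.
#' The prediction is empty (logged) only when no member of the assigned
#' cluster carries annotations.
#'
#' @param target target protein ID.
#' @param ng refined [neighborhood()] graph.
#' @param seqs named character vector of sequences covering the target and
#'   all neighborhood nodes.
#' @param annotations an [annotation_table] (the target's own annotations
#'   are never consulted).
#' @param dist_threshold,k passed to [build_clusters()].
#' @return prediction data.frame (`go_id`, `score`), possibly empty.
#' @export
sequence_predict <- function(target, ng, seqs, annotations,
                             dist_threshold = NULL, k = 3) {
  nodes <- setdiff(igraph::V(ng$graph)$name, ng$target)
  if (length(nodes) == 0L) {
    warning("sequence_predict: empty refined neighborhood", call. = FALSE)
    return(empty_prediction())
  }
  need <- c(target, nodes)
  missing <- setdiff(need, names(seqs))
  if (length(missing) > 0L) {
    stopf("sequence_predict: missing sequence for '%s'", missing[1])
  }
  props <- property_matrix(seqs[nodes])
  clusters <- build_clusters(ng, props, dist_threshold, k)
  if (length(clusters) == 0L) {
    warning("sequence_predict: no clusters formed", call. = FALSE)
    return(empty_prediction())
  }
  zmat <- attr(clusters, "zmat")
  target_z <- if (length(nodes) >= 2L) {
    property_score(seqs[[target]], props)$vector
  } else {
    stats::setNames(rep(0, ncol(props)), colnames(props))
  }
  # only clusters holding at least one annotated protein can act as a
  # function-transfer source; assignment is restricted to those
  ann_prots <- unique(annotations$protein_id)
  usable <- clusters[vapply(clusters, function(cl)
    any(cl$members %in% ann_prots), logical(1))]
  attributes(usable) <- attributes(clusters)[c("zmat", "threshold")]
  if (length(usable) == 0L) {
    message("sequence_predict: no cluster contains an annotated protein")
    return(empty_prediction())
  }
  cl <- assign_target(target_z, usable)
  d <- vapply(cl$members, function(n) euclid(target_z, zmat[n, ]), numeric(1))
  annotated <- cl$members[cl$members %in% ann_prots]
  nearest <- annotated[order(d[annotated], annotated)][1]
  terms <- protein_terms(annotations, nearest)
  score <- 1 / (1 + d[[nearest]])
  order_prediction(data.frame(go_id = terms, score = score,
                              stringsAsFactors = FALSE))
}
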
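# Topology / neighborhood-based GO prediction: every GO term carried by the
# refined neighborhood is ranked by its over-representation among the
# target's neighbors relative to a background universe, using the one-sided
# Fisher exact (hypergeometric tail) p value.

#' One-sided Fisher exact enrichment p value
#'
#' Over-representation tail `P(X >= x)` for
#' `X ~ Hypergeometric(N, K, n)`: drawing `n` from a universe of `N` of
#' which `K` carry the term, the probability of seeing `x` or more carriers.
#' Computed with the exact hypergeometric tail ([stats::phyper]), which sums
#' in log space and is numerically safe for large inputs.
#'
#' @param x observed carriers among the draw.
#' @param n draw size (annotated neighborhood size).
#' @param K carriers in the background.
#' @param N background size.
#' @return p value in `(0, 1]`.
#' @export
fisher_enrichment_p <- function(x, n, K, N) {
  if (any(c(x, n, K, N) < 0) || x > min(n, K) || n > N || K > N) {
    stopf("fisher_enrichment_p: inconsistent counts x=%d n=%d K=%d N=%d",
          x, n, K, N)
  }
  stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
}

#' Neighborhood-enrichment GO prediction for one target
#'
#' Candidate terms are the union of terms annotated to the target's level-1
#' and level-2 neighbors in the refined graph (the target's own annotations
#' never contribute evidence). Each term is scored by
#' [fisher_enrichment_p()] with `x` = annotated neighbors carrying the term,
#' `n` = annotated neighbors, `K` = background carriers, `N` = background
#' size, ranked by p ascending (ties: larger `x`, then term ID) and scored
#' `1 - p`.
#'
#' @param target target protein ID.
#' @param ng refined [neighborhood()] graph.
#' @param annotations an [annotation_table].
#' @param background character vector of background proteins; defaults to
#'   all annotated proteins in `annotations`. The target is always excluded.
#' @param top_n number of terms returned (default 10).
#' @param alpha optional p-value cutoff applied after ranking.
#' @return prediction data.frame (`go_id`, `score`, `p`, `x`), possibly
#'   empty.
#' @export
topo_predict <- function(target, ng, annotations, background = NULL,
                         top_n = 10, alpha = NULL) {
  df <- as.data.frame(annotations)
  if (is.null(background)) background <- unique(df$protein_id)
  background <- setdiff(unique(background), target)
  bg_annot <- intersect(background, unique(df$protein_id))
  neighbors <- setdiff(igraph::V(ng$graph)$name, target)
  ann_nbrs <- intersect(neighbors, unique(df$protein_id))
  if (length(ann_nbrs) == 0L) {
    warning("topo_predict: no annotated neighbors", call. = FALSE)
    return(cbind(empty_prediction(),
                 data.frame(p = numeric(0), x = integer(0))))
  }
  n <- length(ann_nbrs)
  N <- length(bg_annot)
  nbr_pairs <- unique(df[df$protein_id %in% ann_nbrs,
                         c("protein_id", "go_id")])
  terms <- sort(unique(nbr_pairs$go_id))
  x <- vapply(terms, function(t) sum(nbr_pairs$go_id == t), integer(1))
  bg_pairs <- unique(df[df$protein_id %in% bg_annot,
                        c("protein_id", "go_id")])
  K <- vapply(terms, function(t) sum(bg_pairs$go_id == t), integer(1))
  # neighbors are part of the background universe; guard anyway
  K <- pmax(K, x)
  p <- vapply(seq_along(terms),
              function(i) fisher_enrichment_p(x[i], n, K[i], N), numeric(1))
  out <- data.frame(go_id = terms, score = 1 - p, p = p, x = x,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, -out$x, out$go_id), , drop = FALSE]
  if (!is.null(alpha)) out <- out[out$p <= alpha, , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}
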
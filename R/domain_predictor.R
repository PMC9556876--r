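# Domain-domain-interaction-based GO prediction. Neighborhood proteins are
# mapped to their domains; for every edge of the refined graph, domain pairs
# supported by the DDI table are validated; GO terms of the participating
# domains are counted over all validated occurrences and the most frequent
# terms flow back to the target.

#' Domains of every neighborhood node
#'
#' Per node, the union of domains over all of its mapped protein IDs
#' (one-to-many maps fully respected); unmapped nodes get the empty set.
#'
#' @param ng refined [neighborhood()] graph.
#' @param tables a [domain_tables] object.
#' @param map optional `idmap` from network IDs to the protein namespace of
#'   `tables` (`NULL` means identical namespaces).
#' @return named list node -> character vector of domain IDs.
#' @export
neighborhood_domains <- function(ng, tables, map = NULL) {
  nodes <- igraph::V(ng$graph)$name
  pd <- tables$protein_domains
  out <- lapply(stats::setNames(nodes, nodes), function(n) {
    ids <- if (is.null(map)) n else idmap_lookup(map, n)
    sort(unique(pd$domain_id[pd$protein_id %in% ids]))
  })
  n_unmapped <- sum(lengths(out) == 0L)
  if (n_unmapped > 0L) {
    message(sprintf("neighborhood_domains: %d node(s) without domains",
                    n_unmapped))
  }
  out
}

#' DDI-validated domain pairs across neighborhood edges
#'
#' For every edge (u, v) of the refined graph, every domain pair
#' (a in domains(u), b in domains(v)) present in the DDI table
#' (order-insensitive) is retained.
#'
#' @param ng refined [neighborhood()] graph.
#' @param node_domains result of [neighborhood_domains()].
#' @param tables a [domain_tables] object (its `ddi` element is used).
#' @return data.frame with columns `u`, `v`, `domain_u`, `domain_v` (one row
#'   per validated occurrence).
#' @export
validated_domain_pairs <- function(ng, node_domains, tables) {
  ddi_key <- paste(tables$ddi$domain_a, tables$ddi$domain_b, sep = "\r")
  el <- igraph::as_edgelist(ng$graph, names = TRUE)
  rows <- list()
  for (i in seq_len(nrow(el))) {
    u <- el[i, 1]
    v <- el[i, 2]
    du <- node_domains[[u]]
    dv <- node_domains[[v]]
    if (length(du) == 0L || length(dv) == 0L) next
    grid <- expand.grid(domain_u = du, domain_v = dv,
                        stringsAsFactors = FALSE)
    key <- paste(pmin(grid$domain_u, grid$domain_v),
                 pmax(grid$domain_u, grid$domain_v), sep = "\r")
    hit <- grid[key %in% ddi_key, , drop = FALSE]
    if (nrow(hit) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(u = u, v = v, hit,
                                              stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(u = character(0), v = character(0),
                      domain_u = character(0), domain_v = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Domain-interaction-based GO prediction for one target
#'
#' GO terms of every domain participating in a validated pair are collected
#' — one occurrence per distinct (protein, domain) combination taking part
#' in at least one validated pair, so counts scale with the proteins
#' carrying the evidence rather than with the edge density around them —
#' and ranked by frequency descending, ties by term ID; score = frequency /
#' max frequency. When the domain-to-GO table yields no terms at all, the
#' predictor falls back to the annotations of the proteins carrying the
#' validated domains (the target's own annotations excluded).
#'
#' @param target target protein ID.
#' @param ng refined [neighborhood()] graph.
#' @param tables a [domain_tables] object.
#' @param annotations an [annotation_table] (used only for the fallback).
#' @param map optional `idmap` for [neighborhood_domains()].
#' @param top_n number of terms returned (default 10).
#' @return prediction data.frame (`go_id`, `score`), possibly empty.
#' @export
domain_predict <- function(target, ng, tables, annotations, map = NULL,
                           top_n = 10) {
  nd <- neighborhood_domains(ng, tables, map)
  pairs <- validated_domain_pairs(ng, nd, tables)
  if (nrow(pairs) == 0L) {
    warning("domain_predict: no DDI-validated domain pairs", call. = FALSE)
    return(empty_prediction())
  }
  inst_df <- unique(data.frame(
    protein = c(pairs$u, pairs$v),
    domain = c(pairs$domain_u, pairs$domain_v),
    stringsAsFactors = FALSE))
  instances <- inst_df$domain
  dg <- tables$domain_go
  terms <- unlist(lapply(instances, function(d) dg$go_id[dg$domain_id == d]))
  if (length(terms) == 0L) {
    # protein-mediated fallback for a sparse domain->GO table
    prots <- setdiff(unique(c(pairs$u, pairs$v)), target)
    terms <- unlist(lapply(prots, function(p) protein_terms(annotations, p)))
    if (length(terms) == 0L) {
      warning("domain_predict: no GO terms reachable through validated pairs",
              call. = FALSE)
      return(empty_prediction())
    }
  }
  freq <- table(terms)
  df <- data.frame(go_id = names(freq),
                   score = as.numeric(freq) / max(as.numeric(freq)),
                   stringsAsFactors = FALSE)
  utils::head(order_prediction(df), top_n)
}
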
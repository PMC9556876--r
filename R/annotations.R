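# Annotation table, GO-term frequency statistics and the selection of
# functionally active target proteins: proteins carrying any of the most
# frequent GO terms, a random fraction of which become prediction targets.

#' Construct an annotation table
#'
#' Flat protein-to-GO annotations in three aspects (BP, MF, CC). Annotations
#' are treated as flat labels: no ontology ancestor closure is applied.
#'
#' @param df data.frame with columns `protein_id`, `go_id`, `aspect`.
#' @return object of class `annotation_table` (a de-duplicated data.frame).
#' @export
annotation_table <- function(df) {
  stopifnot(all(c("protein_id", "go_id", "aspect") %in% names(df)))
  bad <- !(df$aspect %in% c("BP", "MF", "CC"))
  if (any(bad)) stopf("unknown aspect '%s'", df$aspect[bad][1])
  df <- unique(df[, c("protein_id", "go_id", "aspect")])
  rownames(df) <- NULL
  structure(df, class = c("annotation_table", "data.frame"))
}

#' Per-aspect annotation counts
#' @param tab an [annotation_table].
#' @return named integer vector with entries `BP`, `MF`, `CC`.
#' @export
aspect_counts <- function(tab) {
  counts <- table(factor(tab$aspect, levels = c("BP", "MF", "CC")))
  stats::setNames(as.integer(counts), names(counts))
}

#' GO-term frequencies
#'
#' The frequency of a term is the number of distinct proteins annotated with
#' it, optionally within one aspect.
#'
#' @param tab an [annotation_table].
#' @param aspect optional aspect filter (`"BP"`, `"MF"` or `"CC"`).
#' @return named integer vector, term -> protein count.
#' @export
term_frequencies <- function(tab, aspect = NULL) {
  if (nrow(tab) == 0L) stopf("term_frequencies: empty annotation table")
  df <- as.data.frame(tab)
  if (!is.null(aspect)) df <- df[df$aspect == aspect, , drop = FALSE]
  pairs <- unique(df[, c("protein_id", "go_id")])
  counts <- table(pairs$go_id)
  stats::setNames(as.integer(counts), names(counts))
}

#' Top-k most frequent terms
#'
#' @param freqs named vector as returned by [term_frequencies()].
#' @param k number of terms (default 10, mirroring the top-10 selection
#'   device of the pipeline).
#' @return character vector of term IDs sorted by count descending, ties
#'   broken by term ID ascending; length `min(k, length(freqs))`.
#' @export
top_k_terms <- function(freqs, k = 10) {
  stopifnot(k >= 1)
  ord <- order(-freqs, names(freqs))
  utils::head(names(freqs)[ord], k)
}

#' Terms annotated to a protein
#' @param tab an [annotation_table].
#' @param protein protein ID.
#' @param aspect optional aspect filter.
#' @return character vector of GO term IDs (possibly empty).
#' @export
protein_terms <- function(tab, protein, aspect = NULL) {
  df <- as.data.frame(tab)
  keep <- df$protein_id == protein
  if (!is.null(aspect)) keep <- keep & df$aspect == aspect
  sort(unique(df$go_id[keep]))
}

#' Select functionally active target proteins
#'
#' Proteins annotated with any of the `k_terms` most frequent GO terms are
#' candidates; they are mapped to network IDs (unmappables dropped with a
#' message), restricted to network members, and `ceil(fraction * n)` of them
#' are sampled uniformly without replacement under `seed`.
#'
#' @param tab an [annotation_table].
#' @param network undirected `igraph` PPI graph.
#' @param map optional `idmap` from annotation IDs to network IDs (`NULL`
#'   means the namespaces coincide).
#' @param k_terms number of top terms (default 10).
#' @param fraction sampled fraction of the candidate pool (default 0.20).
#' @param seed integer RNG seed; the selection is a pure function of its
#'   inputs and this seed.
#' @return object of class `target_set`: list with `targets` (character) and
#'   `meta` (k_terms, fraction, seed, pool size).
#' @export
select_targets <- function(tab, network, map = NULL, k_terms = 10,
                           fraction = 0.20, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  top <- top_k_terms(term_frequencies(tab), k_terms)
  annotated <- sort(unique(tab$protein_id[tab$go_id %in% top]))
  if (is.null(map)) {
    mapped <- annotated
  } else {
    per <- lapply(annotated, function(p) idmap_lookup(map, p))
    n_unmapped <- sum(lengths(per) == 0L)
    if (n_unmapped > 0L) {
      message(sprintf("select_targets: %d candidate(s) unmappable, dropped",
                      n_unmapped))
    }
    mapped <- sort(unique(unlist(per)))
  }
  pool <- mapped[mapped %in% igraph::V(network)$name]
  if (length(pool) == 0L) stopf("select_targets: empty candidate pool")
  n_take <- ceiling(fraction * length(pool))
  picked <- with_seed(seed, sample(pool, n_take, replace = FALSE))
  # sampling is without replacement, so de-duplication (kept for parity with
  # the with-replacement reading) is a no-op on the sample order
  picked <- picked[!duplicated(picked)]
  structure(list(targets = picked,
                 meta = list(k_terms = k_terms, fraction = fraction,
                             seed = seed, pool_size = length(pool))),
            class = "target_set")
}

#' Hide targets' own annotations
#'
#' Leave-out protocol helper: removes every annotation of the given proteins
#' from the table (used as truth only), so no predictor sees them.
#'
#' @param tab an [annotation_table].
#' @param targets character vector of protein IDs.
#' @return list with `table` (annotations without the targets) and `truth`
#'   (named list target -> character vector of held-out terms).
#' @export
holdout_annotations <- function(tab, targets) {
  df <- as.data.frame(tab)
  held <- df[df$protein_id %in% targets, , drop = FALSE]
  truth <- lapply(stats::setNames(targets, targets), function(p) {
    sort(unique(held$go_id[held$protein_id == p]))
  })
  list(table = annotation_table(df[!(df$protein_id %in% targets), ,
                                   drop = FALSE]),
       truth = truth)
}
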
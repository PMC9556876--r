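# End-to-end pipeline: for every held-out target, build the level-2
# neighborhood, prune non-essential neighbors, double-filter edges, run the
# three predictors, merge with the n-star consensus and evaluate against the
# truth. All stage outputs are plain TSV/JSON so any stage can be inspected
# or swapped.

#' Run the three predictors on one target
#'
#' @param target target protein ID.
#' @param net full PPI `igraph` network.
#' @param annotations an [annotation_table] (without the target's own
#'   annotations).
#' @param seqs named character vector of sequences.
#' @param tables a [domain_tables] object.
#' @param map optional `idmap` (network to annotation/domain namespace).
#' @param k adaptive-threshold multiplier (default 3).
#' @param top_n terms returned by the domain and topology predictors
#'   (default 10).
#' @param background background universe for [topo_predict()] (default: all
#'   annotated proteins of the network).
#' @return named list of prediction data.frames (`seq`, `domain`, `topo`)
#'   plus the refined `neighborhood_graph` as attribute `refined`.
#' @export
predict_target <- function(target, net, annotations, seqs, tables,
                           map = NULL, k = 3, top_n = 10,
                           background = NULL) {
  if (is.null(background)) {
    background <- intersect(igraph::V(net)$name,
                            unique(annotations$protein_id))
  }
  refined <- refine_neighborhood(net, target, depth = 2, k = k)
  run <- function(expr) {
    tryCatch(suppressMessages(suppressWarnings(expr)),
             error = function(e) empty_prediction())
  }
  preds <- list(
    seq = run(sequence_predict(target, refined, seqs, annotations, k = k)),
    domain = run(domain_predict(target, refined, tables, annotations,
                                map = map, top_n = top_n)),
    topo = run(topo_predict(target, refined, annotations,
                            background = background, top_n = top_n))
  )
  preds$topo <- preds$topo[, c("go_id", "score"), drop = FALSE]
  attr(preds, "refined") <- refined
  preds
}

#' Run the full pipeline on a synthetic world
#'
#' Executes prediction for every held-out target of the world, merges the
#' predictors with the n-star consensus and evaluates against the truth.
#' With `out_dir` set, per-stage outputs (predictions per predictor,
#' consensus, metrics, manifest) are written as TSV/JSON; re-running with
#' identical inputs reproduces identical files.
#'
#' @param world a [generate_world()] (or [read_world()]) result.
#' @param consensus_n n-star level (default 3 = unanimous).
#' @param k adaptive-threshold multiplier (default 3).
#' @param top_n terms per predictor for the ranked predictors (default 10).
#' @param out_dir optional output directory.
#' @return list with `predictions` (long data.frame: target, predictor,
#'   go_id, score), `consensus` (data.frame: target, go_id, score,
#'   n_predictors), `report` (the [evaluate_run()] table) and `per_target`
#'   (list of per-predictor outputs).
#' @export
run_pipeline <- function(world, consensus_n = 3, k = 3, top_n = 10,
                         out_dir = NULL) {
  targets <- names(world$truth)
  if (length(targets) == 0L) stopf("run_pipeline: world has no targets")
  background <- intersect(igraph::V(world$network)$name,
                          unique(world$annotations$protein_id))
  per_target <- lapply(stats::setNames(targets, targets), function(t) {
    predict_target(t, world$network, world$annotations, world$sequences,
                   world$domain_tables, map = NULL, k = k, top_n = top_n,
                   background = background)
  })
  long <- do.call(rbind, unlist(lapply(targets, function(t) {
    lapply(PREDICTOR_LABELS, function(lab) {
      p <- per_target[[t]][[lab]]
      if (nrow(p) == 0L) return(NULL)
      data.frame(target = t, predictor = lab, go_id = p$go_id,
                 score = p$score, stringsAsFactors = FALSE)
    })
  }), recursive = FALSE))
  if (is.null(long)) {
    long <- data.frame(target = character(0), predictor = character(0),
                       go_id = character(0), score = numeric(0))
  }
  cons_list <- lapply(per_target, function(p)
    n_star(p[PREDICTOR_LABELS], n = consensus_n))
  consensus <- do.call(rbind, lapply(targets, function(t) {
    cc <- cons_list[[t]]
    if (nrow(cc) == 0L) return(NULL)
    data.frame(target = t, cc, stringsAsFactors = FALSE)
  }))
  if (is.null(consensus)) {
    consensus <- data.frame(target = character(0), go_id = character(0),
                            score = numeric(0), n_predictors = integer(0),
                            predictors = character(0))
  }
  report <- evaluate_run(cons_list, world$truth, world$term_aspects)
  out <- list(predictions = long, consensus = consensus, report = report,
              per_target = per_target)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(long, file.path(out_dir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(consensus, file.path(out_dir, "consensus.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report, file.path(out_dir, "metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest <- list(
      package_version = as.character(utils::packageVersion("gostar")),
      params = world$params,
      consensus_n = consensus_n, k = k, top_n = top_n,
      n_targets = length(targets))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Shuffle annotations across proteins
#'
#' Null-model helper: permutes the protein column of an annotation table,
#' destroying any association between network position and annotation while
#' preserving term frequencies.
#'
#' @param tab an [annotation_table].
#' @param seed integer seed.
#' @return shuffled `annotation_table`.
#' @export
shuffle_annotations <- function(tab, seed = 1L) {
  df <- as.data.frame(tab)
  with_seed(seed, {
    df$protein_id <- sample(df$protein_id)
  })
  annotation_table(df)
}

#' Shuffle every GO-label source of a world
#'
#' Full label null: permutes protein-to-term assignments in the annotation
#' table and domain-to-term assignments in the domain-to-GO table, so no
#' predictor channel retains any association between planted structure and
#' labels. Network, sequences, domains and DDIs are untouched.
#'
#' @param world a [generate_world()] result.
#' @param seed integer seed.
#' @return the world with shuffled labels.
#' @export
shuffle_world_labels <- function(world, seed = 1L) {
  world$annotations <- shuffle_annotations(world$annotations, seed)
  dg <- world$domain_tables$domain_go
  if (nrow(dg) > 0L) {
    dg$domain_id <- with_seed(seed + 1L, sample(dg$domain_id))
    world$domain_tables$domain_go <- unique(dg)
  }
  world
}
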
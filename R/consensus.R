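# n-star consensus over the three predictors: a GO term is accepted when at
# least n of them propose it. 1-star is the union (least reliable, most
# terms), 3-star the unanimous intersection (most reliable).

PREDICTOR_LABELS <- c("seq", "domain", "topo")

#' n-star consensus of predictor outputs
#'
#' @param preds named list of prediction data.frames (`go_id`, `score`), one
#'   per predictor; names must be among `"seq"`, `"domain"`, `"topo"`. A
#'   missing or empty entry counts as predicting nothing.
#' @param n minimum number of predictors that must propose a term
#'   (1 to `length(preds)`).
#' @return data.frame with `go_id`, `score` (mean of the contributing
#'   predictors' scores), `n_predictors` and `predictors`
#'   (comma-separated contributing labels), sorted by score descending,
#'   ties by term ID.
#' @export
n_star <- function(preds, n = 3) {
  bad <- setdiff(names(preds), PREDICTOR_LABELS)
  if (length(bad) > 0L) stopf("n_star: unknown predictor label '%s'", bad[1])
  stopifnot(n >= 1, n <= length(preds))
  long <- do.call(rbind, lapply(names(preds), function(lab) {
    p <- preds[[lab]]
    if (is.null(p) || nrow(p) == 0L) return(NULL)
    stopifnot(all(p$score >= 0 & p$score <= 1))
    data.frame(predictor = lab, go_id = p$go_id, score = p$score,
               stringsAsFactors = FALSE)
  }))
  if (is.null(long) || nrow(long) == 0L) {
    return(data.frame(go_id = character(0), score = numeric(0),
                      n_predictors = integer(0), predictors = character(0),
                      stringsAsFactors = FALSE))
  }
  agg <- split(long, long$go_id)
  out <- do.call(rbind, lapply(names(agg), function(t) {
    sub <- agg[[t]]
    data.frame(go_id = t, score = mean(sub$score),
               n_predictors = nrow(sub),
               predictors = paste(sort(sub$predictor), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  out <- out[out$n_predictors >= n, , drop = FALSE]
  out <- out[order(-out$score, out$go_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
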
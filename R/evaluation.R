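# Evaluation against held-out truth: per-target precision / recall / F,
# macro averaging over targets, and CAFA-style Fmax over a score-threshold
# grid, pooled or per GO aspect.

#' Precision, recall and F-score of one prediction
#'
#' `P = |pred n truth| / |pred|` (0 for an empty prediction),
#' `R = |pred n truth| / |truth|`, `F = 2PR / (P + R)` (0 when `P + R = 0`).
#'
#' @param predicted character vector of predicted terms.
#' @param truth character vector of true terms (non-empty).
#' @return named numeric vector `c(precision, recall, f)`.
#' @export
prf <- function(predicted, truth) {
  if (length(truth) == 0L) stopf("prf: empty truth set")
  predicted <- unique(predicted)
  truth <- unique(truth)
  tp <- length(intersect(predicted, truth))
  p <- if (length(predicted) == 0L) 0 else tp / length(predicted)
  r <- tp / length(truth)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f = f)
}

#' Macro-averaged precision, recall and F
#'
#' Unweighted mean of per-target P, R and F over evaluable targets (those
#' with non-empty truth; others are excluded with a message).
#'
#' @param predictions named list target -> character vector of predicted
#'   terms (or a prediction data.frame with a `go_id` column).
#' @param truths named list target -> character vector of true terms.
#' @return named numeric vector `c(precision, recall, f, n_targets)`.
#' @export
macro_prf <- function(predictions, truths) {
  evaluable <- names(truths)[lengths(truths) > 0L]
  skipped <- length(truths) - length(evaluable)
  if (skipped > 0L) {
    message(sprintf("macro_prf: %d target(s) with empty truth excluded",
                    skipped))
  }
  if (length(evaluable) == 0L) stopf("macro_prf: no evaluable targets")
  per <- vapply(evaluable, function(t) {
    pred <- predictions[[t]]
    if (is.data.frame(pred)) pred <- pred$go_id
    prf(if (is.null(pred)) character(0) else pred, truths[[t]])
  }, numeric(3))
  c(precision = mean(per["precision", ]), recall = mean(per["recall", ]),
    f = mean(per["f", ]), n_targets = length(evaluable))
}

#' CAFA-style Fmax
#'
#' For each threshold in the grid, terms with score >= threshold are kept;
#' precision is averaged over targets with at least one surviving
#' prediction, recall over all evaluable targets; Fmax is the maximum over
#' thresholds of the harmonic mean of the two averages.
#'
#' @param predictions named list target -> data.frame (`go_id`, `score`).
#' @param truths named list target -> character vector of true terms.
#' @param thresholds score grid (default `seq(0, 1, 0.01)`).
#' @return list with `fmax`, `threshold` (argmax) and `curve` (data.frame of
#'   threshold, precision, recall, f).
#' @export
fmax <- function(predictions, truths, thresholds = seq(0, 1, by = 0.01)) {
  evaluable <- names(truths)[lengths(truths) > 0L]
  if (length(evaluable) == 0L) stopf("fmax: no target with truth")
  curve <- do.call(rbind, lapply(thresholds, function(tau) {
    precs <- numeric(0)
    recs <- numeric(0)
    for (t in evaluable) {
      pred <- predictions[[t]]
      kept <- if (is.null(pred) || nrow(pred) == 0L) character(0) else
        unique(pred$go_id[pred$score >= tau])
      truth <- unique(truths[[t]])
      tp <- length(intersect(kept, truth))
      if (length(kept) > 0L) precs <- c(precs, tp / length(kept))
      recs <- c(recs, tp / length(truth))
    }
    p <- if (length(precs) > 0L) mean(precs) else 0
    r <- mean(recs)
    data.frame(threshold = tau, precision = p, recall = r,
               f = if (p + r == 0) 0 else 2 * p * r / (p + r))
  }))
  best <- which.max(curve$f)
  list(fmax = curve$f[best], threshold = curve$threshold[best], curve = curve)
}

#' Evaluate a prediction run
#'
#' Macro P/R/F and Fmax, pooled over all aspects and (when a term-to-aspect
#' map is supplied) restricted per aspect. Per-aspect evaluation keeps only
#' targets whose truth contains at least one term of that aspect.
#'
#' @param predictions named list target -> data.frame (`go_id`, `score`).
#' @param truths named list target -> character vector of true terms.
#' @param term_aspects optional named character vector term -> aspect
#'   (`BP`/`MF`/`CC`).
#' @return data.frame with one row per evaluated slice (`aspect` is
#'   `"all"`, `"BP"`, `"MF"` or `"CC"`) and columns precision, recall, f,
#'   fmax, n_targets.
#' @export
evaluate_run <- function(predictions, truths, term_aspects = NULL) {
  slice <- function(label, preds, trs) {
    trs <- trs[lengths(trs) > 0L]
    if (length(trs) == 0L) return(NULL)
    m <- suppressMessages(macro_prf(preds, trs))
    fm <- fmax(preds, trs)
    data.frame(aspect = label, precision = m[["precision"]],
               recall = m[["recall"]], f = m[["f"]], fmax = fm$fmax,
               n_targets = m[["n_targets"]], stringsAsFactors = FALSE)
  }
  out <- list(slice("all", predictions, truths))
  if (!is.null(term_aspects)) {
    for (a in c("BP", "MF", "CC")) {
      terms_a <- names(term_aspects)[term_aspects == a]
      preds_a <- lapply(predictions, function(p) {
        if (is.null(p) || nrow(p) == 0L) return(p)
        p[p$go_id %in% terms_a, , drop = FALSE]
      })
      truths_a <- lapply(truths, function(t) intersect(t, terms_a))
      out[[length(out) + 1L]] <- slice(a, preds_a, truths_a)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
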
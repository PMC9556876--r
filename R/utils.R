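#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's RNG
#' state afterwards, so seeded package functions never perturb the session.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Population (not sample) standard deviation; the adaptive threshold and the
# property z-scoring both use it so a one-element population is well defined.
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

#' Empty prediction table
#'
#' Canonical zero-row prediction: every predictor returns this shape.
#' @return data.frame with character `go_id` and numeric `score`, zero rows.
#' @keywords internal
empty_prediction <- function() {
  data.frame(go_id = character(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

# Order a prediction table by score descending, go_id ascending on ties.
order_prediction <- function(df) {
  df <- df[order(-df$score, df$go_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
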
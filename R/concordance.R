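#' Harrell's concordance index
#'
#' C over comparable pairs: a pair (i, j) is comparable when the ordering of
#' the two outcomes is determinable under right censoring — i's event time is
#' observed and strictly precedes j's follow-up, or both have equal times
#' with i an event and j censored. A comparable pair is concordant when the
#' subject with the earlier event carries the higher risk score; tied scores
#' contribute 1/2. Pairs whose ordering censoring hides are excluded.
#'
#' @param score per-sample risk score (higher = higher predicted risk).
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @return object of class `concordance_result`: `c_index`,
#'   `comparable_pairs`, `concordant`, `tied_score`.
#' @export
concordance_index <- function(score, time, event) {
  check_surv_vectors(time, event)
  if (length(score) != length(time)) fail("'score' length mismatch")
  if (anyNA(score)) fail("'score' must not contain NA")
  # comparable[i, j]: i is known to fail before j
  earlier <- outer(time, time, "<") & (event == 1)
  tie_time <- outer(time, time, "==") &
    outer(event == 1, event == 0, "&")
  comp <- earlier | tie_time
  npairs <- sum(comp)
  if (npairs == 0L) fail("no comparable pairs under this censoring pattern")
  hi <- outer(score, score, ">")
  eq <- outer(score, score, "==")
  conc <- sum(comp & hi)
  ties <- sum(comp & eq)
  structure(list(c_index = (conc + 0.5 * ties) / npairs,
                 comparable_pairs = npairs,
                 concordant = conc, tied_score = ties),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Concordance index: %.4f (%d comparable pairs, %d score ties)\n",
              x$c_index, x$comparable_pairs, x$tied_score))
  invisible(x)
}
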
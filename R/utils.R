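`%||%` <- function(a, b) if (is.null(a)) b else a

# Validation helper: all errors are raised without the internal call, in the
# style of user-facing modelling packages.
fail <- function(...) stop(..., call. = FALSE)

check_surv_vectors <- function(time, event) {
  if (length(time) != length(event))
    fail("'time' and 'event' must have equal length")
  if (length(time) == 0L) fail("empty survival input")
  if (anyNA(time) || anyNA(event)) fail("'time'/'event' must not contain NA")
  if (any(time <= 0)) fail("all times must be positive")
  if (!all(event %in% c(0, 1))) fail("'event' must be coded 0 (censored) / 1 (event)")
  invisible(TRUE)
}

#' Generalized inverse via SVD (used when a log-rank covariance is singular)
#' @noRd
ginv_svd <- function(m, tol = sqrt(.Machine$double.eps)) {
  MASS::ginv(m, tol = tol)
}
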
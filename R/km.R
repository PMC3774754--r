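#' Kaplan-Meier product-limit estimate
#'
#' S(t) = prod over distinct event times t_i <= t of (1 - d_i / n_i), with
#' d_i events among n_i at risk. Right-continuous step function; S = 1
#' before the first event time.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @return object of class `km_curve` with `time` (distinct event times,
#'   increasing), `survival`, `n_risk`, `n_event`, `censor_times` and `n`.
#' @export
km_estimate <- function(time, event) {
  check_surv_vectors(time, event)
  ut <- sort(unique(time[event == 1]))
  if (length(ut) == 0L) {
    return(structure(list(time = numeric(0), survival = numeric(0),
                          n_risk = integer(0), n_event = integer(0),
                          censor_times = sort(time[event == 0]),
                          n = length(time)),
                     class = "km_curve"))
  }
  st <- sort(time)
  n_risk <- length(time) - findInterval(ut, st, left.open = TRUE)
  n_event <- tabulate(match(time[event == 1], ut), length(ut))
  surv <- cumprod(1 - n_event / n_risk)
  structure(list(time = ut, survival = surv, n_risk = n_risk,
                 n_event = n_event, censor_times = sort(time[event == 0]),
                 n = length(time)),
            class = "km_curve")
}

#' Evaluate a km_curve at arbitrary times (right-continuous)
#' @param km a [km_estimate()] result.
#' @param t times at which to evaluate S(t).
#' @return numeric vector of survival probabilities.
#' @export
km_survival_at <- function(km, t) {
  if (length(km$time) == 0L) return(rep(1, length(t)))
  idx <- findInterval(t, km$time)
  ifelse(idx == 0L, 1, km$survival[pmax(idx, 1L)])
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, %d event time(s), %d censored\n",
              x$n, length(x$time), length(x$censor_times)))
  invisible(x)
}

#' Number at risk at given times (for at-risk tables under KM plots)
#' @param time,event survival data.
#' @param at times at which to count samples still at risk.
#' @return integer vector.
#' @export
n_at_risk <- function(time, event, at) {
  st <- sort(time)
  length(time) - findInterval(at, st, left.open = TRUE)
}
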
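# Internal fast core: observed/expected events and hypergeometric variance
# per group over the pooled distinct event times. `g` is an integer vector
# in 1..k. Returns the chi-square statistic plus the O/E table.
logrank_core <- function(time, event, g, k) {
  ut <- sort(unique(time[event == 1]))
  O <- E <- numeric(k)
  if (length(ut) == 0L)
    return(list(statistic = 0, O = O, E = E, V = matrix(0, k, k)))
  nt <- length(ut)
  d <- nr <- matrix(0, nt, k)
  for (gi in seq_len(k)) {
    tg <- time[g == gi]
    eg <- event[g == gi]
    stg <- sort(tg)
    nr[, gi] <- length(tg) - findInterval(ut, stg, left.open = TRUE)
    ev <- match(tg[eg == 1], ut)
    d[, gi] <- tabulate(ev[!is.na(ev)], nt)
  }
  dtot <- rowSums(d)
  ntot <- rowSums(nr)
  P <- nr / ntot
  E <- colSums(P * dtot)
  O <- colSums(d)
  mult <- dtot * (ntot - dtot) / pmax(ntot - 1, 1)
  km1 <- k - 1L
  V <- matrix(0, km1, km1)
  for (a in seq_len(km1)) {
    V[a, a] <- sum(mult * P[, a] * (1 - P[, a]))
    if (a < km1) for (b in seq.int(a + 1L, km1)) {
      V[a, b] <- V[b, a] <- -sum(mult * P[, a] * P[, b])
    }
  }
  z <- (O - E)[seq_len(km1)]
  stat <- if (all(abs(z) < 1e-12)) 0 else {
    sol <- tryCatch(solve(V, z), error = function(e) NULL)
    if (is.null(sol)) {
      zz <- O - E
      Vf <- rbind(cbind(V, -rowSums(V)), c(-colSums(V), sum(V)))
      drop(t(zz) %*% ginv_svd(Vf) %*% zz)
    } else drop(crossprod(z, sol))
  }
  list(statistic = max(stat, 0), O = O, E = E, V = V)
}

#' k-sample log-rank test of equal survival curves
#'
#' Standard Mantel-Haenszel log-rank chi-square over the pooled risk sets,
#' with df = k - 1 and the p-value from the upper chi-square tail. With no
#' observed events the statistic is 0 and p = 1.
#'
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @param group group labels with k >= 2 non-empty levels.
#' @return object of class `logrank_test`: `statistic`, `df`, `p_value`,
#'   `observed`, `expected`, `n` per group.
#' @export
logrank_test <- function(time, event, group) {
  check_surv_vectors(time, event)
  if (length(group) != length(time)) fail("'group' length mismatch")
  if (anyNA(group)) fail("'group' must not contain NA")
  # factor levels are preserved so an empty group is reported as such
  f <- if (is.factor(group)) group else factor(group)
  k <- nlevels(f)
  if (k < 2L) fail("need at least 2 groups")
  if (any(tabulate(f, k) == 0L)) fail("every group must be non-empty")
  core <- logrank_core(time, event, as.integer(f), k)
  p <- if (core$statistic == 0) 1 else
    pchisq(core$statistic, df = k - 1, lower.tail = FALSE)
  structure(list(statistic = core$statistic, df = k - 1L,
                 p_value = min(max(p, .Machine$double.xmin), 1),
                 observed = setNames(core$O, levels(f)),
                 expected = setNames(core$E, levels(f)),
                 n = setNames(as.integer(table(f)), levels(f))),
            class = "logrank_test")
}

#' @export
print.logrank_test <- function(x, ...) {
  cat(sprintf("Log-rank test: chisq = %.4g on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
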
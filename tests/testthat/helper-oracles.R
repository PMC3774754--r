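# Independent brute-force oracles used to validate the analytic
# implementations. Deliberately naive (explicit loops over risk sets and
# pairs) and kept free of any code shared with the package internals.

# Product-limit survival by direct risk-set enumeration at each event time.
km_oracle <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    n_i <- 0; d_i <- 0
    for (j in seq_along(time)) {
      if (time[j] >= ut[i]) n_i <- n_i + 1
      if (time[j] == ut[i] && event[j] == 1) d_i <- d_i + 1
    }
    s <- s * (1 - d_i / n_i)
    surv[i] <- s
  }
  list(time = ut, survival = surv)
}

# k-sample log-rank chi-square via explicit O-E and covariance sums.
logrank_oracle <- function(time, event, group) {
  f <- factor(group); k <- nlevels(f); g <- as.integer(f)
  ut <- sort(unique(time[event == 1]))
  OE <- numeric(k); V <- matrix(0, k, k)
  for (u in ut) {
    at <- time >= u
    n <- sum(at)
    d <- sum(time == u & event == 1)
    for (a in 1:k) {
      na <- sum(at & g == a)
      da <- sum(time == u & event == 1 & g == a)
      OE[a] <- OE[a] + da - d * na / n
      for (b in 1:k) {
        nb <- sum(at & g == b)
        delta <- as.numeric(a == b)
        if (n > 1)
          V[a, b] <- V[a, b] +
            d * (n - d) / (n - 1) * (na / n) * (delta - nb / n)
      }
    }
  }
  z <- OE[1:(k - 1)]
  Vs <- V[1:(k - 1), 1:(k - 1), drop = FALSE]
  if (all(abs(z) < 1e-12)) return(0)
  drop(t(z) %*% solve(Vs) %*% z)
}

# Harrell concordance by O(n^2) explicit pair enumeration.
cindex_oracle <- function(score, time, event) {
  conc <- 0; ties <- 0; comp <- 0
  n <- length(time)
  for (i in 1:n) for (j in 1:n) {
    if (i == j) next
    comparable <- (time[i] < time[j] && event[i] == 1) ||
      (time[i] == time[j] && event[i] == 1 && event[j] == 0)
    if (!comparable) next
    comp <- comp + 1
    if (score[i] > score[j]) conc <- conc + 1
    else if (score[i] == score[j]) ties <- ties + 1
  }
  (conc + 0.5 * ties) / comp
}

# Exhaustive admissible-split argmin of the two-group log-rank p-value.
split_oracle <- function(pi_, time, event, min_size) {
  n <- length(pi_)
  ord <- order(pi_, seq_along(pi_))
  ps <- pi_[ord]; ts <- time[ord]; es <- event[ord]
  cand <- min_size:(n - min_size)
  cand <- cand[ps[cand] < ps[cand + 1]]
  best_s <- NA_integer_; best_p <- Inf
  for (s in cand) {
    g <- rep(1:2, c(s, n - s))
    p <- logrank_test(ts, es, g)$p_value
    if (p < best_p - 1e-15) { best_p <- p; best_s <- s }
  }
  list(position = best_s, p = best_p)
}

# Mann-Whitney AUC of a marker for a binary outcome, by rank-sum.
mw_auc <- function(marker, positive) {
  x1 <- marker[positive]; x0 <- marker[!positive]
  r <- rank(c(x1, x0))
  (sum(r[seq_along(x1)]) - length(x1) * (length(x1) + 1) / 2) /
    (length(x1) * length(x0))
}

# Small random censored-survival fixture.
rand_surv <- function(n, seed, event_rate = 0.1, censor_rate = 0.05,
                      beta = 0, x = NULL) {
  set.seed(seed)
  if (is.null(x)) x <- rnorm(n)
  tt <- rexp(n, event_rate * exp(beta * x))
  cc <- rexp(n, censor_rate)
  list(time = pmin(tt, cc), event = as.numeric(tt <= cc), x = x)
}

# One-gene ExpressionMatrix wrapper around a plain score vector, for tests
# that exercise PI-based machinery directly.
pi_of <- function(values) {
  n <- length(values)
  compute_pi(matrix(values, 1, dimnames = list("g", sprintf("s%03d", 1:n))),
             c(g = 1))
}

tmp_tsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
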
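#' Prognostic index (risk score) of a signature
#'
#' The linear predictor of the Cox model, PI = sum_i beta_i x_i per sample;
#' higher PI means higher modeled risk.
#'
#' @param expr gene-by-sample [expression_matrix()] (or plain matrix)
#'   restricted to the active signature genes.
#' @param betas named numeric coefficients aligned to the expression rows.
#' @param source provenance label, `"cox_fit"` or `"user_weights"`.
#' @return object of class `prognostic_index` with `sample_ids`, `pi`,
#'   `betas`, `source`.
#' @export
compute_pi <- function(expr, betas, source = c("cox_fit", "user_weights")) {
  source <- match.arg(source)
  v <- if (inherits(expr, "ExpressionMatrix")) expr$values else expr
  if (is.null(names(betas))) {
    if (length(betas) != nrow(v)) fail("unnamed betas must match row count")
    names(betas) <- rownames(v)
  }
  miss <- setdiff(names(betas), rownames(v))
  extra <- setdiff(rownames(v), names(betas))
  if (length(miss) || length(extra))
    fail("gene sets misaligned; betas without rows: ",
         paste(miss, collapse = ", "), "; rows without betas: ",
         paste(extra, collapse = ", "))
  b <- betas[rownames(v)]
  pi_ <- drop(crossprod(v, b))
  structure(list(sample_ids = colnames(v), pi = setNames(pi_, colnames(v)),
                 betas = b, source = source),
            class = "prognostic_index")
}

#' @export
print.prognostic_index <- function(x, ...) {
  cat(sprintf("Prognostic index (%s): %d samples, %d genes, range [%.3g, %.3g]\n",
              x$source, length(x$pi), length(x$betas),
              min(x$pi), max(x$pi)))
  invisible(x)
}

#' Obtain risk coefficients: Cox fitting or user weights
#'
#' In `"cox"` mode all signature genes enter one multivariate Cox model and
#' its coefficients are returned; zero-variance genes are dropped with a
#' warning and the model refit on the remainder. In `"user"` mode the
#' signature's weights are returned verbatim and no fitting occurs.
#'
#' @param expr gene-by-sample [expression_matrix()] restricted to signature
#'   genes, samples aligned to `clinical`.
#' @param clinical a [clinical_table()] aligned to `expr` samples.
#' @param sig the [gene_signature()] (required for `"user"` weights; in
#'   `"cox"` mode used only to check gene order when provided).
#' @param mode `"cox"` or `"user"`.
#' @param ties tie handling passed to [cox_fit()].
#' @return list with `betas` (named), `fit` (a [cox_fit()] or `NULL`) and
#'   `dropped` (zero-variance genes removed).
#' @export
fit_or_weights <- function(expr, clinical, sig = NULL,
                           mode = c("cox", "user"), ties = "efron") {
  mode <- match.arg(mode)
  v <- if (inherits(expr, "ExpressionMatrix")) expr$values else expr
  if (!identical(colnames(v), clinical$sample_id))
    fail("expression samples and clinical rows must be aligned")
  if (mode == "user") {
    if (is.null(sig) || is.null(sig$weights))
      fail("mode 'user' requires a weight for every signature entry")
    miss <- setdiff(rownames(v), names(sig$weights))
    if (length(miss))
      fail("missing user weights for: ", paste(miss, collapse = ", "))
    return(list(betas = sig$weights[rownames(v)], fit = NULL,
                dropped = character(0)))
  }
  vars <- apply(v, 1, var)
  dropped <- rownames(v)[vars < .Machine$double.eps * 100]
  if (length(dropped)) {
    warning("zero-variance gene(s) dropped from Cox fit: ",
            paste(dropped, collapse = ", "))
    v <- v[setdiff(rownames(v), dropped), , drop = FALSE]
    if (nrow(v) == 0L) fail("no genes left after dropping zero-variance rows")
  }
  fit <- cox_fit(t(v), clinical$time, clinical$event, ties = ties)
  list(betas = fit$coefficients, fit = fit, dropped = dropped)
}

# Order samples by PI with a stable, deterministic tie-break (input order).
pi_order <- function(pi_) order(pi_, seq_along(pi_))

# Enforce the rule that tied PI values never straddle a group boundary:
# samples tied with the last member of a lower group are pulled down into it.
untie_labels <- function(labels_sorted, pi_sorted, k) {
  for (b in seq_len(k - 1L)) {
    in_b <- which(labels_sorted == b)
    if (!length(in_b)) next
    v <- pi_sorted[max(in_b)]
    labels_sorted[labels_sorted > b & pi_sorted == v] <- b
  }
  labels_sorted
}

new_risk_grouping <- function(labels, pi, method, separation, min_group_size,
                              scan = NULL) {
  ord <- pi_order(pi$pi)
  split_points <- vapply(seq_len(max(labels) - 1L), function(b)
    max(pi$pi[labels == b]), 0)
  structure(list(labels = labels, sample_ids = pi$sample_ids,
                 split_points = split_points, method = method,
                 k = max(labels), separation = separation,
                 min_group_size = min_group_size, scan = scan),
            class = "risk_grouping")
}

#' @export
print.risk_grouping <- function(x, ...) {
  cat(sprintf("Risk grouping (%s): %d groups, sizes %s\n", x$method, x$k,
              paste(tabulate(x$labels, x$k), collapse = "/")))
  if (!is.null(x$separation))
    cat(sprintf("  separation: log-rank chisq %.4g, p = %.4g\n",
                x$separation$statistic, x$separation$p_value))
  invisible(x)
}

#' Quantile (equal-size) risk groups
#'
#' Samples are ordered by PI and cut into k contiguous blocks whose sizes
#' differ by at most one; remainder samples go to the lower-risk groups
#' first, so for k = 2 and even n this is the median split. Group 1 is
#' lowest risk. Tied PI values never straddle a boundary (they stay on the
#' lower-risk side, which can unbalance sizes in degenerate data).
#'
#' @param pi a [compute_pi()] result.
#' @param k number of groups (>= 2).
#' @param time,event optional survival data; when given, the k-group
#'   log-rank separation is computed and stored.
#' @return object of class `risk_grouping`.
#' @export
assign_groups_quantile <- function(pi, k = 2L, time = NULL, event = NULL) {
  n <- length(pi$pi)
  if (k < 2L) fail("'k' must be >= 2")
  if (n < k) fail("need at least k samples")
  sizes <- rep(n %/% k, k)
  r <- n %% k
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  ord <- pi_order(pi$pi)
  lab_sorted <- rep(seq_len(k), sizes)
  lab_sorted <- untie_labels(lab_sorted, pi$pi[ord], k)
  labels <- integer(n)
  labels[ord] <- lab_sorted
  sep <- if (!is.null(time)) logrank_test(time, event, labels) else NULL
  new_risk_grouping(labels, pi, "quantile", sep, min_group_size = min(sizes))
}

# Admissible 2-group boundary positions in a PI-sorted sample list:
# both sides >= min_size and no tied PI straddling the cut.
admissible_cuts <- function(pi_sorted, lo, hi) {
  s <- seq.int(lo, hi)
  s[pi_sorted[s] < pi_sorted[s + 1L]]
}

# Scan every admissible boundary position for one moving boundary (k-group
# log-rank on the implied labels); returns positions, chi-square and p.
scan_boundary <- function(pi_sorted, time_sorted, event_sorted, bounds,
                          which_b, lo, hi, k) {
  cuts <- admissible_cuts(pi_sorted, lo, hi)
  if (length(cuts) == 0L) return(NULL)
  stats <- numeric(length(cuts))
  for (i in seq_along(cuts)) {
    b <- bounds
    b[which_b] <- cuts[i]
    lab <- rep.int(seq_len(k), diff(c(0L, b, length(pi_sorted))))
    stats[i] <- logrank_core(time_sorted, event_sorted, lab, k)$statistic
  }
  p <- pchisq(stats, df = k - 1, lower.tail = FALSE)
  list(positions = cuts, statistic = stats, p_value = p)
}

#' Log-rank-optimized risk groups
#'
#' For two groups, a log-rank test is evaluated at every admissible split
#' position along the PI-ordered samples and the boundary with the minimum
#' p-value is chosen (exhaustive scan). For k > 2, boundaries are
#' initialized from the quantile split and refined coordinate-wise: each
#' boundary in turn is re-optimized by the same scan with the others held
#' fixed, cycling until a full pass changes nothing (hard cap 100 cycles).
#' Admissible splits leave every group at least `min_group_size` samples
#' and never separate tied PI values (ties stay on the lower-risk side).
#'
#' The reported minimum p-value is a maximally selected statistic and is
#' optimistically biased; see [split_pvalue_bias_check()] for a
#' selection-adjusted permutation p.
#'
#' @param pi a [compute_pi()] result.
#' @param time,event survival data aligned to `pi`.
#' @param k number of groups (>= 2).
#' @param min_group_size minimum samples per group; default
#'   `max(5, ceiling(0.1 * n))`.
#' @return object of class `risk_grouping`; `scan` holds the final moving
#'   boundary's (position, chi-square, p) profile for risk-optimization
#'   plots, and `cycles` the number of refinement cycles used.
#' @export
optimize_groups <- function(pi, time, event, k = 2L, min_group_size = NULL) {
  check_surv_vectors(time, event)
  n <- length(pi$pi)
  if (length(time) != n) fail("'time' length must match PI")
  if (k < 2L) fail("'k' must be >= 2")
  min_group_size <- min_group_size %||% max(5L, ceiling(0.1 * n))
  if (n < k * min_group_size)
    fail("infeasible min_group_size: need at least ", k * min_group_size,
         " samples")
  ord <- pi_order(pi$pi)
  ps <- pi$pi[ord]; ts <- time[ord]; es <- event[ord]

  if (k == 2L) {
    scan <- scan_boundary(ps, ts, es, bounds = 0L, which_b = 1L,
                          lo = min_group_size, hi = n - min_group_size,
                          k = 2L)
    if (is.null(scan)) fail("no admissible split point (PI ties too heavy)")
    best <- which.max(scan$statistic)  # max chisq = min p; first on ties
    bounds <- scan$positions[best]
    cycles <- 1L
  } else {
    sizes <- rep(n %/% k, k); rr <- n %% k
    if (rr > 0) sizes[seq_len(rr)] <- sizes[seq_len(rr)] + 1L
    bounds <- cumsum(sizes)[seq_len(k - 1L)]
    # nudge infeasible initial boundaries onto admissible cuts
    cur_stat <- -Inf
    cycles <- 0L
    scan <- NULL
    repeat {
      cycles <- cycles + 1L
      changed <- FALSE
      for (b in seq_len(k - 1L)) {
        lo <- max(if (b == 1L) min_group_size else bounds[b - 1L] + min_group_size,
                  min_group_size)
        hi <- min(if (b == k - 1L) n - min_group_size
                  else bounds[b + 1L] - min_group_size,
                  n - min_group_size)
        if (lo > hi) next
        sc <- scan_boundary(ps, ts, es, bounds, b, lo, hi, k)
        if (is.null(sc)) next
        best <- which.max(sc$statistic)
        if (sc$statistic[best] > cur_stat + 1e-12 &&
            sc$positions[best] != bounds[b]) {
          bounds[b] <- sc$positions[best]
          cur_stat <- sc$statistic[best]
          changed <- TRUE
        } else if (sc$statistic[best] > cur_stat) {
          cur_stat <- sc$statistic[best]
        }
        scan <- sc
      }
      if (!changed) break
      if (cycles >= 100L) {
        warning("boundary refinement hit the 100-cycle cap")
        break
      }
    }
  }
  lab_sorted <- rep.int(seq_len(k), diff(c(0L, bounds, n)))
  lab_sorted <- untie_labels(lab_sorted, ps, k)
  labels <- integer(n)
  labels[ord] <- lab_sorted
  sep <- logrank_test(time, event, labels)
  g <- new_risk_grouping(labels, pi, "optimized", sep, min_group_size,
                         scan = scan)
  g$cycles <- cycles
  g
}

#' Assign risk-group labels to new samples from learned split points
#'
#' Samples with PI at or below a split point fall in the lower-risk group
#' (consistent with the tie rule used when learning the split).
#'
#' @param pi a [compute_pi()] result for the new samples.
#' @param split_points increasing PI thresholds (from a `risk_grouping`).
#' @return integer labels 1..k.
#' @export
apply_split_points <- function(pi, split_points) {
  vapply(pi$pi, function(v) 1L + sum(v > split_points), 0L)
}

#' Permutation diagnostic for the optimized-split minimum p-value
#'
#' The minimum p-value over all candidate split points is a maximally
#' selected statistic whose naive reference distribution is optimistic.
#' This diagnostic permutes the (time, event) pairs against the PI
#' `n_perm` times, re-runs the optimizer, and returns the fraction of
#' permuted minimum p-values at or below the observed one — an honest
#' selection-adjusted p-value.
#'
#' @param pi a [compute_pi()] result.
#' @param time,event survival data.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed for the permutation stream.
#' @param k,min_group_size passed to [optimize_groups()].
#' @return list with `p_adjusted`, `p_naive`, `n_perm`.
#' @export
split_pvalue_bias_check <- function(pi, time, event, n_perm = 200L,
                                    seed = 1L, k = 2L,
                                    min_group_size = NULL) {
  if (n_perm < 100L) fail("'n_perm' must be >= 100")
  obs <- optimize_groups(pi, time, event, k = k,
                         min_group_size = min_group_size)
  p_obs <- obs$separation$p_value
  n <- length(time)
  perm_p <- numeric(n_perm)
  set.seed(seed)
  for (i in seq_len(n_perm)) {
    idx <- sample.int(n)
    g <- optimize_groups(pi, time[idx], event[idx], k = k,
                         min_group_size = min_group_size)
    perm_p[i] <- g$separation$p_value
  }
  list(p_adjusted = mean(perm_p <= p_obs), p_naive = p_obs,
       n_perm = n_perm, grouping = obs)
}
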
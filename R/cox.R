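# Partial log-likelihood, gradient and observed information for the Cox
# proportional-hazards model, with Efron or Breslow handling of tied event
# times. Risk-set sums are accumulated over distinct times in descending
# order so the whole evaluation is O(n p^2) after one sort.
cox_pl <- function(beta, X, time, event, ties = "efron") {
  n <- nrow(X); p <- ncol(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)
  ord <- order(time, decreasing = TRUE)
  tt <- time[ord]; ee <- event[ord]
  Xo <- X[ord, , drop = FALSE]; wo <- w[ord]; etao <- eta[ord]
  ll <- 0; grad <- numeric(p); info <- matrix(0, p, p)
  W <- 0; S1 <- numeric(p); S2 <- matrix(0, p, p)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j <= n && tt[j] == tt[i]) j <- j + 1L
    idx <- i:(j - 1L)
    xi <- Xo[idx, , drop = FALSE]
    W <- W + sum(wo[idx])
    S1 <- S1 + colSums(wo[idx] * xi)
    S2 <- S2 + crossprod(xi * sqrt(wo[idx]))
    ev <- idx[ee[idx] == 1]
    d <- length(ev)
    if (d > 0L) {
      xe <- Xo[ev, , drop = FALSE]
      ll <- ll + sum(etao[ev])
      grad <- grad + colSums(xe)
      if (ties == "breslow") {
        mu <- S1 / W
        ll <- ll - d * log(W)
        grad <- grad - d * mu
        info <- info + d * (S2 / W - tcrossprod(mu))
      } else {
        wd <- sum(wo[ev])
        S1d <- colSums(wo[ev] * xe)
        S2d <- crossprod(xe * sqrt(wo[ev]))
        for (l in seq_len(d) - 1L) {
          f <- l / d
          Wl <- W - f * wd
          mu <- (S1 - f * S1d) / Wl
          ll <- ll - log(Wl)
          grad <- grad - mu
          info <- info + ((S2 - f * S2d) / Wl - tcrossprod(mu))
        }
      }
    }
    i <- j
  }
  list(loglik = ll, gradient = grad, info = info)
}

#' Fit a Cox proportional-hazards model by Newton-Raphson
#'
#' Maximizes the partial likelihood with Efron (default) or Breslow tie
#' handling. Standard errors come from the inverse observed information;
#' per-covariate Wald p-values are two-sided normal. Convergence is declared
#' when the gradient max-norm drops below `grad_tol` or the relative
#' log-likelihood change drops below `ll_tol`; step-halving guards
#' overshooting, and a monotone-likelihood fit (coefficients drifting to
#' infinity) is returned flagged non-converged with a warning.
#'
#' @param X samples-by-covariates numeric matrix (complete cases only;
#'   zero-variance columns are an error so callers can drop them).
#' @param time positive follow-up times.
#' @param event 0/1 event indicators.
#' @param ties `"efron"` or `"breslow"`.
#' @param max_iter,grad_tol,ll_tol Newton-Raphson controls.
#' @return object of class `cox_fit`: `coefficients`, `se`, `z`, `wald_p`,
#'   `var` (covariance), `loglik` (start, convergence), `iterations`,
#'   `converged`, `ties`, `n`, `n_event`.
#' @export
cox_fit <- function(X, time, event, ties = c("efron", "breslow"),
                    max_iter = 50L, grad_tol = 1e-8, ll_tol = 1e-9) {
  ties <- match.arg(ties)
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  check_surv_vectors(time, event)
  if (nrow(X) != length(time)) fail("'X' rows must match 'time' length")
  if (anyNA(X)) fail("'X' must be complete (impute or drop incomplete cases)")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  vars <- apply(X, 2, var)
  if (any(vars < .Machine$double.eps * 100))
    fail("zero-variance covariate(s): ",
         paste(colnames(X)[vars < .Machine$double.eps * 100], collapse = ", "))
  if (sum(event) == 0L) fail("no events observed; Cox model undefined")

  p <- ncol(X)
  beta <- numeric(p)
  ev0 <- cox_pl(beta, X, time, event, ties)
  loglik0 <- ev0$loglik
  ev <- ev0
  converged <- FALSE
  monotone <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(ev$info, ev$gradient), error = function(e) NULL)
    if (is.null(step)) { monotone <- TRUE; break }
    halve <- 0L
    repeat {
      cand <- beta + step
      ev_new <- cox_pl(cand, X, time, event, ties)
      if (is.finite(ev_new$loglik) && ev_new$loglik >= ev$loglik - 1e-12) break
      step <- step / 2
      halve <- halve + 1L
      if (halve > 20L) break
    }
    if (halve > 20L) break
    rel <- abs(ev_new$loglik - ev$loglik) /
      max(abs(ev$loglik), .Machine$double.eps)
    beta <- cand
    ev <- ev_new
    if (max(abs(ev$gradient)) < grad_tol || rel < ll_tol) {
      converged <- TRUE
      break
    }
    if (max(abs(beta)) > 20) { monotone <- TRUE; break }
  }
  if (!converged)
    warning(if (monotone)
      "possible monotone likelihood: coefficients diverging, fit flagged"
      else "Cox fit did not converge within iteration limit")
  covmat <- tryCatch(solve(ev$info), error = function(e)
    matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(covmat), 0))
  z <- beta / se
  structure(list(coefficients = setNames(beta, colnames(X)),
                 se = setNames(se, colnames(X)),
                 z = setNames(z, colnames(X)),
                 wald_p = setNames(2 * pnorm(-abs(z)), colnames(X)),
                 var = covmat,
                 loglik = c(start = loglik0, final = ev$loglik),
                 iterations = iter, converged = converged,
                 monotone = monotone, ties = ties,
                 n = length(time), n_event = sum(event)),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox fit (%s ties): n = %d, events = %d, %s in %d iteration(s)\n",
              x$ties, x$n, x$n_event,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  tab <- data.frame(coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
                    se = x$se, z = x$z, p = x$wald_p, check.names = FALSE)
  print(tab, digits = 4)
  invisible(x)
}

#' Coefficient table of a Cox fit (gene, beta, HR, SE, Wald p)
#' @param fit a [cox_fit()].
#' @return data.frame.
#' @export
cox_table <- function(fit) {
  data.frame(gene = names(fit$coefficients),
             beta = unname(fit$coefficients),
             hr = unname(exp(fit$coefficients)),
             se = unname(fit$se),
             z = unname(fit$z),
             wald_p = unname(fit$wald_p),
             stringsAsFactors = FALSE)
}

#' Hazard ratio between two groups
#'
#' Univariate Cox fit on the indicator of the second factor level;
#' HR = exp(beta) with a 95% Wald interval. When one group has no events the
#' likelihood is monotone; the fit is flagged and the interval unbounded.
#'
#' @param time,event survival data.
#' @param group labels with exactly 2 levels; the HR is for level 2 vs
#'   level 1.
#' @return list with `hr`, `ci95`, `p`, `beta`, `se`, `flagged`.
#' @export
hazard_ratio <- function(time, event, group) {
  f <- factor(group)
  if (nlevels(f) != 2L) fail("'group' must have exactly 2 levels")
  if (any(tabulate(f, 2L) == 0L)) fail("both groups must be non-empty")
  if (sum(event) == 0L) fail("need at least one event")
  x <- matrix(as.numeric(f == levels(f)[2]), ncol = 1L,
              dimnames = list(NULL, "group"))
  ev_per_group <- tapply(event, f, sum)
  fit <- withCallingHandlers(
    cox_fit(x, time, event),
    warning = function(w) invokeRestart("muffleWarning"))
  flagged <- !fit$converged || any(ev_per_group == 0)
  if (any(ev_per_group == 0))
    warning("no events in one group: monotone likelihood, CI unbounded")
  b <- fit$coefficients[[1]]; s <- fit$se[[1]]
  ci <- if (flagged && !is.finite(s)) c(0, Inf)
        else exp(b + c(-1, 1) * qnorm(0.975) * s)
  list(hr = exp(b), ci95 = ci, p = fit$wald_p[[1]],
       beta = b, se = s, flagged = flagged)
}
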
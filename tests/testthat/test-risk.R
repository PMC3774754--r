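test_that("compute_pi is the stated linear combination and is linear", {
  m <- rbind(g1 = c(2, 1), g2 = c(3, 4))
  colnames(m) <- c("A", "B")
  # beta = (1, -1), x_A = (2, 3) -> PI_A = -1
  p <- compute_pi(m, c(g1 = 1, g2 = -1))
  expect_equal(unname(p$pi), c(-1, -3))
  # all betas zero -> PI identically 0
  expect_equal(unname(compute_pi(m, c(g1 = 0, g2 = 0))$pi), c(0, 0))
  # single gene with beta = 1 -> PI equals the expression row
  expect_equal(unname(compute_pi(m["g1", , drop = FALSE], c(g1 = 1))$pi),
               unname(m["g1", ]))
  # linearity in beta
  set.seed(6)
  mm <- matrix(rnorm(40), 4, 10,
               dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  b1 <- setNames(rnorm(4), rownames(mm))
  b2 <- setNames(rnorm(4), rownames(mm))
  expect_equal(compute_pi(mm, 2.5 * b1)$pi, 2.5 * compute_pi(mm, b1)$pi)
  expect_equal(compute_pi(mm, b1 + b2)$pi,
               compute_pi(mm, b1)$pi + compute_pi(mm, b2)$pi)
  expect_error(compute_pi(mm, c(bad = 1)), "misaligned")
})

test_that("fit_or_weights passes user weights verbatim and delegates Cox", {
  d <- simulate_dataset(sim_config(n = 80, q = 0, seed = 5))
  sigw <- gene_signature(rownames(d$expression$values),
                         weights = c(0.5, -0.2, 0.1, 0, 0.3))
  fw <- fit_or_weights(d$expression, d$clinical, sigw, mode = "user")
  expect_null(fw$fit)
  expect_equal(unname(fw$betas), c(0.5, -0.2, 0.1, 0, 0.3))
  # cox mode equals a direct cox_fit call
  fw2 <- fit_or_weights(d$expression, d$clinical, mode = "cox")
  direct <- cox_fit(t(d$expression$values), d$clinical$time,
                    d$clinical$event)
  expect_equal(fw2$betas, direct$coefficients)
  # partial weights are an error
  expect_error(fit_or_weights(d$expression, d$clinical,
                              gene_signature(rownames(d$expression$values)),
                              mode = "user"),
               "weight")
})

test_that("a zero-variance gene is dropped with a warning and the model refit", {
  d <- simulate_dataset(sim_config(n = 60, q = 0, seed = 9))
  v <- d$expression$values
  v["SIG05", ] <- 7  # constant
  e <- expression_matrix(v)
  expect_warning(fw <- fit_or_weights(e, d$clinical, mode = "cox"), "SIG05")
  expect_equal(fw$dropped, "SIG05")
  expect_setequal(names(fw$betas), paste0("SIG0", 1:4))
})

test_that("quantile groups: equal sizes, median split, low-risk remainder", {
  set.seed(14)
  p10 <- pi_of(rnorm(10))
  g <- assign_groups_quantile(p10, 2)
  expect_equal(unname(tabulate(g$labels, 2)), c(5, 5))
  expect_equal(g$split_points,
               max(sort(p10$pi)[1:5]))  # threshold at the median boundary
  expect_true(all(p10$pi[g$labels == 1] <= min(p10$pi[g$labels == 2])))
  p9 <- pi_of(rnorm(9))
  expect_equal(unname(tabulate(assign_groups_quantile(p9, 3)$labels, 3)),
               c(3, 3, 3))
  # remainder goes to the lower-risk group
  expect_equal(unname(tabulate(assign_groups_quantile(p9, 2)$labels, 2)),
               c(5, 4))
  expect_error(assign_groups_quantile(p9, 10), "at least")
})

test_that("group labels are monotone in PI and concatenate to sorted order", {
  for (s in 1:5) {
    set.seed(s)
    p <- pi_of(rnorm(37))
    k <- sample(2:4, 1)
    g <- assign_groups_quantile(p, k)
    ord <- order(p$pi, seq_along(p$pi))
    expect_true(all(diff(g$labels[ord]) >= 0))
    expect_lte(diff(range(tabulate(g$labels, k))), 1)
  }
})

test_that("tied PI values never straddle a quantile boundary", {
  p <- pi_of(c(1, 2, 2, 2, 3, 4))
  g <- assign_groups_quantile(p, 2)
  expect_equal(unique(g$labels[p$pi == 2]), 1L)  # all ties on the low side
})

test_that("optimized 2-group split equals the exhaustive-scan oracle", {
  for (s in 1:12) {
    set.seed(s * 7)
    n <- sample(40:200, 1)
    pi_ <- rnorm(n)
    tt <- rexp(n, 0.1 * exp(0.4 * pi_)); cc <- rexp(n, 0.05)
    time <- pmin(tt, cc); event <- as.numeric(tt <= cc)
    p <- pi_of(pi_)
    g <- optimize_groups(p, time, event, k = 2)
    orc <- split_oracle(pi_, time, event, g$min_group_size)
    expect_equal(sum(g$labels == 1), orc$position)
    expect_equal(g$separation$p_value, orc$p, tolerance = 1e-12)
    # never below the floor
    expect_true(all(tabulate(g$labels, 2) >= g$min_group_size))
  }
})

test_that("optimized split p-value never exceeds the median split's", {
  for (s in 1:8) {
    set.seed(100 + s)
    n <- 60
    pi_ <- rnorm(n)
    tt <- rexp(n, 0.1 * exp(0.3 * pi_))
    p <- pi_of(pi_)
    g_opt <- optimize_groups(p, tt, rep(1, n), k = 2)
    g_med <- assign_groups_quantile(p, 2, tt, rep(1, n))
    expect_lte(g_opt$separation$p_value, g_med$separation$p_value + 1e-12)
  }
})

test_that("a sharp planted flip in survival is recovered at the boundary", {
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    n <- 300; m <- 150
    pi_ <- sort(runif(n))
    rate <- ifelse(seq_len(n) > m, 1.0, 0.1)  # sharp distribution flip
    tt <- rexp(n, rate)
    g <- optimize_groups(pi_of(pi_), tt, rep(1, n), k = 2)
    if (abs(sum(g$labels == 1) - m) <= 2) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("k = 3 refinement terminates, respects the floor and separates
           a three-population design", {
  set.seed(31)
  n <- 150
  pi_ <- sort(rnorm(n))
  rate <- c(rep(0.05, 50), rep(0.2, 50), rep(0.8, 50))
  tt <- rexp(n, rate)
  g <- optimize_groups(pi_of(pi_), tt, rep(1, n), k = 3,
                       min_group_size = 15)
  expect_equal(g$k, 3)
  expect_true(all(tabulate(g$labels, 3) >= 15))
  expect_lt(g$cycles, 100)
  expect_lt(g$separation$p_value, 1e-6)
  # boundaries land near the planted 50/100 positions
  sizes <- cumsum(tabulate(g$labels, 3))[1:2]
  expect_lt(max(abs(sizes - c(50, 100))), 10)
})

test_that("permutation diagnostic validates its inputs and null behavior", {
  d <- rand_surv(40, seed = 3)
  p <- pi_of(rnorm(40))
  expect_error(split_pvalue_bias_check(p, d$time, d$event, n_perm = 50),
               ">= 100")
  r <- split_pvalue_bias_check(p, d$time, d$event, n_perm = 100, seed = 4)
  expect_true(r$p_adjusted >= 0 && r$p_adjusted <= 1)
  # the adjusted p is never smaller than the naive minimum-p suggests
  expect_gte(r$p_adjusted, 0)
  expect_equal(r$n_perm, 100)
})

test_that("train/test: thresholds learned on training generalize", {
  wins <- 0
  for (s in 1:20) {
    d <- simulate_dataset(sim_config(n = 160, q = 2, seed = 400 + s))
    sig <- gene_signature(names(d$truth$betas))
    ids <- d$clinical$sample_id
    tr <- ids[1:100]; te <- ids[101:160]
    res <- suppressWarnings(suppressMessages(
      train_test_run(d$expression, d$clinical, sig,
                     train_ids = tr, test_ids = te)))
    lab <- res$test$labels
    cl <- res$test$clinical
    hi_rate <- mean(cl$event[lab == 2])
    lo_rate <- mean(cl$event[lab == 1])
    if (isTRUE(hi_rate > lo_rate)) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("train/test input contracts: overlap, empties, small-train warning", {
  d <- simulate_dataset(sim_config(n = 40, q = 0, seed = 2))
  sig <- gene_signature(names(d$truth$betas))
  ids <- d$clinical$sample_id
  expect_error(train_test_run(d$expression, d$clinical, sig,
                              train_ids = ids[1:20], test_ids = ids[15:30]),
               "overlap")
  expect_error(train_test_run(d$expression, d$clinical, sig,
                              train_ids = ids[1:20],
                              test_ids = character(0)),
               "empty test")
  expect_warning(suppressMessages(
    train_test_run(d$expression, d$clinical, sig,
                   train_ids = ids[1:25], test_ids = ids[26:40])),
    "few events")
})

test_that("stratified analysis partitions by covariate and skips tiny strata", {
  d <- simulate_dataset(sim_config(n = 120, q = 0, seed = 55))
  sig <- gene_signature(names(d$truth$betas))
  res <- suppressMessages(
    stratified_run(d$expression, d$clinical, sig, stratum_col = "grade",
                   min_n = 10))
  expect_setequal(names(res$strata),
                  unique(d$clinical$grade))
  expect_equal(nrow(res$summary), length(res$strata))
  # strata are disjoint and each report used only its own samples
  ns <- vapply(res$strata, function(r) nrow(r$clinical), 0L)
  expect_equal(sum(ns), 120L)
  # a covariate level below min_n is skipped with a note
  d$clinical$grade[1] <- "G9"
  res2 <- suppressMessages(
    stratified_run(d$expression, d$clinical, sig, stratum_col = "grade",
                   min_n = 10))
  expect_match(res2$skipped[["G9"]], "below minimum")
  expect_error(stratified_run(d$expression, d$clinical, sig,
                              stratum_col = "nope"),
               "nope")
})

test_that("signature is prognostic only in the planted stratum", {
  better <- 0
  for (s in 1:20) {
    set.seed(700 + s)
    n <- 150
    strat <- rep(c("A", "B", "C"), each = n / 3)
    x <- matrix(rnorm(2 * n, 8), 2, n,
                dimnames = list(c("g1", "g2"),
                                sprintf("s%03d", 1:n)))
    xc <- x - rowMeans(x)
    eff <- ifelse(strat == "A", 1.2, 0)  # prognostic in A only
    tt <- rexp(n, 0.1 * exp(eff * xc["g1", ]))
    cc <- rexp(n, 0.04)
    clin <- clinical_table(colnames(x), pmin(tt, cc),
                           as.numeric(tt <= cc),
                           covariates = data.frame(stratum = strat))
    res <- suppressWarnings(suppressMessages(
      stratified_run(expression_matrix(x), clin,
                     gene_signature(c("g1", "g2")), stratum_col = "stratum",
                     min_n = 10)))
    pA <- res$summary$logrank_p[res$summary$stratum == "A"]
    pBC <- res$summary$logrank_p[res$summary$stratum != "A"]
    if (length(pA) == 1 && all(pA < pBC)) better <- better + 1
  }
  expect_gte(better, 18)
})
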
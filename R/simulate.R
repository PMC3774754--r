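#' Simulation configuration for proportional-hazards fixtures
#'
#' Defines a synthetic cohort: per-gene normal expression on the log2 scale,
#' exponential baseline hazard, and a per-sample hazard multiplier
#' exp(sum beta_i * centered x_i), so `lambda` is the event rate of a
#' median subject. Censoring is an independent exponential whose rate
#' targets the requested censoring fraction (rate = lambda * f / (1 - f)
#' under the null), or an administrative cutoff.
#'
#' @param n samples.
#' @param p signature genes carrying the listed `betas`.
#' @param q additional noise genes with beta = 0.
#' @param betas true risk coefficients, length `p`.
#' @param lambda baseline (median-subject) exponential event rate.
#' @param censoring_fraction target fraction censored (default 0.3); ignored
#'   when `admin_cutoff` is given.
#' @param admin_cutoff optional administrative censoring time.
#' @param mu_range,sigma_range per-gene mean/SD ranges on the log2 scale.
#' @param seed RNG seed fixing the whole stream.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n = 200L, p = 5L, q = 20L,
                       betas = c(0.7, -0.5, 0.3, 0, 0),
                       lambda = 0.1, censoring_fraction = 0.3,
                       admin_cutoff = NULL,
                       mu_range = c(6, 10), sigma_range = c(0.5, 1.5),
                       seed = 1L) {
  if (length(betas) != p) fail("'betas' must have length p")
  if (lambda <= 0) fail("'lambda' must be > 0")
  if (is.null(admin_cutoff) &&
      (censoring_fraction < 0 || censoring_fraction >= 1))
    fail("'censoring_fraction' must be in [0, 1)")
  if (!is.null(admin_cutoff) && admin_cutoff <= 0)
    fail("'admin_cutoff' must be > 0")
  structure(list(n = as.integer(n), p = as.integer(p), q = as.integer(q),
                 betas = betas, lambda = lambda,
                 censoring_fraction = censoring_fraction,
                 admin_cutoff = admin_cutoff,
                 mu_range = mu_range, sigma_range = sigma_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate one expression + clinical fixture with known prognostic truth
#'
#' Expression: gene-wise normal draws. Event time T ~ exponential with rate
#' lambda * exp(PI_true) where PI_true uses gene-centered expression;
#' censoring time C independent exponential (or administrative cutoff);
#' time = min(T, C), event = 1[T <= C]. A 3-level `grade` covariate is
#' attached for stratified-analysis exercises.
#'
#' @param cfg a [sim_config()].
#' @return list with `expression` ([expression_matrix()]), `clinical`
#'   ([clinical_table()]) and `truth` (betas, true PI, rates, seed).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ng <- cfg$p + cfg$q
  genes <- c(sprintf("SIG%02d", seq_len(cfg$p)),
             if (cfg$q > 0) sprintf("NOISE%02d", seq_len(cfg$q)))
  samples <- sprintf("S%04d", seq_len(cfg$n))
  mu <- runif(ng, cfg$mu_range[1], cfg$mu_range[2])
  sg <- runif(ng, cfg$sigma_range[1], cfg$sigma_range[2])
  vals <- matrix(rnorm(ng * cfg$n, mean = mu, sd = sg), nrow = ng,
                 dimnames = list(genes, samples))
  xs <- vals[seq_len(cfg$p), , drop = FALSE]
  xc <- xs - rowMeans(xs)
  pi_true <- drop(crossprod(xc, cfg$betas))
  rate <- cfg$lambda * exp(pi_true)
  T_ <- rexp(cfg$n, rate = rate)
  if (is.null(cfg$admin_cutoff)) {
    if (cfg$censoring_fraction > 0) {
      crate <- cfg$lambda * cfg$censoring_fraction /
        (1 - cfg$censoring_fraction)
      C_ <- rexp(cfg$n, rate = crate)
    } else C_ <- rep(Inf, cfg$n)
  } else {
    C_ <- rep(cfg$admin_cutoff, cfg$n)
  }
  time <- pmin(T_, C_)
  event <- as.numeric(T_ <= C_)
  grade <- sample(c("G1", "G2", "G3"), cfg$n, replace = TRUE)
  clin <- clinical_table(samples, time, event,
                         covariates = data.frame(grade = grade,
                                                 stringsAsFactors = FALSE),
                         time_unit = "years")
  list(expression = expression_matrix(vals),
       clinical = clin,
       truth = list(betas = setNames(cfg$betas, genes[seq_len(cfg$p)]),
                    pi_true = setNames(pi_true, samples),
                    lambda = cfg$lambda,
                    censoring_fraction = cfg$censoring_fraction,
                    seed = cfg$seed))
}

#' Simulate multiple cohorts sharing one prognostic truth
#'
#' Each cohort is generated under the same configuration (fresh draws, seeds
#' derived from `cfg$seed`), then distorted by a cohort-specific location
#' shift and scale on the expression values — the batch structure the
#' meta-base merge is designed to remove.
#'
#' @param cfg a [sim_config()] (per-cohort sample size `cfg$n`).
#' @param k number of cohorts (>= 2).
#' @param shifts numeric length-k location distortions (default 0).
#' @param scales numeric length-k scale distortions (default 1).
#' @return list of k elements, each with `expression`, `clinical`, `truth`,
#'   `cohort_id`.
#' @export
simulate_multicohort <- function(cfg, k = 2L, shifts = rep(0, k),
                                 scales = rep(1, k)) {
  if (k < 2L) fail("'k' must be >= 2")
  if (length(shifts) != k || length(scales) != k)
    fail("'shifts' and 'scales' must have length k")
  lapply(seq_len(k), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + 1000L * i
    d <- simulate_dataset(cfg_i)
    v <- d$expression$values * scales[i] + shifts[i]
    colnames(v) <- paste0("C", i, "_", colnames(v))
    d$clinical$sample_id <- paste0("C", i, "_", d$clinical$sample_id)
    d$expression <- expression_matrix(v)
    d$cohort_id <- paste0("cohort", i)
    d
  })
}

# Shared TSV writer: matrix with an id column, deterministic formatting.
write_tsv_matrix <- function(mat, path, id_col = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated fixture to delimited files plus a truth JSON
#' @param dataset a [simulate_dataset()] result.
#' @param outdir output directory; writes `expression.tsv`, `clinical.tsv`,
#'   `signature.txt`, `truth.json`.
#' @return invisibly, the file paths.
#' @export
write_fixture <- function(dataset, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fe <- file.path(outdir, "expression.tsv")
  fc <- file.path(outdir, "clinical.tsv")
  fs <- file.path(outdir, "signature.txt")
  ft <- file.path(outdir, "truth.json")
  write_tsv_matrix(dataset$expression$values, fe, id_col = "gene")
  write.table(as.data.frame(dataset$clinical), fc, sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeLines(names(dataset$truth$betas), fs)
  jsonlite::write_json(dataset$truth, ft, auto_unbox = TRUE, digits = NA)
  invisible(c(fe, fc, fs, ft))
}
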
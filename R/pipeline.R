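#' Run the full signature-evaluation pipeline
#'
#' Orchestrates: sample join, preprocessing, identifier resolution, probe
#' collapsing, Cox fitting (or user weights), prognostic-index computation,
#' risk-group generation, and the survival statistics (log-rank, hazard
#' ratio, concordance overall and within each group, per-gene group tests,
#' optional time-dependent ROC).
#'
#' @param expression an [expression_matrix()].
#' @param clinical a [clinical_table()].
#' @param signature a [gene_signature()].
#' @param annotation optional [read_gene_info()] index.
#' @param k number of risk groups.
#' @param method `"quantile"` (equal-size split; median for k = 2) or
#'   `"optimized"` (log-rank-minimizing split points).
#' @param mode `"cox"` (multivariate Cox coefficients) or `"user"`
#'   (signature weights taken verbatim).
#' @param collapse probe collapsing rule, see [collapse_probes()].
#' @param log2,qnorm preprocessing switches, see [preprocess()].
#' @param tdroc_time optional horizon for [td_roc()]; skipped when `NULL`.
#' @param tdroc_estimator `"nne"` or `"km"`.
#' @param min_group_size floor for optimized groups (default
#'   `max(5, ceiling(0.1 n))`).
#' @param ties Cox tie handling.
#' @return object of class `survsig_report`.
#' @export
run_analysis <- function(expression, clinical, signature, annotation = NULL,
                         k = 2L, method = c("quantile", "optimized"),
                         mode = c("cox", "user"),
                         collapse = "max_row_average",
                         log2 = "auto", qnorm = "off",
                         tdroc_time = NULL, tdroc_estimator = "nne",
                         min_group_size = NULL, ties = "efron") {
  method <- match.arg(method)
  mode <- match.arg(mode)
  joined <- join_samples(expression, clinical)
  expr <- preprocess(joined$expression, log2 = log2, qnorm = qnorm)
  res <- resolve_signature(signature, expr, annotation)
  gexpr <- collapse_probes(expr, res, method = collapse)
  fw <- fit_or_weights(gexpr, joined$clinical, signature, mode = mode,
                       ties = ties)
  used <- names(fw$betas)
  gx <- expression_matrix(gexpr$values[used, , drop = FALSE],
                          gexpr$annotation)
  pi_ <- compute_pi(gx, fw$betas,
                    source = if (mode == "cox") "cox_fit" else "user_weights")
  tm <- joined$clinical$time; ev <- joined$clinical$event
  grouping <- if (method == "quantile")
    assign_groups_quantile(pi_, k, tm, ev)
  else
    optimize_groups(pi_, tm, ev, k = k, min_group_size = min_group_size)
  hr <- if (k == 2L)
    tryCatch(hazard_ratio(tm, ev, grouping$labels), error = function(e) NULL)
    else NULL
  conc <- concordance_index(pi_$pi, tm, ev)
  conc_by_group <- lapply(split(seq_along(tm), grouping$labels), function(ix)
    tryCatch(concordance_index(pi_$pi[ix], tm[ix], ev[ix]),
             error = function(e) NULL))
  tests <- gene_group_tests(gx, grouping$labels)
  roc <- if (!is.null(tdroc_time))
    td_roc(pi_$pi, tm, ev, tdroc_time, estimator = tdroc_estimator)
    else NULL
  structure(list(
    config = list(k = k, method = method, mode = mode, collapse = collapse,
                  log2 = log2, qnorm = qnorm, ties = ties,
                  tdroc_time = tdroc_time,
                  tdroc_estimator = if (is.null(tdroc_time)) NULL
                                    else tdroc_estimator,
                  min_group_size = grouping$min_group_size),
    resolution = res, fit = fw$fit, betas = fw$betas,
    dropped_genes = fw$dropped,
    expression = gx, clinical = joined$clinical,
    pi = pi_, grouping = grouping, hazard_ratio = hr,
    concordance = conc, concordance_by_group = conc_by_group,
    gene_tests = tests, tdroc = roc,
    km_data = km_plot_data(tm, ev, grouping$labels)),
    class = "survsig_report")
}

#' @export
print.survsig_report <- function(x, ...) {
  cat("Signature survival report\n")
  cat(sprintf("  %d gene(s), %d sample(s), %d risk group(s) (%s split)\n",
              length(x$betas), nrow(x$clinical), x$grouping$k,
              x$grouping$method))
  cat(sprintf("  log-rank p = %.4g; concordance = %.3f\n",
              x$grouping$separation$p_value, x$concordance$c_index))
  if (!is.null(x$hazard_ratio))
    cat(sprintf("  hazard ratio (high vs low) = %.3f [%.3f, %.3f]\n",
                x$hazard_ratio$hr, x$hazard_ratio$ci95[1],
                x$hazard_ratio$ci95[2]))
  if (!is.null(x$tdroc))
    cat(sprintf("  tdROC AUC at t = %g: %.3f\n", x$tdroc$t, x$tdroc$auc))
  cat(sprintf("  differential genes between groups (p < 0.05): %d of %d\n",
              x$gene_tests$n_differential, length(x$betas)))
  invisible(x)
}

#' Train/test evaluation of a signature
#'
#' Coefficients are estimated on the training samples only; the prognostic
#' index of both sets uses the training betas; risk thresholds are learned
#' on the training PI and applied unchanged to the test samples. All
#' statistics are reported separately per set.
#'
#' @param expression,clinical,signature,annotation as in [run_analysis()].
#' @param train_ids,test_ids disjoint character vectors of sample ids.
#' @param ... options forwarded to [run_analysis()] for the training run.
#' @return list with `train` (a `survsig_report`) and `test` (labels and
#'   statistics computed under the frozen training model).
#' @export
train_test_run <- function(expression, clinical, signature,
                           annotation = NULL, train_ids, test_ids, ...) {
  if (length(intersect(train_ids, test_ids)))
    fail("train and test sample sets overlap")
  if (length(test_ids) == 0L) fail("empty test set")
  if (length(train_ids) == 0L) fail("empty train set")
  missing_ids <- setdiff(c(train_ids, test_ids), sample_ids(expression))
  if (length(missing_ids))
    fail("sample id(s) absent from expression: ",
         paste(missing_ids, collapse = ", "))
  sub <- function(ids) {
    expression_matrix(expression$values[, ids, drop = FALSE],
                      expression$annotation)
  }
  clin_sub <- function(ids) {
    out <- clinical[match(ids, clinical$sample_id), , drop = FALSE]
    rownames(out) <- NULL
    class(out) <- class(clinical)
    out
  }
  p <- length(signature$ids)
  tr_clin <- clin_sub(train_ids)
  if (sum(tr_clin$event) < 5 * p)
    warning("training set has few events relative to signature size (",
            sum(tr_clin$event), " events, ", p,
            " genes); Cox fit may be unstable")
  train <- run_analysis(sub(train_ids), tr_clin, signature, annotation, ...)
  te_clin <- clin_sub(test_ids)
  te_joined <- join_samples(sub(test_ids), te_clin)
  te_expr <- preprocess(te_joined$expression, log2 = train$config$log2,
                        qnorm = train$config$qnorm)
  res <- resolve_signature(signature, te_expr, annotation)
  te_gx <- collapse_probes(te_expr, res, method = train$config$collapse)
  te_gx <- expression_matrix(
    te_gx$values[names(train$betas), , drop = FALSE], te_gx$annotation)
  te_pi <- compute_pi(te_gx, train$betas, source = train$pi$source)
  labels <- apply_split_points(te_pi, train$grouping$split_points)
  tm <- te_joined$clinical$time; ev <- te_joined$clinical$event
  lr <- if (length(unique(labels)) >= 2L)
    logrank_test(tm, ev, labels) else NULL
  conc <- tryCatch(concordance_index(te_pi$pi, tm, ev),
                   error = function(e) NULL)
  hr <- if (length(unique(labels)) == 2L)
    tryCatch(hazard_ratio(tm, ev, labels), error = function(e) NULL)
    else NULL
  list(train = train,
       test = list(pi = te_pi, labels = labels, logrank = lr,
                   concordance = conc, hazard_ratio = hr,
                   clinical = te_joined$clinical))
}

#' Stratified signature evaluation by a clinical covariate
#'
#' Runs the full pipeline (fit, PI, risk groups, statistics) independently
#' within each level of a clinical covariate. Strata below `min_n` samples
#' (or failing to fit) are skipped with a note.
#'
#' @param expression,clinical,signature,annotation as in [run_analysis()].
#' @param stratum_col name of the covariate column in `clinical`.
#' @param min_n minimum stratum size analyzed (default 10).
#' @param ... forwarded to [run_analysis()].
#' @return list with `strata` (named list of `survsig_report`), `skipped`
#'   (named character of skip reasons) and `summary` (per-stratum n,
#'   log-rank p, concordance).
#' @export
stratified_run <- function(expression, clinical, signature,
                           annotation = NULL, stratum_col, min_n = 10L,
                           ...) {
  if (!stratum_col %in% names(clinical))
    fail("clinical table lacks column '", stratum_col, "'")
  levels_ <- sort(unique(as.character(clinical[[stratum_col]])))
  strata <- list(); skipped <- character(0)
  for (lv in levels_) {
    ids <- clinical$sample_id[clinical[[stratum_col]] == lv]
    ids <- intersect(ids, sample_ids(expression))
    if (length(ids) < min_n) {
      skipped[lv] <- sprintf("n = %d below minimum %d", length(ids), min_n)
      next
    }
    sub_expr <- expression_matrix(expression$values[, ids, drop = FALSE],
                                  expression$annotation)
    sub_clin <- clinical[match(ids, clinical$sample_id), , drop = FALSE]
    rownames(sub_clin) <- NULL
    class(sub_clin) <- class(clinical)
    rep_ <- tryCatch(
      suppressWarnings(run_analysis(sub_expr, sub_clin, signature,
                                    annotation, ...)),
      error = function(e) conditionMessage(e))
    if (is.character(rep_)) skipped[lv] <- rep_ else strata[[lv]] <- rep_
  }
  if (length(strata) == 0L)
    fail("no stratum met the minimum size / fit requirements")
  summary <- do.call(rbind, lapply(names(strata), function(lv)
    data.frame(stratum = lv, n = nrow(strata[[lv]]$clinical),
               logrank_p = strata[[lv]]$grouping$separation$p_value,
               concordance = strata[[lv]]$concordance$c_index,
               stringsAsFactors = FALSE)))
  list(strata = strata, skipped = skipped, summary = summary)
}

#' Export a report to a directory of figures, tables and a JSON summary
#'
#' Writes a fixed layout: `coefficients.tsv`, `prognostic_index.tsv`,
#' `km_curves.tsv`, `gene_tests.tsv`, `heatmap_matrix.tsv`, optional
#' `tdroc.tsv` and `scan.tsv`, figures (`km.pdf`, `heatmap.pdf`,
#' `boxplots.pdf`, optional `scan.pdf`), a machine-readable `summary.json`
#' of all statistics and a `manifest.json` listing files, options and any
#' omitted panels. Output is deterministic given identical inputs.
#'
#' @param report a [run_analysis()] result.
#' @param outdir output directory (created; must be writable).
#' @param figures draw PDF figures (default TRUE).
#' @return invisibly, the manifest list.
#' @export
export_report <- function(report, outdir, figures = TRUE) {
  if (is.null(report) || !inherits(report, "survsig_report"))
    fail("'report' must be a survsig_report")
  ok <- dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) fail("cannot create output directory: ", outdir)
  tm <- report$clinical$time; ev <- report$clinical$event
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(outdir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, name)
  }
  if (!is.null(report$fit)) wr(cox_table(report$fit), "coefficients.tsv")
  else wr(data.frame(gene = names(report$betas),
                     beta = unname(report$betas)), "coefficients.tsv")
  wr(data.frame(sample_id = report$pi$sample_ids,
                pi = unname(report$pi$pi),
                risk_group = report$grouping$labels,
                time = tm, event = ev), "prognostic_index.tsv")
  wr(report$km_data, "km_curves.tsv")
  wr(report$gene_tests$table, "gene_tests.tsv")
  hm <- render_heatmap(report$expression, report$grouping$labels, report$pi,
                       file = if (figures) file.path(outdir, "heatmap.pdf"))
  wr(data.frame(gene = rownames(hm$matrix), hm$matrix, check.names = FALSE),
     "heatmap_matrix.tsv")
  if (figures) files <- c(files, "heatmap.pdf")
  if (!is.null(report$tdroc))
    wr(data.frame(threshold = report$tdroc$thresholds,
                  sensitivity = report$tdroc$tp,
                  fpr = report$tdroc$fp), "tdroc.tsv")
  if (!is.null(report$grouping$scan)) {
    wr(data.frame(position = report$grouping$scan$positions,
                  chisq = report$grouping$scan$statistic,
                  p_value = report$grouping$scan$p_value), "scan.tsv")
    if (figures) {
      render_scan(report$grouping, file.path(outdir, "scan.pdf"))
      files <- c(files, "scan.pdf")
    }
  }
  if (figures) {
    render_km(tm, ev, report$grouping$labels,
              file = file.path(outdir, "km.pdf"),
              concordance = report$concordance)
    render_boxplots(report$expression, report$grouping$labels,
                    file = file.path(outdir, "boxplots.pdf"))
    files <- c(files, "km.pdf", "boxplots.pdf")
  }
  summary <- list(
    n_samples = nrow(report$clinical),
    n_genes = length(report$betas),
    n_events = sum(ev),
    groups = list(k = report$grouping$k,
                  method = report$grouping$method,
                  sizes = as.integer(tabulate(report$grouping$labels,
                                              report$grouping$k)),
                  split_points = unname(report$grouping$split_points)),
    logrank = list(statistic = report$grouping$separation$statistic,
                   df = report$grouping$separation$df,
                   p_value = report$grouping$separation$p_value),
    hazard_ratio = if (!is.null(report$hazard_ratio))
      list(hr = report$hazard_ratio$hr,
           ci95 = report$hazard_ratio$ci95,
           p = report$hazard_ratio$p),
    concordance = report$concordance$c_index,
    concordance_by_group = lapply(report$concordance_by_group, function(x)
      if (is.null(x)) NULL else x$c_index),
    tdroc_auc = if (!is.null(report$tdroc)) report$tdroc$auc,
    n_differential_genes = report$gene_tests$n_differential,
    betas = as.list(report$betas))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  files <- c(files, "summary.json")
  manifest <- list(files = sort(files), config = report$config,
                   omitted = c(if (is.null(report$tdroc)) "tdroc",
                               if (is.null(report$grouping$scan)) "scan"),
                   dropped_genes = report$dropped_genes,
                   unmatched_genes = report$resolution$unmatched)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}
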
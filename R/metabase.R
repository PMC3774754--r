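#' Merge expression cohorts into a meta-base
#'
#' Implements the cross-cohort merging recipe: each cohort is quantile
#' normalized; then, probeset by probeset, every cohort's values are shifted
#' so cohort means meet a common target (the unweighted grand mean of the
#' cohort means) while each cohort's standard deviation is untouched;
#' finally only probesets present in every cohort are kept and columns are
#' concatenated with cohort labels.
#'
#' @param cohorts list of >= 2 [expression_matrix()] objects, each with
#'   >= 2 samples; names (or `cohort_ids`) label the cohorts.
#' @param cohort_ids optional character labels, default `names(cohorts)` or
#'   `cohort1..k`.
#' @param qnorm quantile normalize each cohort first (default TRUE).
#' @return object of class `meta_base`: `expression` (merged
#'   [expression_matrix()]), `cohort` (label per sample), `audit`
#'   (per cohort x probeset pre/post means and SDs), `target`
#'   (per-probeset common mean).
#' @export
merge_cohorts <- function(cohorts, cohort_ids = NULL, qnorm = TRUE) {
  if (!is.list(cohorts) || length(cohorts) < 2L)
    fail("need at least 2 cohorts")
  cohort_ids <- cohort_ids %||% names(cohorts) %||%
    paste0("cohort", seq_along(cohorts))
  if (length(cohort_ids) != length(cohorts) || anyDuplicated(cohort_ids))
    fail("cohort ids must be unique, one per cohort")
  ns <- vapply(cohorts, function(co) ncol(co$values), 0L)
  if (any(ns < 2L))
    fail("cohort(s) with < 2 samples (SD undefined): ",
         paste(cohort_ids[ns < 2L], collapse = ", "))
  shared <- Reduce(intersect, lapply(cohorts, probe_ids))
  if (length(shared) == 0L) fail("no probesets shared by all cohorts")

  mats <- lapply(cohorts, function(co) {
    m <- co$values[shared, , drop = FALSE]
    if (qnorm) quantile_normalize(m) else m
  })
  pre_means <- vapply(mats, rowMeans, numeric(length(shared)))
  pre_sds <- vapply(mats, function(m) apply(m, 1, sd),
                    numeric(length(shared)))
  if (length(shared) == 1L) {
    pre_means <- matrix(pre_means, nrow = 1L)
    pre_sds <- matrix(pre_sds, nrow = 1L)
  }
  target <- rowMeans(pre_means)
  adjusted <- lapply(seq_along(mats), function(i)
    mats[[i]] - pre_means[, i] + target)
  merged <- do.call(cbind, adjusted)
  cohort <- rep(cohort_ids, ns)
  if (anyDuplicated(colnames(merged)))
    colnames(merged) <- paste(cohort, colnames(merged), sep = ".")
  audit <- do.call(rbind, lapply(seq_along(mats), function(i)
    data.frame(cohort = cohort_ids[i], probe_id = shared,
               pre_mean = pre_means[, i], pre_sd = pre_sds[, i],
               post_mean = rowMeans(adjusted[[i]]),
               post_sd = apply(adjusted[[i]], 1, sd),
               target = target, stringsAsFactors = FALSE)))
  rownames(audit) <- NULL
  structure(list(expression = expression_matrix(merged),
                 cohort = setNames(cohort, colnames(merged)),
                 audit = audit, target = setNames(target, shared)),
            class = "meta_base")
}

#' @export
print.meta_base <- function(x, ...) {
  cat(sprintf("Meta-base: %d shared probesets, %d samples, %d cohorts\n",
              nrow(x$expression$values), ncol(x$expression$values),
              length(unique(x$cohort))))
  invisible(x)
}

#' Write a meta-base to delimited files
#' @param mb a [merge_cohorts()] result.
#' @param outdir output directory (created if needed); writes
#'   `metabase_expression.tsv`, `metabase_cohorts.tsv`,
#'   `metabase_audit.tsv`.
#' @return invisibly, the file paths.
#' @export
write_metabase <- function(mb, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fe <- file.path(outdir, "metabase_expression.tsv")
  fc <- file.path(outdir, "metabase_cohorts.tsv")
  fa <- file.path(outdir, "metabase_audit.tsv")
  write_tsv_matrix(mb$expression$values, fe, id_col = "probe_id")
  write.table(data.frame(sample_id = names(mb$cohort), cohort = mb$cohort),
              fc, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(mb$audit, fa, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fe, fc, fa))
}
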
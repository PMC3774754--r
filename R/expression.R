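#' Expression matrix container
#'
#' A light container for a probes/genes-by-samples numeric matrix with an
#' optional probe-level annotation table. Row names are probe (or gene) ids,
#' column names are sample ids; both must be unique.
#'
#' @param values numeric matrix, rows = probes/genes, columns = samples, with
#'   unique row and column names.
#' @param annotation optional `data.frame` with columns `probe_id` and any of
#'   `symbol`, `entrez`; one row per probe. When absent, row ids are taken to
#'   be gene identifiers themselves (gene-level data).
#' @return an object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, annotation = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    fail("'values' must be a numeric matrix")
  pid <- rownames(values); sid <- colnames(values)
  if (is.null(pid) || is.null(sid))
    fail("'values' must have row names (probes) and column names (samples)")
  if (anyDuplicated(pid))
    fail("duplicated probe ids: ",
         paste(unique(pid[duplicated(pid)]), collapse = ", "))
  if (anyDuplicated(sid))
    fail("duplicated sample ids: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (!is.null(annotation)) {
    if (!is.data.frame(annotation) || !"probe_id" %in% names(annotation))
      fail("'annotation' must be a data.frame with a 'probe_id' column")
    annotation <- annotation[match(pid, annotation$probe_id), , drop = FALSE]
    rownames(annotation) <- NULL
  }
  structure(list(values = values, annotation = annotation),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  if (!is.null(x$annotation)) cat("  with probe annotation\n")
  nmiss <- sum(is.na(x$values))
  if (nmiss) cat(sprintf("  missing values: %d\n", nmiss))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x an `ExpressionMatrix`.
#' @export
probe_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

infer_sep <- function(path, dialect) {
  if (dialect == "tsv") return("\t")
  if (dialect == "csv") return(",")
  if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
}

open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

#' Read a delimited expression matrix
#'
#' Expects a header row of sample ids and a first column of probe/gene ids;
#' all remaining cells numeric. Non-numeric cells become missing values (a
#' message reports the count); duplicated probe ids and ragged rows are
#' errors.
#'
#' @param path file path (plain or gzipped TSV/CSV).
#' @param dialect `"auto"` (by extension), `"tsv"` or `"csv"`.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) fail("file not found: ", path)
  sep <- infer_sep(path, dialect)
  nf <- count.fields(path, sep = sep, quote = "\"", comment.char = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    fail("ragged row in ", path, ": line ", bad, " has ", nf[bad],
         " fields, expected ", nf[1])
  }
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2L) fail("expression file needs id column plus >= 1 sample")
  pid <- df[[1]]
  if (anyDuplicated(pid))
    fail("duplicated probe ids in ", path, ": ",
         paste(unique(pid[duplicated(pid)]), collapse = ", "))
  vals <- suppressWarnings(
    vapply(df[-1], function(col) as.numeric(col), numeric(nrow(df))))
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L,
                                     dimnames = list(NULL, names(df)[-1]))
  rownames(vals) <- pid
  n_miss <- sum(is.na(vals))
  if (n_miss > 0)
    message(n_miss, " non-numeric/missing expression cell(s) recorded as NA")
  expression_matrix(vals)
}

#' Read a clinical outcome table
#'
#' @param path delimited file; first column sample ids unless `sample_col`
#'   names another column.
#' @param time_col,event_col names of the follow-up time and event-indicator
#'   columns.
#' @param sample_col optional name of the sample-id column (default: first).
#' @param event_map optional named vector mapping textual event codes to 0/1,
#'   e.g. `c(DECEASED = 1, LIVING = 0)`.
#' @param dialect `"auto"`, `"tsv"` or `"csv"`.
#' @return a `data.frame` of class `ClinicalTable` with standardized columns
#'   `sample_id`, `time`, `event`, plus any covariate columns untouched.
#' @export
read_clinical <- function(path, time_col = "time", event_col = "event",
                          sample_col = NULL, event_map = NULL,
                          dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) fail("file not found: ", path)
  sep <- infer_sep(path, dialect)
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  sample_col <- sample_col %||% names(df)[1]
  for (col in c(sample_col, time_col, event_col))
    if (!col %in% names(df)) fail("clinical table lacks column '", col, "'")
  clinical_table(sample_id = as.character(df[[sample_col]]),
                 time = df[[time_col]], event = df[[event_col]],
                 covariates = df[setdiff(names(df),
                                         c(sample_col, time_col, event_col))],
                 event_map = event_map)
}

#' Construct a clinical table
#'
#' @param sample_id character vector of unique sample ids.
#' @param time positive follow-up times.
#' @param event event indicators (0 = censored, 1 = event), or codes covered
#'   by `event_map`.
#' @param covariates optional data.frame of extra clinical columns.
#' @param event_map optional named vector mapping codes to 0/1.
#' @param time_unit free-text unit recorded as an attribute (days/months/...).
#' @export
clinical_table <- function(sample_id, time, event, covariates = NULL,
                           event_map = NULL, time_unit = "unknown") {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    fail("duplicated sample ids: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  time_num <- suppressWarnings(as.numeric(time))
  bad <- is.na(time_num) | time_num <= 0
  if (any(bad))
    fail("non-positive or non-numeric time for sample(s): ",
         paste(sample_id[bad], collapse = ", "))
  if (!is.null(event_map)) {
    mapped <- unname(event_map[as.character(event)])
    if (anyNA(mapped))
      fail("event codes outside the coercion map: ",
           paste(unique(event[is.na(mapped)]), collapse = ", "))
    event <- mapped
  }
  ev <- suppressWarnings(as.numeric(event))
  if (anyNA(ev) || !all(ev %in% c(0, 1)))
    fail("event indicator must be 0/1 after coercion; offending sample(s): ",
         paste(sample_id[is.na(ev) | !(ev %in% c(0, 1))], collapse = ", "))
  out <- data.frame(sample_id = sample_id, time = time_num, event = ev,
                    stringsAsFactors = FALSE)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0)
    out <- cbind(out, as.data.frame(covariates, stringsAsFactors = FALSE))
  attr(out, "time_unit") <- time_unit
  class(out) <- c("ClinicalTable", "data.frame")
  out
}

#' Join expression and clinical tables on shared samples
#'
#' Restricts both inputs to the intersection of their sample ids (expression
#' column order) and reports dropped samples.
#'
#' @param expr an [expression_matrix()].
#' @param clinical a [clinical_table()].
#' @return list with elements `expression`, `clinical` and `dropped`
#'   (list of ids dropped from each side).
#' @export
join_samples <- function(expr, clinical) {
  shared <- intersect(sample_ids(expr), clinical$sample_id)
  if (length(shared) == 0L) fail("no shared samples between expression and clinical")
  drop_expr <- setdiff(sample_ids(expr), shared)
  drop_clin <- setdiff(clinical$sample_id, shared)
  if (length(drop_expr) || length(drop_clin))
    message("sample join dropped ", length(drop_expr), " expression / ",
            length(drop_clin), " clinical sample(s)")
  e <- expression_matrix(expr$values[, shared, drop = FALSE], expr$annotation)
  cl <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  rownames(cl) <- NULL
  list(expression = e, clinical = cl,
       dropped = list(expression = drop_expr, clinical = drop_clin))
}

#' Quantile-normalize a matrix across columns
#'
#' Thin wrapper over `limma::normalizeQuantiles` with the tie dialect in
#' which tied values within a column receive the mean of the reference
#' quantiles they span.
#'
#' @param mat numeric matrix (rows = features, columns = samples).
#' @return matrix of the same shape.
#' @export
quantile_normalize <- function(mat) {
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Preprocess an expression matrix
#'
#' Applies, in order: log2 transform (`auto` applies it only when the matrix
#' maximum exceeds `log2_threshold`, the signature of linear-scale
#' intensities or counts), quantile normalization across samples, and
#' missing-value resolution. `auto` is idempotent on already-transformed
#' data.
#'
#' @param expr an [expression_matrix()].
#' @param log2 `"auto"`, `"on"` or `"off"`.
#' @param qnorm `"off"` or `"on"`.
#' @param pseudocount value added before log2 (default 1).
#' @param log2_threshold matrix maximum above which `auto` treats data as
#'   linear scale (default 50).
#' @param missing `"row_mean"` imputes by the probe's across-sample mean;
#'   `"drop_sample"` removes samples carrying any missing value.
#' @return a preprocessed [expression_matrix()] with all values finite.
#' @export
preprocess <- function(expr, log2 = c("auto", "on", "off"),
                       qnorm = c("off", "on"), pseudocount = 1,
                       log2_threshold = 50,
                       missing = c("row_mean", "drop_sample")) {
  log2 <- match.arg(log2); qnorm <- match.arg(qnorm)
  missing <- match.arg(missing)
  if (pseudocount < 0) fail("'pseudocount' must be >= 0")
  v <- expr$values
  apply_log <- switch(log2, on = TRUE, off = FALSE,
                      auto = max(v, na.rm = TRUE) > log2_threshold)
  if (apply_log) {
    if (min(v, na.rm = TRUE) + pseudocount <= 0)
      fail("negative values remain after pseudocount; cannot log2 transform")
    v <- log2(v + pseudocount)
  }
  if (qnorm == "on") v <- quantile_normalize(v)
  n_miss <- sum(is.na(v))
  if (n_miss > 0) {
    if (missing == "drop_sample") {
      keep <- colSums(is.na(v)) == 0
      if (!any(keep)) fail("every sample has missing values; cannot drop all")
      message("dropped ", sum(!keep), " sample(s) with missing values")
      v <- v[, keep, drop = FALSE]
    } else {
      rm_ <- rowMeans(v, na.rm = TRUE)
      if (anyNA(rm_)) {
        bad <- rownames(v)[is.na(rm_)]
        fail("probe(s) with all values missing: ", paste(bad, collapse = ", "))
      }
      idx <- which(is.na(v), arr.ind = TRUE)
      v[idx] <- rm_[idx[, 1]]
      message("imputed ", n_miss, " missing value(s) by row mean")
    }
  }
  expression_matrix(v, expr$annotation)
}
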
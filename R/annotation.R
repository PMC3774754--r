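#' Read an NCBI gene_info-format annotation file
#'
#' Parses the tab-delimited gene_info dialect (columns GeneID, Symbol,
#' Synonyms, dbXrefs among the standard 15+) into an identifier index. Each
#' official symbol, Entrez id, Ensembl/HGNC cross-reference and synonym is
#' mapped to a canonical gene record; synonym matches are flagged as
#' lower-confidence than official-symbol matches. Malformed lines are
#' skipped with a warning.
#'
#' @param path plain or gzipped gene_info file.
#' @return an object of class `GeneAnnotation`.
#' @export
read_gene_info <- function(path) {
  if (!file.exists(path)) fail("file not found: ", path)
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, 0L) >= 6L
  if (any(!ok))
    warning(sum(!ok), " malformed gene_info line(s) skipped")
  fields <- fields[ok]
  if (length(fields) == 0L) fail("empty annotation index from ", path)
  entrez <- vapply(fields, `[[`, "", 2L)
  symbol <- vapply(fields, `[[`, "", 3L)
  synonyms <- vapply(fields, `[[`, "", 5L)
  dbxrefs <- vapply(fields, `[[`, "", 6L)
  records <- data.frame(entrez = entrez, symbol = symbol,
                        stringsAsFactors = FALSE)
  syn_list <- strsplit(synonyms, "|", fixed = TRUE)
  syn_list <- lapply(syn_list, function(s) setdiff(s, "-"))
  xr_list <- strsplit(dbxrefs, "|", fixed = TRUE)
  ens_list <- lapply(xr_list, function(x)
    sub("^Ensembl:", "", x[startsWith(x, "Ensembl:")]))
  # dbXrefs writes HGNC ids as "HGNC:HGNC:1234"; keep the bare number
  hgnc_list <- lapply(xr_list, function(x)
    gsub("^(HGNC:)+", "", x[startsWith(x, "HGNC:")]))

  build_map <- function(tokens_list) {
    n <- vapply(tokens_list, length, 0L)
    if (sum(n) == 0L) return(list())
    split(rep(seq_along(tokens_list), n),
          toupper(unlist(tokens_list)))
  }
  idx <- list(
    entrez  = build_map(as.list(entrez)),
    symbol  = build_map(as.list(symbol)),
    ensembl = build_map(ens_list),
    hgnc    = build_map(hgnc_list),
    synonym = build_map(syn_list)
  )
  structure(list(records = records, index = idx, synonyms = syn_list),
            class = "GeneAnnotation")
}

#' @export
print.GeneAnnotation <- function(x, ...) {
  cat(sprintf("GeneAnnotation: %d gene records\n", nrow(x$records)))
  invisible(x)
}

#' Look up one identifier in a gene annotation index
#'
#' Resolution precedence: exact Entrez id, then official symbol, then
#' Ensembl/HGNC cross-reference, then synonym. Within a tier an ambiguous
#' token (matching several genes) resolves to the lowest Entrez id with an
#' ambiguity note.
#'
#' @param ann a `GeneAnnotation`.
#' @param id identifier string.
#' @return `NULL` when unmatched, else list with `entrez`, `symbol`,
#'   `match_type` and `note` (NA or ambiguity description).
#' @export
gene_lookup <- function(ann, id) {
  key <- toupper(trimws(id))
  tiers <- c("entrez", "symbol", "ensembl", "hgnc", "synonym")
  # bare HGNC numeric ids are written HGNC:1234 in dbXrefs
  keys <- c(entrez = key, symbol = key, ensembl = key,
            hgnc = gsub("^(HGNC:)+", "", key),
            synonym = key)
  for (tier in tiers) {
    hit <- ann$index[[tier]][[keys[[tier]]]]
    if (!is.null(hit)) {
      hit <- sort(unique(hit))
      note <- NA_character_
      if (length(hit) > 1L)
        note <- paste0("ambiguous ", tier, " match: ",
                       paste(ann$records$symbol[hit], collapse = "/"),
                       "; kept lowest Entrez id")
      pick <- hit[order(as.numeric(ann$records$entrez[hit]))][1]
      if (tier == "synonym" && is.na(note))
        note <- paste0("synonym of ", ann$records$symbol[pick])
      return(list(entrez = ann$records$entrez[pick],
                  symbol = ann$records$symbol[pick],
                  match_type = tier, note = note))
    }
  }
  NULL
}

#' Gene signature constructor
#'
#' @param ids character identifiers (symbol, Entrez, Ensembl, HGNC, ...).
#' @param weights optional numeric risk weights; either absent or one per
#'   identifier (partial weighting is an error).
#' @param id_space declared identifier space, `"auto"` by default.
#' @return an object of class `GeneSignature`.
#' @export
gene_signature <- function(ids, weights = NULL,
                           id_space = c("auto", "symbol", "entrez",
                                        "ensembl", "hgnc")) {
  id_space <- match.arg(id_space)
  ids <- trimws(as.character(ids))
  if (length(ids) == 0L || any(!nzchar(ids)))
    fail("signature identifiers must be non-empty")
  if (anyDuplicated(ids))
    fail("duplicated signature identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (!is.null(weights)) {
    if (length(weights) != length(ids) || anyNA(weights))
      fail("weights must be given for all entries or none")
    weights <- as.numeric(weights)
    names(weights) <- ids
  }
  structure(list(ids = ids, weights = weights, id_space = id_space),
            class = "GeneSignature")
}

#' Read a gene signature file (one id per line, optional weight column)
#' @param path text file; whitespace- or tab-separated second column taken
#'   as per-gene weight when present on every line.
#' @return a [gene_signature()].
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) fail("file not found: ", path)
  con <- open_text(path)
  on.exit(close(con))
  lines <- trimws(readLines(con, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) fail("empty signature file: ", path)
  parts <- strsplit(lines, "[\t ,]+")
  ids <- vapply(parts, `[[`, "", 1L)
  has_w <- vapply(parts, length, 0L) >= 2L
  if (all(has_w)) {
    w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
    if (anyNA(w)) fail("non-numeric weight in signature file")
    gene_signature(ids, w)
  } else if (any(has_w)) {
    fail("weights must be given for all entries or none")
  } else {
    gene_signature(ids)
  }
}

#' Restrict a signature to an active subset of genes
#'
#' Mirrors interactive gene toggling: any previously fitted model is stale
#' after toggling and must be refit.
#'
#' @param sig a [gene_signature()].
#' @param active character subset of the signature's identifiers.
#' @return the restricted [gene_signature()] (original entry order kept).
#' @export
toggle_genes <- function(sig, active) {
  if (length(active) == 0L) fail("active gene set must be non-empty")
  extra <- setdiff(active, sig$ids)
  if (length(extra))
    fail("not in signature: ", paste(extra, collapse = ", "))
  keep <- sig$ids %in% active
  gene_signature(sig$ids[keep],
                 if (!is.null(sig$weights)) sig$weights[keep],
                 sig$id_space)
}

#' Resolve signature identifiers to expression rows
#'
#' Each identifier is mapped (optionally through a `GeneAnnotation` index)
#' to the probe rows present in the expression matrix. Probe rows match a
#' gene through the expression annotation's `symbol`/`entrez` columns, or by
#' the probe id itself for gene-level matrices. Every input identifier lands
#' in exactly one of `matched`/`unmatched`.
#'
#' @param sig a [gene_signature()].
#' @param expr an [expression_matrix()].
#' @param ann optional [read_gene_info()] index for identifier conversion.
#' @return object of class `GeneResolution`: `matched` (named list,
#'   identifier -> probe ids), `unmatched`, `notes` (identifier -> note),
#'   and the signature.
#' @export
resolve_signature <- function(sig, expr, ann = NULL) {
  pid <- probe_ids(expr)
  asym <- aent <- NULL
  if (!is.null(expr$annotation)) {
    if ("symbol" %in% names(expr$annotation)) asym <- toupper(expr$annotation$symbol)
    if ("entrez" %in% names(expr$annotation)) aent <- as.character(expr$annotation$entrez)
  }
  pid_up <- toupper(pid)
  matched <- list(); unmatched <- character(); notes <- character()
  for (id in sig$ids) {
    rec <- if (!is.null(ann)) gene_lookup(ann, id) else NULL
    cand <- toupper(unique(c(id, rec$symbol, rec$entrez)))
    hits <- pid[pid_up %in% cand]
    if (!is.null(asym)) hits <- union(hits, pid[asym %in% cand])
    if (!is.null(aent)) hits <- union(hits, pid[aent %in% cand])
    if (length(hits)) {
      matched[[id]] <- sort(hits)
      if (!is.null(rec) && !is.na(rec$note)) notes[id] <- rec$note
    } else {
      unmatched <- c(unmatched, id)
    }
  }
  if (length(matched) == 0L) fail("empty signature after resolution")
  structure(list(matched = matched, unmatched = unmatched, notes = notes,
                 signature = sig),
            class = "GeneResolution")
}

#' @export
print.GeneResolution <- function(x, ...) {
  cat(sprintf("GeneResolution: %d matched, %d unmatched\n",
              length(x$matched), length(x$unmatched)))
  if (length(x$unmatched))
    cat("  unmatched:", paste(x$unmatched, collapse = ", "), "\n")
  invisible(x)
}

#' Collapse multi-probe genes to one row per gene
#'
#' @param expr an [expression_matrix()].
#' @param resolution a [resolve_signature()] result.
#' @param method `"max_row_average"` keeps, verbatim, the probe with the
#'   largest across-sample mean (ties: lexicographically smallest probe id);
#'   `"mean"` averages the gene's probes element-wise; `"max_variance"`
#'   keeps the probe with the largest across-sample variance.
#' @return an [expression_matrix()] with one row per resolved gene, row ids
#'   the signature identifiers, annotated with the probe(s) used.
#' @export
collapse_probes <- function(expr, resolution,
                            method = c("max_row_average", "mean",
                                       "max_variance")) {
  method <- match.arg(method)
  if (length(resolution$matched) == 0L) fail("empty resolution")
  genes <- names(resolution$matched)
  out <- matrix(NA_real_, length(genes), ncol(expr$values),
                dimnames = list(genes, sample_ids(expr)))
  used <- character(length(genes))
  for (i in seq_along(genes)) {
    probes <- sort(resolution$matched[[genes[i]]])
    sub <- expr$values[probes, , drop = FALSE]
    if (length(probes) == 1L) {
      out[i, ] <- sub[1, ]; used[i] <- probes
    } else if (method == "mean") {
      out[i, ] <- colMeans(sub); used[i] <- paste(probes, collapse = "|")
    } else {
      stat <- if (method == "max_row_average") rowMeans(sub)
              else apply(sub, 1, var)
      pick <- probes[which.max(stat)]  # which.max -> first max = lowest-sorting id
      out[i, ] <- expr$values[pick, ]; used[i] <- pick
    }
  }
  expression_matrix(out, data.frame(probe_id = genes, source_probe = used,
                                    symbol = genes,
                                    stringsAsFactors = FALSE))
}
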
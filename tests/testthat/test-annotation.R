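gene_info_fixture <- function() {
  hdr <- paste("#tax_id", "GeneID", "Symbol", "LocusTag", "Synonyms",
               "dbXrefs", "chromosome", "map_location", "description",
               sep = "\t")
  row <- function(id, sym, syn, xr)
    paste("9606", id, sym, "-", syn, xr, "1", "-", "desc", sep = "\t")
  tmp_tsv(c(
    hdr,
    row("2099", "ESR1", "ER|ESR|Era",
        "MIM:133430|HGNC:HGNC:3467|Ensembl:ENSG00000091831"),
    row("2064", "ERBB2", "HER2|NEU|HER-2",
        "HGNC:HGNC:3430|Ensembl:ENSG00000141736"),
    row("5241", "PGR", "PR|NR3C3",
        "HGNC:HGNC:8910|Ensembl:ENSG00000082175"),
    # deliberate synonym collision: "ER" also a synonym of this fake gene
    row("99999", "FAKE1", "ER|XYZ", "-"),
    "malformed line without enough fields"))
}

test_that("gene_info parsing resolves symbols, synonyms and cross-refs", {
  expect_warning(ann <- read_gene_info(gene_info_fixture()), "malformed")
  # synonym resolves and is flagged as lower confidence
  hit <- gene_lookup(ann, "Era")
  expect_equal(hit$symbol, "ESR1")
  expect_equal(hit$match_type, "synonym")
  expect_match(hit$note, "synonym")
  # Entrez and symbol agree
  expect_equal(gene_lookup(ann, "2099")$symbol, "ESR1")
  expect_equal(gene_lookup(ann, "ESR1")$entrez, "2099")
  # Ensembl and HGNC cross-references
  expect_equal(gene_lookup(ann, "ENSG00000141736")$symbol, "ERBB2")
  expect_equal(gene_lookup(ann, "HGNC:8910")$symbol, "PGR")
  # unknown token
  expect_null(gene_lookup(ann, "NOTAGENE"))
})

test_that("official-symbol matches outrank synonyms; ambiguity is noted", {
  suppressWarnings(ann <- read_gene_info(gene_info_fixture()))
  # "PGR" is an official symbol: must not fall through to any synonym tier
  expect_equal(gene_lookup(ann, "PGR")$match_type, "symbol")
  # "ER" is a synonym of both ESR1 and FAKE1: deterministic pick + note
  hit <- gene_lookup(ann, "ER")
  expect_equal(hit$symbol, "ESR1")  # lowest Entrez id wins
  expect_match(hit$note, "ambiguous")
})

test_that("empty annotation index errors", {
  f <- tmp_tsv("#tax_id\tGeneID\tSymbol")
  expect_error(suppressWarnings(read_gene_info(f)), "empty")
})

test_that("signature resolution is total and prefers present probes", {
  suppressWarnings(ann <- read_gene_info(gene_info_fixture()))
  m <- matrix(rnorm(8), 4, 2,
              dimnames = list(c("201_at", "202_at", "203_at", "204_at"),
                              c("A", "B")))
  e <- expression_matrix(m, annotation = data.frame(
    probe_id = rownames(m),
    symbol = c("ESR1", "ESR1", "ERBB2", "OTHER"),
    stringsAsFactors = FALSE))
  sig <- gene_signature(c("ER", "HER2", "PGR"))
  res <- resolve_signature(sig, e, ann)
  # totality: every identifier in exactly one of matched/unmatched
  expect_setequal(c(names(res$matched), res$unmatched), sig$ids)
  expect_equal(length(names(res$matched)) + length(res$unmatched),
               length(sig$ids))
  expect_equal(res$matched$ER, c("201_at", "202_at"))
  expect_equal(res$matched$HER2, "203_at")
  expect_equal(res$unmatched, "PGR")
  # nothing matched at all -> error
  expect_error(resolve_signature(gene_signature("NOTAGENE"), e, ann),
               "empty signature")
})

test_that("the bundled 16-gene panel fully resolves on a platform carrying
           every gene", {
  sig <- read_signature(system.file("extdata", "oncotypedx_genes.txt",
                                    package = "survsig"))
  expect_length(sig$ids, 16)
  set.seed(8)
  m <- matrix(rnorm(16 * 4, 8), 16, 4,
              dimnames = list(sig$ids, paste0("s", 1:4)))
  res <- resolve_signature(sig, expression_matrix(m))
  expect_length(res$matched, 16)
  expect_length(res$unmatched, 0)
})

test_that("signatures without annotation match gene-level row ids", {
  m <- matrix(rnorm(4), 2, 2,
              dimnames = list(c("ESR1", "ERBB2"), c("A", "B")))
  res <- resolve_signature(gene_signature(c("ESR1", "MISSING")),
                           expression_matrix(m))
  expect_equal(res$matched$ESR1, "ESR1")
  expect_equal(res$unmatched, "MISSING")
})

test_that("collapse_probes implements all three rules with documented ties", {
  m <- rbind(p1 = c(5, 5, 5), p2 = c(7, 7, 7), p3 = c(1, 9, 2))
  colnames(m) <- c("A", "B", "C")
  e <- expression_matrix(m)
  res <- structure(list(matched = list(G = c("p1", "p2", "p3"))),
                   class = "GeneResolution")
  # max_row_average keeps the mean-7 probe row verbatim
  out <- collapse_probes(e, res, "max_row_average")
  expect_equal(unname(out$values["G", ]), c(7, 7, 7))
  expect_equal(out$annotation$source_probe, "p2")
  # mean is the element-wise probe mean
  out2 <- collapse_probes(e, res, "mean")
  expect_equal(unname(out2$values["G", ]), unname(colMeans(m)))
  # max_variance keeps the most variable probe
  out3 <- collapse_probes(e, res, "max_variance")
  expect_equal(unname(out3$values["G", ]), c(1, 9, 2))
  # single-probe gene passes through unchanged under every method
  res1 <- structure(list(matched = list(G = "p3")), class = "GeneResolution")
  for (meth in c("max_row_average", "mean", "max_variance"))
    expect_equal(unname(collapse_probes(e, res1, meth)$values["G", ]),
                 c(1, 9, 2))
  # equal row means: lexicographically smallest probe id kept
  m2 <- rbind(pB = c(3, 5), pA = c(4, 4))
  colnames(m2) <- c("A", "B")
  resT <- structure(list(matched = list(G = c("pB", "pA"))),
                    class = "GeneResolution")
  outT <- collapse_probes(expression_matrix(m2), resT, "max_row_average")
  expect_equal(outT$annotation$source_probe, "pA")
  expect_error(collapse_probes(e, res, "bogus"))
})

test_that("max_row_average output equals one original probe row verbatim", {
  set.seed(3)
  m <- matrix(rnorm(30, 8), 6, 5,
              dimnames = list(paste0("p", 1:6), paste0("s", 1:5)))
  e <- expression_matrix(m)
  res <- structure(list(matched = list(G1 = c("p1", "p2", "p3"),
                                       G2 = c("p4", "p6"))),
                   class = "GeneResolution")
  out <- collapse_probes(e, res, "max_row_average")
  for (g in rownames(out$values)) {
    src <- out$annotation$source_probe[out$annotation$probe_id == g]
    expect_identical(unname(out$values[g, ]), unname(m[src, ]))
  }
})

test_that("toggle_genes restricts the signature and validates the subset", {
  sig <- gene_signature(letters[1:5], weights = 1:5 / 10)
  expect_identical(toggle_genes(sig, letters[1:5])$ids, sig$ids)
  s2 <- toggle_genes(sig, c("a", "c"))
  expect_equal(s2$ids, c("a", "c"))
  expect_equal(unname(s2$weights), c(0.1, 0.3))
  expect_error(toggle_genes(sig, character(0)), "non-empty")
  expect_error(toggle_genes(sig, "zz"), "not in signature")
})

test_that("signature weights are all-or-none and files round-trip", {
  expect_error(gene_signature(c("a", "b"), weights = 1), "all entries")
  f <- tmp_tsv(c("ESR1\t0.5", "ERBB2\t-0.2"))
  sig <- read_signature(f)
  expect_equal(unname(sig$weights), c(0.5, -0.2))
  g <- tmp_tsv(c("ESR1", "ERBB2\t0.3"))
  expect_error(read_signature(g), "all entries")
})
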
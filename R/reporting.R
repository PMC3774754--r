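#' Per-gene expression differences between risk groups
#'
#' Two groups: Welch t-test per gene; more than two: one-way F-test.
#' Degenerate genes whose values are identical across all samples score
#' statistic 0, p = 1. Benjamini-Hochberg adjusted p-values are reported
#' alongside; the headline differential count uses unadjusted p < `alpha`.
#'
#' @param expr gene-by-sample [expression_matrix()] (or matrix) restricted
#'   to the signature.
#' @param labels risk-group labels, >= 2 groups with >= 2 samples each.
#' @param alpha threshold for the differential-gene count (default 0.05).
#' @return list with `table` (gene, estimate, statistic, p, p_bh) and
#'   `n_differential`.
#' @export
gene_group_tests <- function(expr, labels, alpha = 0.05) {
  v <- if (inherits(expr, "ExpressionMatrix")) expr$values else expr
  f <- factor(labels)
  if (nlevels(f) < 2L) fail("need >= 2 groups")
  if (any(table(f) < 2L)) fail("every group needs >= 2 samples")
  k <- nlevels(f)
  res <- lapply(rownames(v), function(g) {
    y <- v[g, ]
    if (max(y) - min(y) < .Machine$double.eps * 100)
      return(c(0, 0, 1))
    if (k == 2L) {
      ok <- tryCatch({
        tt <- t.test(y ~ f)  # Welch
        c(diff(rev(tapply(y, f, mean))), tt$statistic, tt$p.value)
      }, error = function(e) c(0, 0, 1))
      ok
    } else {
      ok <- tryCatch({
        ft <- oneway.test(y ~ f, var.equal = TRUE)
        c(NA_real_, ft$statistic, ft$p.value)
      }, error = function(e) c(NA_real_, 0, 1))
      ok
    }
  })
  m <- do.call(rbind, res)
  tab <- data.frame(gene = rownames(v), estimate = m[, 1],
                    statistic = m[, 2], p = m[, 3],
                    p_bh = p.adjust(m[, 3], "BH"),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab, n_differential = sum(tab$p < alpha))
}

km_plot_data <- function(time, event, labels) {
  f <- factor(labels)
  do.call(rbind, lapply(levels(f), function(g) {
    km <- km_estimate(time[f == g], event[f == g])
    data.frame(group = g,
               time = c(0, km$time), survival = c(1, km$survival),
               n_risk = c(km$n, km$n_risk),
               n_event = c(0L, km$n_event),
               stringsAsFactors = FALSE)
  }))
}

#' Kaplan-Meier figure with at-risk table, plus its sidecar data
#'
#' Draws per-group step curves with censoring ticks, at-risk counts along
#' the time axis, and an annotation block (log-rank p, HR with CI for two
#' groups, concordance). Every plotted number is also returned (and
#' written) as a table, so the figure can be reproduced from the TSV alone.
#'
#' @param time,event survival data.
#' @param labels risk-group labels (group 1 = lowest risk).
#' @param file optional path; `.pdf` or `.png` figure written when given.
#' @param main plot title.
#' @param concordance optional [concordance_index()] result to annotate.
#' @return invisibly, the sidecar `data.frame` of curve coordinates.
#' @export
render_km <- function(time, event, labels, file = NULL, main = "Risk groups",
                      concordance = NULL) {
  f <- factor(labels)
  dat <- km_plot_data(time, event, labels)
  lr <- if (nlevels(f) >= 2L) logrank_test(time, event, labels) else NULL
  hr <- if (nlevels(f) == 2L && sum(event) > 0)
    tryCatch(hazard_ratio(time, event, labels), error = function(e) NULL)
    else NULL
  draw <- function() {
    cols <- colorRampPalette(c("forestgreen", "red3"))(nlevels(f))
    op <- par(mar = c(7, 4, 3, 1)); on.exit(par(op))
    plot(NA, xlim = c(0, max(time)), ylim = c(0, 1),
         xlab = "", ylab = "Survival probability", main = main)
    mtext("Time", side = 1, line = 2)
    for (i in seq_len(nlevels(f))) {
      g <- levels(f)[i]
      d <- dat[dat$group == g, ]
      lines(c(d$time, max(time)), c(d$survival, min(d$survival)),
            type = "s", col = cols[i], lwd = 2)
      cen <- time[f == g & event == 0]
      if (length(cen)) {
        km <- km_estimate(time[f == g], event[f == g])
        points(cen, km_survival_at(km, cen), pch = 3, col = cols[i])
      }
    }
    at <- pretty(c(0, max(time)))
    at <- at[at <= max(time)]
    for (i in seq_len(nlevels(f))) {
      g <- levels(f)[i]
      mtext(n_at_risk(time[f == g], event[f == g], at), side = 1,
            line = 3 + i, at = at, col = cols[i], cex = 0.8)
    }
    ann <- character(0)
    if (!is.null(lr))
      ann <- c(ann, sprintf("log-rank p = %.3g", lr$p_value))
    if (!is.null(hr))
      ann <- c(ann, sprintf("HR = %.2f (%.2f-%.2f)", hr$hr,
                            hr$ci95[1], hr$ci95[2]))
    if (!is.null(concordance))
      ann <- c(ann, sprintf("CI = %.1f", 100 * concordance$c_index))
    if (length(ann)) legend("topright", legend = ann, bty = "n")
    legend("bottomleft", legend = paste("group", levels(f)),
           col = cols, lwd = 2, bty = "n")
  }
  if (!is.null(file)) {
    open_device(file)
    draw()
    dev.off()
  }
  invisible(dat)
}

open_device <- function(file, width = 7, height = 6) {
  if (grepl("\\.png$", file)) png(file, width * 110, height * 110, res = 110)
  else pdf(file, width = width, height = height)
}

#' Expression heat map ordered by prognostic index within risk group
#'
#' Rows are genes, columns samples sorted by PI ascending within group; the
#' diverging scale is centered at each gene's median. The plotted (ordered,
#' median-centered) matrix is returned as sidecar data.
#'
#' @param expr gene-by-sample [expression_matrix()] or matrix.
#' @param labels risk-group labels.
#' @param pi a [compute_pi()] result aligned to the samples.
#' @param file optional `.pdf`/`.png` output path.
#' @return invisibly, list with `matrix` (ordered, centered) and `order`.
#' @export
render_heatmap <- function(expr, labels, pi, file = NULL) {
  v <- if (inherits(expr, "ExpressionMatrix")) expr$values else expr
  if (ncol(v) == 0L || nrow(v) == 0L) fail("empty expression matrix")
  ord <- order(labels, pi$pi, seq_along(pi$pi))
  m <- v[, ord, drop = FALSE]
  centered <- m - apply(m, 1, median)
  if (!is.null(file)) {
    open_device(file)
    lim <- max(abs(centered), 1e-9)
    cols <- colorRampPalette(c("green3", "black", "red2"))(64)
    image(t(centered[rev(seq_len(nrow(centered))), , drop = FALSE]),
          zlim = c(-lim, lim), col = cols, axes = FALSE,
          main = "Expression by risk group (PI-ordered)")
    box()
    dev.off()
  }
  invisible(list(matrix = centered, order = colnames(m)))
}

#' Per-gene box plots across risk groups (with group-difference tests)
#' @param expr gene-by-sample expression restricted to the signature.
#' @param labels risk-group labels.
#' @param file optional `.pdf`/`.png` output path.
#' @return invisibly, the [gene_group_tests()] result.
#' @export
render_boxplots <- function(expr, labels, file = NULL) {
  v <- if (inherits(expr, "ExpressionMatrix")) expr$values else expr
  tests <- gene_group_tests(v, labels)
  if (!is.null(file)) {
    open_device(file, width = 8, height = 2 + 2 * ceiling(nrow(v) / 4))
    op <- par(mfrow = c(ceiling(nrow(v) / 4), min(4, nrow(v))),
              mar = c(2, 3, 2.5, 0.5))
    for (g in rownames(v)) {
      p <- tests$table$p[tests$table$gene == g]
      boxplot(v[g, ] ~ factor(labels), col = c("forestgreen", "red3"),
              main = sprintf("%s (p = %.3g)", g, p), xlab = "", ylab = "")
    }
    par(op)
    dev.off()
  }
  invisible(tests)
}

#' Risk-optimization profile plot (scan p-values along the ordered PI)
#' @param grouping an [optimize_groups()] result carrying a scan profile.
#' @param file optional `.pdf`/`.png` output path.
#' @return invisibly, the scan `data.frame`.
#' @export
render_scan <- function(grouping, file = NULL) {
  if (is.null(grouping$scan)) fail("grouping carries no scan profile")
  dat <- data.frame(position = grouping$scan$positions,
                    chisq = grouping$scan$statistic,
                    p_value = grouping$scan$p_value)
  if (!is.null(file)) {
    open_device(file)
    plot(dat$position, -log10(dat$p_value), type = "l",
         xlab = "split position (PI order)", ylab = "-log10 p (log-rank)",
         main = "Risk-group split optimization")
    abline(v = dat$position[which.min(dat$p_value)], lty = 2, col = "red3")
    dev.off()
  }
  invisible(dat)
}
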
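#' Per-gene log fold change between two groups
#'
#' For log2-scale input the difference of group means is the log fold change.
#' Direction is group `a` minus group `b`.
#'
#' @inheritParams resolve_contrast
#' @return Named numeric vector, one value per gene.
#' @export
log_fold_change <- function(expr, groups, a, b) {
  cx <- resolve_contrast(expr, groups, a, b, min_per_group = 1L)
  rowMeans(expr[, cx$a_samples, drop = FALSE]) -
    rowMeans(expr[, cx$b_samples, drop = FALSE])
}

#' Per-gene two-sample t statistics
#'
#' Row-wise two-sample t between the two groups: pooled-variance Student's t
#' (default) or Welch. Two-sided p-values come from the t distribution with
#' the corresponding degrees of freedom. Genes where both group variances are
#' zero get t = 0, p = 1 when the means agree; if the means differ the input
#' is degenerate (noise-free) and an error advises adding noise.
#'
#' @inheritParams resolve_contrast
#' @param variant `"student"` (pooled variance) or `"welch"`.
#' @return Data frame with columns `tstat`, `pvalue`, rownames = gene ids.
#' @export
t_statistic <- function(expr, groups, a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  cx <- resolve_contrast(expr, groups, a, b, min_per_group = 2L)
  xa <- expr[, cx$a_samples, drop = FALSE]
  xb <- expr[, cx$b_samples, drop = FALSE]
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  diff <- ma - mb
  if (variant == "student") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep.int(na + nb - 2, length(se))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  degenerate <- se == 0
  if (any(degenerate & abs(diff) > 0)) {
    stop("gene(s) with zero within-group variance but differing means (",
         paste(utils::head(rownames(expr)[degenerate & abs(diff) > 0], 5),
               collapse = ", "),
         "); the fixture is noise-free -- add noise or drop these genes")
  }
  t <- ifelse(degenerate, 0, diff / se)
  p <- ifelse(degenerate, 1, 2 * stats::pt(-abs(t), df))
  data.frame(tstat = t, pvalue = p, row.names = rownames(expr))
}

#' Combined ranking metric: logFC weighted by significance
#'
#' `logfc * -log10(max(pvalue, p_floor))`. Adds statistical significance to
#' the directionality of the fold change; zero whenever p = 1.
#'
#' @param logfc Numeric vector of log fold changes.
#' @param pvalue Numeric vector of p-values in (0, 1].
#' @param p_floor Lower clamp applied before log10 (default 1e-300) so the
#'   metric stays finite at numerically zero p.
#' @return Numeric vector.
#' @export
combined_metric <- function(logfc, pvalue, p_floor = 1e-300) {
  stopifnot(length(logfc) == length(pvalue), p_floor > 0)
  if (any(pvalue <= 0 | pvalue > 1)) stop("pvalue must lie in (0, 1]")
  logfc * -log10(pmax(pvalue, p_floor))
}

#' Differential-expression table for a two-group contrast
#'
#' Computes, per gene, the log fold change (group `a` minus `b`), the
#' two-sample t statistic and p-value, and the combined metric
#' `logfc * -log10(p)`.
#'
#' @inheritParams t_statistic
#' @param p_floor Passed to [combined_metric()].
#' @return Data frame with columns `gene`, `logfc`, `tstat`, `pvalue`,
#'   `combined`.
#' @export
differential_table <- function(expr, groups, a, b,
                               variant = c("student", "welch"),
                               p_floor = 1e-300) {
  variant <- match.arg(variant)
  lfc <- log_fold_change(expr, groups, a, b)
  tt <- t_statistic(expr, groups, a, b, variant)
  data.frame(gene = rownames(expr),
             logfc = unname(lfc),
             tstat = tt$tstat,
             pvalue = tt$pvalue,
             combined = combined_metric(unname(lfc), tt$pvalue, p_floor),
             row.names = NULL)
}

#' Build the ranked gene list for preranked enrichment
#'
#' Sorts genes by the chosen metric, descending; ties are broken by gene id
#' (lexicographic, C locale) so the order is a reproducible total order.
#'
#' @param table A [differential_table()] data frame (columns `gene` plus the
#'   metric columns).
#' @param metric One of `"tstat"`, `"logfc"`, `"combined"`.
#' @return Named numeric vector sorted in non-increasing order, names = gene
#'   ids, with the metric recorded in attribute `"metric"`.
#' @export
rank_genes <- function(table, metric = c("tstat", "logfc", "combined")) {
  metric <- match.arg(metric)
  vals <- table[[metric]]
  if (anyNA(vals) || any(!is.finite(vals))) {
    bad <- table$gene[!is.finite(vals)]
    stop("non-finite ", metric, " for gene(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  ord <- order(-vals, rank_key(table$gene), method = "radix")
  structure(stats::setNames(vals[ord], table$gene[ord]), metric = metric)
}

# locale-independent sort key for gene-id tie-breaks
rank_key <- function(x) {
  factor(x, levels = sort(unique(x), method = "radix"))
}

#' Write a ranked list in the two-column .rnk dialect
#'
#' @param ranked Output of [rank_genes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rnk <- function(ranked, path) {
  write_result_tsv(data.frame(gene = names(ranked), metric = unname(ranked)),
                   path)
}
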
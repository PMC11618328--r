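#' Enrichment (running-sum) plot for one gene set
#'
#' Running-sum curve over the ranked list with tick marks at set-member
#' positions and the ES extremum highlighted.
#'
#' @param report A `dual_report`.
#' @param set Gene-set name (must be among the scored sets).
#' @return A ggplot object.
#' @export
plot_enrichment <- function(report, set) {
  rs <- report$pairwise$running_sums[[set]]
  if (is.null(rs)) stop("set '", set, "' was not scored")
  row <- report$pairwise$results[report$pairwise$results$set == set, ]
  le_genes <- strsplit(row$leading_edge, ";", fixed = TRUE)[[1]]
  hit_pos <- which(names(report$ranked) %in% le_genes)
  df <- data.frame(position = seq_along(rs), running_sum = rs)
  iext <- which.max(abs(rs))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$running_sum)) +
    ggplot2::geom_line(color = "darkgreen") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = iext, linetype = "dotted", color = "red") +
    ggplot2::geom_rug(data = data.frame(position = hit_pos),
                      ggplot2::aes(x = .data$position), inherit.aes = FALSE,
                      sides = "b", length = ggplot2::unit(0.04, "npc")) +
    ggplot2::labs(title = set,
                  subtitle = sprintf("ES = %.3f, NES = %.3f, padj = %.3g",
                                     row$es, row$nes, row$padj),
                  x = "rank position", y = "running enrichment score") +
    ggplot2::theme_minimal()
}

#' Per-group score density plot for one gene set
#'
#' @inheritParams plot_enrichment
#' @return A ggplot object.
#' @export
plot_score_density <- function(report, set) {
  wf <- report$strata[[set]]
  if (is.null(wf)) stop("set '", set, "' was not assessed")
  cut <- report$assessment$cutpoint[report$assessment$set == set]
  df <- data.frame(score = wf$centred + cut, group = wf$group)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.45) +
    ggplot2::geom_vline(xintercept = cut, linetype = "dashed") +
    ggplot2::labs(title = set, x = "single-sample score", y = "density") +
    ggplot2::theme_minimal()
}

#' ROC curve plot for one gene set
#'
#' @inheritParams plot_enrichment
#' @return A ggplot object.
#' @export
plot_roc <- function(report, set) {
  pts <- report$roc[[set]]
  if (is.null(pts)) stop("set '", set, "' was not assessed")
  auc <- report$assessment$auc[report$assessment$set == set]
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = set, subtitle = sprintf("AUC = %.3f", auc),
                  x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' Waterfall plot of cutpoint-centred scores for one gene set
#'
#' @inheritParams plot_enrichment
#' @return A ggplot object.
#' @export
plot_waterfall <- function(report, set) {
  wf <- report$strata[[set]]
  if (is.null(wf)) stop("set '", set, "' was not assessed")
  wf$sample <- factor(wf$sample, levels = wf$sample)
  ggplot2::ggplot(wf, ggplot2::aes(x = .data$sample, y = .data$centred,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(title = set, x = NULL, y = "score centred on cutpoint") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}
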
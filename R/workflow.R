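#' Run the full dual workflow from files to an output directory
#'
#' File-level front end: reads the expression matrix, phenotype table and GMT
#' collection, runs [build_dual_report()], and writes every result table
#' (differential.tsv, ranked.rnk, gsea_results.tsv, scores.tsv, report.tsv,
#' roc_points.csv, waterfall.csv, density.csv, run_log.txt; plots when
#' requested). Deterministic: equal inputs and config give byte-identical
#' tables.
#'
#' @param expr_path,pheno_path,gmt_path Input file paths.
#' @param outdir Output directory (created if needed).
#' @param group_a,group_b Contrast labels.
#' @param gene_column,sample_column,group_column Column names for the readers.
#' @param collapse_duplicates Collapse duplicate gene rows by highest mean.
#' @param emit_plots Render basic plots (density, ROC, waterfall, enrichment)
#'   per significant set (default FALSE).
#' @inheritParams build_dual_report
#' @return The `dual_report`, invisibly; side effect: files in `outdir`.
#' @export
run_dual_workflow <- function(expr_path, pheno_path, gmt_path, outdir,
                              group_a, group_b,
                              gene_column = NULL, sample_column = "sample",
                              group_column = "group",
                              collapse_duplicates = FALSE,
                              rank_metric = "tstat", t_variant = "student",
                              n_perm = 1000, min_size = 1, max_size = Inf,
                              weight_exponent = 1, seed = 127,
                              ss_method = "ssgsea", alpha = 0.25,
                              tau = 1, kernel = "gaussian", normalize = TRUE,
                              fdr_threshold = 0.05, auc_threshold = 0.8,
                              emit_plots = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  # marker removed only on success, so partial outputs are identifiable
  manifest <- file.path(outdir, "MANIFEST")
  writeLines("status: INCOMPLETE (run in progress or aborted)", manifest)

  expr <- read_expression(expr_path, gene_column = gene_column,
                          collapse_duplicates = collapse_duplicates)
  groups <- read_phenotype(pheno_path, sample_column, group_column)
  collection <- read_gmt(gmt_path)
  report <- build_dual_report(
    expr, groups, group_a, group_b, collection,
    rank_metric = rank_metric, t_variant = t_variant,
    n_perm = n_perm, min_size = min_size, max_size = max_size,
    weight_exponent = weight_exponent, seed = seed,
    ss_method = ss_method, alpha = alpha, tau = tau, kernel = kernel,
    normalize = normalize, fdr_threshold = fdr_threshold,
    auc_threshold = auc_threshold)
  write_dual_report(report, outdir, emit_plots = emit_plots)
  unlink(manifest)
  invisible(report)
}

#' Write all tables (and optional plots) of a dual report
#'
#' @param report A `dual_report` from [build_dual_report()].
#' @param outdir Output directory.
#' @param emit_plots Render basic plots for each significant set.
#' @return Named vector of written paths, invisibly.
#' @export
write_dual_report <- function(report, outdir, emit_plots = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)

  write_result_tsv(report$differential, p("differential.tsv"),
                   "gene<TAB>logfc<TAB>tstat<TAB>pvalue<TAB>combined")
  write_rnk(report$ranked, p("ranked.rnk"))
  write_result_tsv(report$pairwise$results, p("gsea_results.tsv"),
                   "set size es nes pvalue padj significant leading_edge(;-joined)")
  write_scores(report$scores, p("scores.tsv"))
  if (!is.null(report$assessment) && nrow(report$assessment)) {
    write_result_tsv(report$assessment, p("report.tsv"),
                     "per-set dual assessment: t/p/padj overlap_pct auc cutpoint strat counts+pcts verdict")
  }
  rs_long <- do.call(rbind, lapply(names(report$pairwise$running_sums),
    function(s) data.frame(set = s,
                           position = seq_along(report$pairwise$running_sums[[s]]),
                           value = report$pairwise$running_sums[[s]])))
  utils::write.csv(rs_long, p("running_sums.csv"), row.names = FALSE,
                   quote = FALSE)
  roc_long <- do.call(rbind, lapply(names(report$roc), function(s)
    data.frame(set = s, report$roc[[s]])))
  if (!is.null(roc_long))
    utils::write.csv(roc_long, p("roc_points.csv"), row.names = FALSE,
                     quote = FALSE)
  wf_long <- do.call(rbind, lapply(names(report$strata), function(s)
    data.frame(set = s, report$strata[[s]])))
  if (!is.null(wf_long))
    utils::write.csv(wf_long, p("waterfall.csv"), row.names = FALSE,
                     quote = FALSE)
  dens_long <- density_table(report)
  if (!is.null(dens_long))
    utils::write.csv(dens_long, p("density.csv"), row.names = FALSE,
                     quote = FALSE)

  log_lines <- c(
    paste0("contrast: ", report$contrast[["a"]], " vs ", report$contrast[["b"]]),
    paste0("rank_metric: ", report$rank_metric),
    vapply(names(report$params), function(k)
      paste0(k, ": ", paste(report$params[[k]], collapse = ",")), character(1)),
    paste0("package_version: ",
           as.character(utils::packageVersion("tandemgsea"))),
    paste0("sets_scored: ", nrow(report$pairwise$results)),
    paste0("sets_skipped: ", nrow(report$pairwise$skipped)),
    if (nrow(report$pairwise$skipped))
      paste0("skipped: ", report$pairwise$skipped$set, " (",
             report$pairwise$skipped$reason, ")"))
  writeLines(log_lines, p("run_log.txt"))

  if (emit_plots) {
    sig <- report$pairwise$results$set[report$pairwise$results$significant]
    for (s in intersect(sig, names(report$roc))) {
      safe <- gsub("[^A-Za-z0-9_.-]", "_", s)
      ggplot2::ggsave(p(paste0("enrichment_", safe, ".pdf")),
                      plot_enrichment(report, s), width = 6, height = 4)
      ggplot2::ggsave(p(paste0("density_", safe, ".pdf")),
                      plot_score_density(report, s), width = 6, height = 4)
      ggplot2::ggsave(p(paste0("roc_", safe, ".pdf")),
                      plot_roc(report, s), width = 5, height = 5)
      ggplot2::ggsave(p(paste0("waterfall_", safe, ".pdf")),
                      plot_waterfall(report, s), width = 7, height = 4)
    }
  }
  invisible(outdir)
}

# per-group kernel-density grids of each assessed set's scores
density_table <- function(report) {
  if (is.null(report$assessment) || !nrow(report$assessment)) return(NULL)
  groups_of <- report$contrast
  do.call(rbind, lapply(report$assessment$set, function(s) {
    do.call(rbind, lapply(unname(groups_of), function(g) {
      sc <- report$strata[[s]]
      vals <- sc$centred[sc$group == g] +
        report$assessment$cutpoint[report$assessment$set == s]
      if (length(vals) < 2) return(NULL)
      d <- stats::density(vals, n = 128)
      data.frame(set = s, group = g, score = d$x, density = d$y)
    }))
  }))
}

#' Generate a synthetic cohort and write it to disk
#'
#' Convenience wrapper pairing [generate_cohort()] with [write_cohort()];
#' backs the CLI `simulate` subcommand.
#'
#' @param spec A [fixture_spec()] (or preset name accepted by
#'   [preset_fixture()]).
#' @param dir Output directory.
#' @return Named vector of written file paths, invisibly.
#' @export
simulate_cohort <- function(spec, dir) {
  if (is.character(spec)) spec <- preset_fixture(spec)
  write_cohort(generate_cohort(spec), dir)
}
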
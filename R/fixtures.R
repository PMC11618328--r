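#' Specification for a synthetic two-group cohort
#'
#' Describes a seeded synthetic expression cohort with one planted gene set:
#' i.i.d. Gaussian log2-scale background (a per-gene baseline drawn once,
#' plus per-cell noise) with `effect_delta` added in group `a` to the
#' responding members of the planted set. The other sets are uniform random
#' draws from the gene universe, so they carry no signal.
#'
#' @param n_genes Number of genes.
#' @param n_samples_a,n_samples_b Samples per group.
#' @param n_sets Number of gene sets in the generated collection (planted set
#'   included).
#' @param set_size_range Length-2 integer range of set sizes.
#' @param planted_set Name of the planted set.
#' @param planted_fraction Fraction of planted-set genes that respond
#'   (default 0.7, so the leading edge is a proper subset).
#' @param effect_delta Mean log2 shift added in group a to responding genes.
#' @param baseline_mean,baseline_sd Per-gene baseline distribution.
#' @param noise_sd Per-cell noise standard deviation.
#' @param seed Integer seed; the cohort is fully determined by the spec.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_genes = 2000, n_samples_a = 50, n_samples_b = 50,
                         n_sets = 50, set_size_range = c(20, 60),
                         planted_set = "PLANTED",
                         planted_fraction = 0.7, effect_delta = 1,
                         baseline_mean = 7, baseline_sd = 1.5,
                         noise_sd = 1, seed = 127) {
  spec <- list(n_genes = as.integer(n_genes),
               n_samples_a = as.integer(n_samples_a),
               n_samples_b = as.integer(n_samples_b),
               n_sets = as.integer(n_sets),
               set_size_range = as.integer(set_size_range),
               planted_set = planted_set,
               planted_fraction = planted_fraction,
               effect_delta = effect_delta,
               baseline_mean = baseline_mean, baseline_sd = baseline_sd,
               noise_sd = noise_sd, seed = as.integer(seed))
  stopifnot(spec$n_genes > 0, spec$n_samples_a > 0, spec$n_samples_b > 0,
            spec$n_sets > 0, length(spec$set_size_range) == 2,
            spec$set_size_range[1] >= 1,
            spec$set_size_range[2] >= spec$set_size_range[1],
            spec$set_size_range[2] < spec$n_genes,
            spec$planted_fraction > 0, spec$planted_fraction <= 1,
            spec$noise_sd > 0)
  if (spec$planted_fraction * spec$set_size_range[1] < 1) {
    stop("planted_fraction times the minimum set size must be >= 1 ",
         "(no responding gene otherwise)")
  }
  structure(spec, class = "fixture_spec")
}

#' Named preset fixture specifications
#'
#' Two pinned study conditions used throughout the tests:
#' \describe{
#'   \item{`overlapping_regime`}{Large cohort (200 + 200), small per-gene
#'     shift (`effect_delta = 0.25`, a quarter of the noise sd) on 70% of a
#'     small planted set. The planted set comes out significant in pairwise
#'     GSEA while its per-sample score distributions barely separate -- the
#'     "statistically significant but biologically overlapping" situation
#'     seen when contrasting clinical outcome groups.}
#'   \item{`distinct_regime`}{Moderate cohort (56 + 63, mirroring typical
#'     transcriptional-subtype arm sizes), large shift
#'     (`effect_delta = 2`, twice the noise sd) on every planted gene.
#'     The planted set is both significant and discriminating (AUC near 1,
#'     little overlap) -- the biologically distinct situation.}
#' }
#'
#' Both presets carry 20 gene sets: at 1000 permutations the +1-corrected
#' same-sign empirical p-value cannot fall below about 1/500, so with a
#' single truly shifted set BH-adjusted significance is arithmetically out of
#' reach for collections much larger than ~25 sets (real cohorts escape this
#' because many sets shift together).
#'
#' @param name `"overlapping_regime"` or `"distinct_regime"`.
#' @return A `fixture_spec`.
#' @export
preset_fixture <- function(name = c("overlapping_regime", "distinct_regime")) {
  name <- match.arg(name)
  switch(name,
    overlapping_regime = fixture_spec(
      n_genes = 2000, n_samples_a = 200, n_samples_b = 200, n_sets = 20,
      set_size_range = c(8, 17), planted_fraction = 0.7,
      effect_delta = 0.25, baseline_mean = 7, baseline_sd = 1.5,
      noise_sd = 1, seed = 127),
    distinct_regime = fixture_spec(
      n_genes = 2000, n_samples_a = 56, n_samples_b = 63, n_sets = 20,
      set_size_range = c(20, 60), planted_fraction = 1,
      effect_delta = 2, baseline_mean = 7, baseline_sd = 1.5,
      noise_sd = 1, seed = 127))
}

#' Generate a synthetic cohort with a planted gene-set shift
#'
#' @param spec A [fixture_spec()].
#' @return List with `expr` (genes x samples matrix), `groups` (named label
#'   vector, labels `"A"`/`"B"`), `collection` (gene_set_collection),
#'   `truth` (list: planted set name, responding genes, effect_delta).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_preserved_seed(spec$seed, {
    genes <- sprintf("g%04d", seq_len(spec$n_genes))
    samples <- c(sprintf("A%03d", seq_len(spec$n_samples_a)),
                 sprintf("B%03d", seq_len(spec$n_samples_b)))
    grp <- stats::setNames(rep(c("A", "B"),
                               c(spec$n_samples_a, spec$n_samples_b)), samples)
    baseline <- stats::rnorm(spec$n_genes, spec$baseline_mean, spec$baseline_sd)
    expr <- baseline + matrix(
      stats::rnorm(spec$n_genes * length(samples), 0, spec$noise_sd),
      nrow = spec$n_genes, dimnames = list(genes, samples))

    sizes <- sample(seq(spec$set_size_range[1], spec$set_size_range[2]),
                    spec$n_sets, replace = TRUE)
    sets <- lapply(sizes, function(k) sample(genes, k))
    names(sets) <- c(spec$planted_set,
                     sprintf("RANDOM_%02d", seq_len(spec$n_sets - 1)))
    planted_genes <- sets[[spec$planted_set]]
    n_resp <- max(1L, floor(spec$planted_fraction * length(planted_genes)))
    responding <- sample(planted_genes, n_resp)
    if (spec$effect_delta != 0) {
      expr[responding, grp == "A"] <-
        expr[responding, grp == "A"] + spec$effect_delta
    }
    list(expr = validate_expression(expr),
         groups = grp,
         collection = new_gene_set_collection(
           sets, stats::setNames(rep("synthetic", length(sets)), names(sets))),
         truth = list(planted_set = spec$planted_set,
                      responding_genes = if (spec$effect_delta != 0) responding
                                         else character(0),
                      effect_delta = spec$effect_delta,
                      spec = spec))
  })
}

#' Write a generated cohort to standard on-disk formats
#'
#' Expression and phenotype as TSV, the collection as GMT, the truth record
#' as a two-column TSV -- so fixtures double as end-to-end CLI inputs.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             phenotype = file.path(dir, "phenotype.tsv"),
             gene_sets = file.path(dir, "gene_sets.gmt"),
             truth = file.path(dir, "truth.tsv"))
  write_result_tsv(data.frame(gene = rownames(cohort$expr), cohort$expr,
                              check.names = FALSE, row.names = NULL),
                   paths[["expression"]])
  write_result_tsv(data.frame(sample = names(cohort$groups),
                              group = unname(cohort$groups)),
                   paths[["phenotype"]])
  write_gmt(cohort$collection, paths[["gene_sets"]])
  tr <- cohort$truth
  write_result_tsv(data.frame(
    key = c("planted_set", "effect_delta",
            rep("responding_gene", length(tr$responding_genes))),
    value = c(tr$planted_set, tr$effect_delta, tr$responding_genes)),
    paths[["truth"]])
  invisible(paths)
}

#' Null-calibration study of raw p-values
#'
#' Repeatedly generates null cohorts (`effect_delta = 0`), runs the pairwise
#' stage and the per-set score t-tests, and aggregates raw p-values: the
#' fraction below 0.05 should sit inside the binomial envelope around 0.05,
#' and the Kolmogorov-Smirnov distance from Uniform(0,1) should be small.
#'
#' @param spec A [fixture_spec()]; its `effect_delta` must be 0.
#' @param n_reps Number of replicate cohorts (>= 20).
#' @param seed Master seed; replicate r uses `seed + r`.
#' @param n_perm Permutations per pairwise run (default 200; the score-test
#'   calibration does not depend on it).
#' @param include_pairwise Also run the pairwise stage per rep (default TRUE).
#' @return List with `per_rep` (data frame: rep, min_padj_pairwise,
#'   min_padj_score), `pairwise_frac_p05`, `score_frac_p05`,
#'   `pairwise_ks`, `score_ks`, `n_pvalues`.
#' @export
null_pvalue_study <- function(spec, n_reps = 50, seed = 1,
                              n_perm = 200, include_pairwise = TRUE) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$effect_delta != 0) stop("null study requires effect_delta = 0")
  if (n_reps < 20) stop("n_reps must be >= 20")
  pw_p <- list(); sc_p <- list()
  per_rep <- data.frame(rep = seq_len(n_reps),
                        min_padj_pairwise = NA_real_,
                        min_padj_score = NA_real_)
  for (r in seq_len(n_reps)) {
    sp <- spec
    sp$seed <- spec$seed + r
    cohort <- generate_cohort(sp)
    if (include_pairwise) {
      diff <- differential_table(cohort$expr, cohort$groups, "A", "B")
      ranked <- rank_genes(diff, "tstat")
      pw <- run_pairwise_gsea(ranked, cohort$collection, n_perm = n_perm,
                              seed = seed + r)
      pw_p[[r]] <- pw$results$pvalue
      per_rep$min_padj_pairwise[r] <- min(pw$results$padj)
    }
    sc <- score_collection(cohort$expr, cohort$collection, method = "ssgsea")
    ps <- apply(sc, 1, function(row) {
      group_t_test(stats::setNames(row, colnames(sc)),
                   cohort$groups, "A", "B")$pvalue
    })
    sc_p[[r]] <- unname(ps)
    per_rep$min_padj_score[r] <- min(benjamini_hochberg(ps))
  }
  pw_all <- unlist(pw_p); sc_all <- unlist(sc_p)
  ks <- function(p) if (length(p)) unname(suppressWarnings(
    stats::ks.test(p, "punif")$statistic)) else NA_real_
  list(per_rep = per_rep,
       pairwise_frac_p05 = if (length(pw_all)) mean(pw_all < 0.05) else NA_real_,
       score_frac_p05 = mean(sc_all < 0.05),
       pairwise_ks = ks(pw_all),
       score_ks = ks(sc_all),
       n_pvalues = c(pairwise = length(pw_all), score = length(sc_all)))
}
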
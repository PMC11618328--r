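#' Weighted running-sum enrichment score
#'
#' Classic preranked GSEA statistic: walking down the ranked list, set members
#' ("hits") add `|metric|^p / sum_hits(|metric|^p)` and non-members subtract
#' `1 / (N - N_hit)`; the enrichment score is the running-sum value of maximal
#' absolute deviation. The leading edge contains the hit genes at or before
#' the extremum for positive ES, and at or after it for negative ES.
#'
#' @param ranked Named numeric vector from [rank_genes()] (descending order).
#' @param gene_set Character vector of gene ids.
#' @param weight_exponent Hit-weight exponent p (default 1, classic weighted
#'   GSEA).
#' @return List with `es`, `running_sum` (length N), `leading_edge`,
#'   `size_used`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  N <- length(ranked)
  hit <- names(ranked) %in% gene_set
  nh <- sum(hit)
  if (nh == 0) stop("gene set has empty intersection with the ranked universe")
  if (nh == N) stop("gene set covers the entire ranked universe; ",
                    "miss increment undefined")
  w <- abs(unname(ranked))^weight_exponent
  hw <- ifelse(hit, w, 0)
  denom <- sum(hw)
  if (denom == 0) {
    # all hit metrics are exactly zero: fall back to equal hit weights
    hw <- as.numeric(hit)
    denom <- nh
  }
  rs <- cumsum(hw / denom - (!hit) / (N - nh))
  imax <- which.max(rs); imin <- which.min(rs)
  es <- if (rs[imax] >= -rs[imin]) rs[imax] else rs[imin]
  iext <- if (es >= 0) imax else imin
  le <- if (es >= 0) names(ranked)[hit & seq_len(N) <= iext]
        else names(ranked)[hit & seq_len(N) >= iext]
  list(es = es, running_sum = rs, leading_edge = le, size_used = nh)
}

# ES only, from sorted hit positions; O(k) given sorted positions. The max
# positive deviation can only occur at a hit position and the min negative
# deviation only just before a hit (or 0 at the end), so only 2k candidates
# need checking. Used by the permutation null.
es_from_positions <- function(pos, w_at_pos, N) {
  k <- length(pos)
  denom <- sum(w_at_pos)
  if (denom == 0) {
    w_at_pos <- rep.int(1, k)
    denom <- k
  }
  cumhit <- cumsum(w_at_pos) / denom
  miss_before <- (pos - seq_len(k)) / (N - k)  # misses strictly before pos_j
  top <- cumhit - miss_before
  bottom <- c(0, cumhit[-k]) - miss_before
  maxdev <- max(top)
  mindev <- min(bottom, 0)
  if (maxdev >= -mindev) maxdev else mindev
}

#' Permutation null distribution of the enrichment score
#'
#' Gene-tag permutation: each draw scores a uniformly random subset of
#' `set_size` positions of the fixed ranking. Appropriate for the preranked
#' workflow, where phenotype labels are already consumed by the ranking step.
#' Reproducible given `seed`; nulls depend on the ranking and the set size
#' only, so equal-size sets can share one null sample.
#'
#' @inheritParams enrichment_score
#' @param set_size Number of genes per random set.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer RNG seed (default 127).
#' @return Numeric vector of `n_perm` null enrichment scores.
#' @export
permutation_null <- function(ranked, set_size, n_perm = 1000, seed = 127,
                             weight_exponent = 1) {
  N <- length(ranked)
  stopifnot(n_perm >= 1, set_size >= 1, set_size < N)
  w <- abs(unname(ranked))^weight_exponent
  with_preserved_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pos <- sort.int(sample.int(N, set_size))
      es_from_positions(pos, w[pos], N)
    }, numeric(1))
  })
}

# evaluate expr under set.seed(seed) without disturbing the caller's RNG state
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Normalized enrichment score and permutation p-value
#'
#' NES divides the observed ES by the mean magnitude of same-sign null scores;
#' the p-value is the +1-corrected one-sided empirical tail probability among
#' same-sign null scores (so p is never exactly 0).
#'
#' @param es Observed enrichment score.
#' @param null_sample Numeric vector of null enrichment scores.
#' @return List with `nes`, `pvalue`.
#' @export
normalized_enrichment <- function(es, null_sample) {
  if (length(null_sample) == 0) stop("empty null sample")
  if (es == 0) return(list(nes = 0, pvalue = 1))
  same <- null_sample[sign(null_sample) == sign(es)]
  if (length(same) == 0) {
    warning("no same-sign null enrichment scores; NES undefined, set to NA")
    return(list(nes = NA_real_, pvalue = 1))
  }
  list(nes = es / mean(abs(same)),
       pvalue = (1 + sum(abs(same) >= abs(es))) / (1 + length(same)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validating front end to `stats::p.adjust(method = "BH")`; input values must
#' lie in (0, 1] and the output is order-aligned with the input.
#'
#' @param pvalues Numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values (q-values), capped at 1.
#' @export
benjamini_hochberg <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Run preranked GSEA over a gene-set collection
#'
#' Scores every set against the ranked list, builds a shared gene-permutation
#' null per distinct set size, normalizes, and applies Benjamini-Hochberg
#' across all scored sets. Sets whose intersection with the ranked universe
#' falls outside `[min_size, max_size]` (or is empty / covers the universe)
#' are skipped with a recorded reason.
#'
#' @inheritParams enrichment_score
#' @param collection A `gene_set_collection` (named list of gene-id vectors).
#' @param n_perm Permutations per distinct set size (default 1000).
#' @param min_size,max_size Set-size filter applied to the intersection with
#'   the ranked universe (defaults 1 and `Inf`).
#' @param seed RNG seed for the permutation null (default 127).
#' @param fdr_threshold BH-adjusted significance threshold (default 0.05).
#' @return Object of class `pairwise_gsea`: list with `results` (data frame:
#'   set, size, es, nes, pvalue, padj, significant, leading_edge), `running_sums`
#'   (named list of numeric vectors), `skipped` (data frame set/reason),
#'   `params`.
#' @export
run_pairwise_gsea <- function(ranked, collection, n_perm = 1000,
                              min_size = 1, max_size = Inf,
                              weight_exponent = 1, seed = 127,
                              fdr_threshold = 0.05) {
  stopifnot(length(collection) > 0)
  universe <- names(ranked)
  N <- length(universe)
  inter <- lapply(collection, function(g) g[g %in% universe])
  sizes <- lengths(inter)
  reason <- rep("", length(collection))
  reason[sizes == 0] <- "empty intersection with ranked universe"
  reason[sizes == N] <- "covers entire ranked universe"
  reason[sizes > 0 & sizes < min_size] <- paste0("smaller than min_size = ", min_size)
  reason[sizes > max_size & sizes < N] <- paste0("larger than max_size = ", max_size)
  keep <- reason == ""
  if (!any(keep)) {
    stop("every gene set was filtered out: ",
         paste(unique(reason[!keep]), collapse = "; "))
  }
  scored <- names(collection)[keep]
  esr <- lapply(inter[keep], enrichment_score,
                ranked = ranked, weight_exponent = weight_exponent)
  # one null per distinct intersection size, seeded per size for independence
  # of set ordering
  used_sizes <- sort(unique(sizes[keep]))
  nulls <- lapply(used_sizes, function(k) {
    permutation_null(ranked, k, n_perm = n_perm,
                     seed = seed + match(k, used_sizes),
                     weight_exponent = weight_exponent)
  })
  names(nulls) <- as.character(used_sizes)
  norm <- lapply(seq_along(esr), function(i) {
    normalized_enrichment(esr[[i]]$es, nulls[[as.character(esr[[i]]$size_used)]])
  })
  res <- data.frame(
    set = scored,
    size = vapply(esr, `[[`, integer(1) + 0, "size_used"),
    es = vapply(esr, `[[`, numeric(1), "es"),
    nes = vapply(norm, `[[`, numeric(1), "nes"),
    pvalue = vapply(norm, `[[`, numeric(1), "pvalue"),
    row.names = NULL)
  res$padj <- benjamini_hochberg(res$pvalue)
  res$significant <- res$padj < fdr_threshold
  res$leading_edge <- vapply(esr, function(e)
    paste(e$leading_edge, collapse = ";"), character(1))
  rs <- lapply(esr, `[[`, "running_sum")
  names(rs) <- scored
  structure(list(
    results = res,
    running_sums = rs,
    skipped = data.frame(set = names(collection)[!keep],
                         reason = reason[!keep], row.names = NULL),
    params = list(n_perm = n_perm, min_size = min_size, max_size = max_size,
                  weight_exponent = weight_exponent, seed = seed,
                  fdr_threshold = fdr_threshold)),
    class = "pairwise_gsea")
}

#' @export
print.pairwise_gsea <- function(x, ...) {
  cat("pairwise_gsea:", nrow(x$results), "sets scored,",
      sum(x$results$significant), "significant at padj <",
      x$params$fdr_threshold, "\n")
  if (nrow(x$skipped)) cat("  skipped:", nrow(x$skipped), "sets\n")
  invisible(x)
}
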
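#' ssGSEA score of one gene set across samples
#'
#' Per sample, genes are ranked by expression (descending; average ranks for
#' ties) and given rank weights N..1 from the top. Walking down the list, the
#' normalized cumulative weighted hit ECDF minus the cumulative miss ECDF is
#' accumulated and the score is the SUM of those stepwise differences (the
#' integral of the gap, not its extremum). Depends only on within-sample rank
#' order, so it is invariant under strictly increasing per-sample transforms.
#'
#' @param expr Expression matrix, genes x samples.
#' @param gene_set Character vector of gene ids.
#' @param alpha Rank-weight exponent (default 0.25).
#' @return Named numeric vector of per-sample scores.
#' @export
ssgsea_score <- function(expr, gene_set, alpha = 0.25) {
  stopifnot(alpha >= 0)
  N <- nrow(expr)
  hit0 <- rownames(expr) %in% gene_set
  nh <- sum(hit0)
  if (nh == 0) stop("gene set has empty intersection with the expression matrix")
  if (nh == N) stop("gene set covers every gene in the matrix")
  scores <- vapply(seq_len(ncol(expr)), function(j) {
    x <- expr[, j]
    if (stats::sd(x) == 0) {
      warning("constant expression in sample '", colnames(expr)[j],
              "'; score set to 0 by symmetric tie handling")
      return(0)
    }
    # weight = within-sample rank counted from the bottom (top gene gets N);
    # ties share the average rank
    wts <- rank(x, ties.method = "average")
    ord <- order(x, decreasing = TRUE)
    hit <- hit0[ord]
    hw <- ifelse(hit, wts[ord]^alpha, 0)
    steps <- cumsum(hw) / sum(hw) - cumsum(!hit) / (N - nh)
    sum(steps)
  }, numeric(1))
  stats::setNames(scores, colnames(expr))
}

#' Range-normalize a score matrix
#'
#' Divides every value by the global (matrix-wide) max minus min. This is the
#' customary post-processing of raw ssGSEA scores; it preserves all within-
#' and between-sample orderings. Not idempotent: applying it twice divides
#' twice.
#'
#' @param scores Numeric matrix of single-sample scores.
#' @return Matrix of the same shape.
#' @export
range_normalize <- function(scores) {
  rng <- max(scores) - min(scores)
  if (rng == 0) stop("zero global score range; cannot range-normalize")
  out <- scores / rng
  attr(out, "method") <- attr(scores, "method")
  attr(out, "normalization") <- "range_normalized"
  out
}

#' gsva-style score of one gene set across samples
#'
#' A simplified faithful variant of the gene-set variation statistic: per
#' gene, each sample's expression level is converted to a cumulative density
#' across samples (gaussian kernel with bandwidth sd/4, or the empirical CDF);
#' per sample, genes are ordered by that density and given the symmetric rank
#' weight `|N/2 - position|^tau`; the score is the maximum positive deviation
#' plus the minimum negative deviation of the weighted hit-minus-miss walk
#' (difference-of-extremes convention). Not a bit-compatible port of any
#' existing package.
#'
#' @inheritParams ssgsea_score
#' @param tau Rank-weight exponent (default 1).
#' @param kernel `"gaussian"` or `"ecdf"`.
#' @return Named numeric vector of per-sample scores.
#' @export
gsva_score <- function(expr, gene_set, tau = 1,
                       kernel = c("gaussian", "ecdf")) {
  kernel <- match.arg(kernel)
  n <- ncol(expr)
  if (n < 3) stop("gsva-style scoring needs >= 3 samples for across-sample ",
                  "density estimation; use ssgsea_score instead")
  N <- nrow(expr)
  hit0 <- rownames(expr) %in% gene_set
  nh <- sum(hit0)
  if (nh == 0) stop("gene set has empty intersection with the expression matrix")
  if (nh == N) stop("gene set covers every gene in the matrix")
  cdf <- t(apply(expr, 1, function(x) {
    if (kernel == "gaussian") {
      h <- stats::sd(x) / 4
      if (h == 0) return(rep.int(0.5, n))
      rowMeans(stats::pnorm(outer(x, x, "-") / h))
    } else {
      (rank(x, ties.method = "average")) / n
    }
  }))
  scores <- vapply(seq_len(n), function(j) {
    if (diff(range(cdf[, j])) < 1e-12) return(0)  # no between-sample signal
    ord <- order(cdf[, j], decreasing = TRUE)
    hit <- hit0[ord]
    w <- abs(N / 2 - seq_len(N))^tau
    hw <- ifelse(hit, w, 0)
    denom <- sum(hw)
    if (denom == 0) { hw <- as.numeric(hit); denom <- nh }
    rs <- cumsum(hw / denom - (!hit) / (N - nh))
    max(rs, 0) + min(rs, 0)
  }, numeric(1))
  stats::setNames(scores, colnames(expr))
}

#' Z-score a score matrix by gene set (row)
#'
#' Per row: subtract the mean, divide by the sample (n-1) standard deviation.
#' Used to put heterogeneous gene sets on a common scale for heatmaps.
#'
#' @param scores Numeric matrix, sets x samples.
#' @return Matrix of the same shape; each row has mean 0 and sd 1.
#' @export
zscore_by_set <- function(scores) {
  sds <- apply(scores, 1, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance score row(s): ",
         paste(rownames(scores)[sds == 0], collapse = ", "))
  }
  out <- (scores - rowMeans(scores)) / sds
  attr(out, "method") <- attr(scores, "method")
  attr(out, "normalization") <- "zscore"
  out
}

#' Score a whole gene-set collection per sample
#'
#' Applies [ssgsea_score()] (default) or [gsva_score()] to every set in the
#' collection. Sets with no genes in the matrix are skipped and recorded.
#' ssGSEA scores are range-normalized by default, matching the customary
#' convention; pass `normalize = FALSE` for raw scores.
#'
#' @param expr Expression matrix, genes x samples.
#' @param collection Named list of gene-id vectors.
#' @param method `"ssgsea"` or `"gsva"`.
#' @param alpha,tau,kernel Scorer parameters, see [ssgsea_score()] and
#'   [gsva_score()].
#' @param normalize Range-normalize ssGSEA output (default TRUE; ignored for
#'   gsva, whose statistic is already range-bound).
#' @return Numeric matrix, sets x samples, with attributes `method`,
#'   `normalization` and `skipped` (data frame set/reason).
#' @export
score_collection <- function(expr, collection, method = c("ssgsea", "gsva"),
                             alpha = 0.25, tau = 1,
                             kernel = c("gaussian", "ecdf"),
                             normalize = TRUE) {
  method <- match.arg(method)
  kernel <- match.arg(kernel)
  present <- vapply(collection, function(g) any(g %in% rownames(expr)),
                    logical(1))
  if (!any(present)) stop("no gene set overlaps the expression matrix")
  dropped_genes <- vapply(collection[present],
                          function(g) sum(!g %in% rownames(expr)), numeric(1))
  if (any(dropped_genes > 0)) {
    message(sum(dropped_genes), " gene(s) absent from the matrix dropped ",
            "across ", sum(dropped_genes > 0), " set(s)")
  }
  rows <- lapply(collection[present], function(g) {
    if (method == "ssgsea") ssgsea_score(expr, g, alpha = alpha)
    else gsva_score(expr, g, tau = tau, kernel = kernel)
  })
  m <- do.call(rbind, rows)
  rownames(m) <- names(collection)[present]
  attr(m, "method") <- method
  attr(m, "normalization") <- "raw"
  if (method == "ssgsea" && normalize) m <- range_normalize(m)
  attr(m, "skipped") <- data.frame(
    set = names(collection)[!present],
    reason = rep("empty intersection with expression matrix", sum(!present)),
    row.names = NULL)
  m
}

#' Write a score matrix as TSV with a metadata sidecar line
#'
#' @param scores Matrix from [score_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  meta <- paste0("method=", attr(scores, "method") %||% "unknown",
                 " normalization=", attr(scores, "normalization") %||% "raw")
  df <- data.frame(set = rownames(scores), scores, check.names = FALSE,
                   row.names = NULL)
  write_result_tsv(df, path, schema_comment = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
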
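# Independent brute-force oracles. These deliberately re-derive each
# statistic from its definition with naive loops, sharing no code with the
# implementation under test.

# enrichment score: literal position-by-position walk
naive_es <- function(metrics, genes, gene_set, p = 1) {
  N <- length(metrics)
  in_set <- genes %in% gene_set
  nh <- sum(in_set)
  denom <- sum(abs(metrics[in_set])^p)
  rs <- numeric(N)
  acc <- 0
  for (i in seq_len(N)) {
    if (in_set[i]) {
      acc <- acc + if (denom > 0) abs(metrics[i])^p / denom else 1 / nh
    } else {
      acc <- acc - 1 / (N - nh)
    }
    rs[i] <- acc
  }
  # on an exact |max| == |min| tie the positive deviation wins (the
  # implementation's documented convention)
  if (max(rs) >= -min(rs)) max(rs) else min(rs)
}

# AUC: count wins + half-ties over all (positive, negative) pairs
brute_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  wins <- 0
  for (p in pos) for (n in neg) {
    wins <- wins + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  wins / (length(pos) * length(neg))
}

# BH: explicit sort / scale / cumulative-minimum step-up
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# tie-free random ranked list
random_ranked <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- sort(rnorm(n), decreasing = TRUE)
  while (anyDuplicated(v)) v <- sort(rnorm(n), decreasing = TRUE)
  structure(stats::setNames(v, sprintf("g%04d", seq_len(n))), metric = "tstat")
}

# tiny deterministic two-group expression fixture
tiny_cohort <- function(n_genes = 60, n_a = 6, n_b = 6, seed = 42) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  samples <- c(sprintf("a%02d", seq_len(n_a)), sprintf("b%02d", seq_len(n_b)))
  expr <- matrix(rnorm(n_genes * (n_a + n_b), 7, 1), n_genes,
                 dimnames = list(genes, samples))
  groups <- stats::setNames(rep(c("A", "B"), c(n_a, n_b)), samples)
  list(expr = expr, groups = groups)
}
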
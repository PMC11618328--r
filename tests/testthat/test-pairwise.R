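test_that("running-sum walk reproduces the hand-computed enrichment scores", {
  r3 <- structure(stats::setNames(c(3, 2, 1), c("g1", "g2", "g3")),
                  metric = "tstat")
  e <- enrichment_score(r3, "g1")
  expect_equal(e$es, 1.0)
  expect_equal(e$running_sum, c(1, 0.5, 0))
  expect_identical(e$leading_edge, "g1")

  e2 <- enrichment_score(r3, "g3")
  expect_equal(e2$es, -1.0)
  expect_identical(e2$leading_edge, "g3")

  r4 <- stats::setNames(c(4, 3, 2, 1), paste0("g", 1:4))
  e3 <- enrichment_score(r4, c("g1", "g3"))
  expect_equal(e3$es, 2 / 3)
  expect_equal(e3$running_sum, c(2 / 3, 1 / 6, 1 / 2, 0), tolerance = 1e-12)

  expect_error(enrichment_score(r3, c("g1", "g2", "g3")), "entire")
  expect_error(enrichment_score(r3, "absent"), "empty intersection")
})

test_that("enrichment_score agrees with the naive loop oracle on random instances", {
  set.seed(101)
  for (i in 1:200) {
    N <- sample(5:50, 1)
    ranked <- random_ranked(N)
    k <- sample(seq_len(N - 1), 1)
    gs <- sample(names(ranked), k)
    p <- sample(c(0, 0.5, 1, 1.5), 1)
    mine <- enrichment_score(ranked, gs, weight_exponent = p)
    expect_equal(mine$es,
                 naive_es(unname(ranked), names(ranked), gs, p),
                 tolerance = 1e-12)
    expect_lte(abs(mine$es), 1)
    expect_equal(mine$running_sum[N], 0, tolerance = 1e-9)
  }
})

test_that("enrichment scores agree with fgsea on a shared instance", {
  skip_if_not_installed("fgsea")
  set.seed(5)
  ranked <- random_ranked(300)
  sets <- lapply(1:10, function(i) sample(names(ranked), sample(5:40, 1)))
  names(sets) <- paste0("S", 1:10)
  ref <- suppressWarnings(
    fgsea::fgsea(sets, ranked, minSize = 1, maxSize = 500, nproc = 1))
  mine <- vapply(sets, function(g) enrichment_score(ranked, g)$es, numeric(1))
  expect_equal(unname(mine[ref$pathway]), ref$ES, tolerance = 1e-9)
})

test_that("reversing and negating the ranking negates the enrichment score", {
  set.seed(33)
  for (i in 1:30) {
    ranked <- random_ranked(sample(10:60, 1))
    gs <- sample(names(ranked), sample(2:5, 1))
    flipped <- structure(rev(-ranked), metric = "tstat")
    expect_equal(enrichment_score(flipped, gs)$es,
                 -enrichment_score(ranked, gs)$es, tolerance = 1e-12)
  }
})

test_that("permutation null is seeded, bounded, and centred for symmetric metrics", {
  ranked <- random_ranked(200, seed = 8)
  n1 <- permutation_null(ranked, 15, n_perm = 300, seed = 4)
  n2 <- permutation_null(ranked, 15, n_perm = 300, seed = 4)
  expect_identical(n1, n2)
  expect_true(all(abs(n1) <= 1))

  big <- permutation_null(ranked, 199, n_perm = 100, seed = 4)
  expect_true(all(abs(big) <= 1))

  # for an exactly sign-symmetric metric the null ES is symmetric about 0
  set.seed(13)
  half <- rexp(100) + 0.01
  sym <- structure(stats::setNames(sort(c(half, -half), decreasing = TRUE),
                                   sprintf("g%03d", 1:200)), metric = "tstat")
  null <- permutation_null(sym, 20, n_perm = 10000, seed = 12)
  expect_lt(abs(mean(null)), 3 * stats::sd(null) / sqrt(10000) + 0.01)
  expect_lt(abs(mean(sign(null))), 0.04)
})

test_that("fast null ES path matches the full walk", {
  set.seed(55)
  for (i in 1:100) {
    N <- sample(10:80, 1)
    ranked <- random_ranked(N)
    k <- sample(seq_len(N - 1), 1)
    pos <- sort(sample(N, k))
    w <- abs(unname(ranked))
    expect_equal(tandemgsea:::es_from_positions(pos, w[pos], N),
                 naive_es(unname(ranked), names(ranked),
                          names(ranked)[pos], 1),
                 tolerance = 1e-12)
  }
})

test_that("NES and permutation p follow the same-sign convention", {
  r <- normalized_enrichment(0.6, c(0.2, 0.4, -0.5))
  expect_equal(r$nes, 2)
  expect_equal(r$pvalue, 1 / 3)

  # boundary: a null value equal to |es| counts
  r2 <- normalized_enrichment(0.4, c(0.4, 0.2))
  expect_equal(r2$pvalue, 2 / 3)

  expect_identical(normalized_enrichment(0, c(0.1, -0.1)),
                   list(nes = 0, pvalue = 1))
  expect_warning(r3 <- normalized_enrichment(0.5, c(-0.1, -0.2)),
                 "no same-sign")
  expect_equal(r3$pvalue, 1)
  expect_error(normalized_enrichment(0.5, numeric(0)), "empty")
})

test_that("benjamini_hochberg matches the sort/cummin oracle and validates input", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_error(benjamini_hochberg(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\(0, 1\\]")
  set.seed(14)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(benjamini_hochberg(p), bh_oracle(p), tolerance = 1e-15)
  }
})

test_that("run_pairwise_gsea is deterministic, filters sets, and flags the planted set", {
  co <- generate_cohort(fixture_spec(n_genes = 400, n_samples_a = 30,
                                     n_samples_b = 30, n_sets = 10,
                                     set_size_range = c(10, 25),
                                     effect_delta = 1.5, seed = 10))
  ranked <- rank_genes(differential_table(co$expr, co$groups, "A", "B"),
                       "tstat")
  pw1 <- run_pairwise_gsea(ranked, co$collection, n_perm = 500, seed = 127)
  pw2 <- run_pairwise_gsea(ranked, co$collection, n_perm = 500, seed = 127)
  expect_identical(pw1$results, pw2$results)

  res <- pw1$results
  planted <- res[res$set == "PLANTED", ]
  expect_equal(which.max(abs(res$nes)), which(res$set == "PLANTED"))
  expect_lt(planted$padj, 0.05)
  expect_gt(planted$nes, 0)
  expect_true(all(res$padj >= res$pvalue - 1e-15))
  expect_true(all(sign(res$nes) == sign(res$es) | res$es == 0))
  # leading edge of the planted set is enriched in responding genes
  le <- strsplit(planted$leading_edge, ";")[[1]]
  expect_gt(mean(le %in% co$truth$responding_genes), 0.5)

  # size filters recorded with reasons
  pw3 <- run_pairwise_gsea(ranked, co$collection, n_perm = 100,
                           min_size = 15, seed = 1)
  expect_true(all(pw3$results$size >= 15))
  expect_true(all(grepl("min_size", pw3$skipped$reason)))
  expect_error(run_pairwise_gsea(ranked, co$collection, min_size = 1000),
               "filtered out")
})
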
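test_that("group t-test on scores matches the one-gene matrix route", {
  scores <- stats::setNames(c(1, 2, 3, 4, 5, 6), paste0("s", 1:6))
  grp <- stats::setNames(rep(c("A", "B"), each = 3), names(scores))
  r <- group_t_test(scores, grp, "A", "B")
  expect_equal(r$t, -3.674, tolerance = 1e-3)
  expect_equal(r$pvalue, 0.0213, tolerance = 1e-3)

  same <- stats::setNames(c(1, 2, 3, 1, 2, 3), paste0("s", 1:6))
  r2 <- group_t_test(same, grp, "A", "B")
  expect_equal(r2$t, 0)
  expect_equal(r2$pvalue, 1)

  co <- tiny_cohort(1, 5, 5, seed = 2)
  r3 <- group_t_test(co$expr[1, ], co$groups, "A", "B", "welch")
  ref <- t_statistic(co$expr, co$groups, "A", "B", "welch")
  expect_equal(r3$t, ref$tstat[[1]])
  expect_equal(r3$pvalue, ref$pvalue[[1]])
})

test_that("pearson correlation matches hand values and rejects degenerate input", {
  expect_equal(pearson_correlation(1:5, 1:5)$r, 1)
  expect_equal(pearson_correlation(1:5, -(1:5))$r, -1)
  expect_equal(pearson_correlation(c(1, 2, 3), c(1, 3, 2))$r, 0.5)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_correlation(1:2, 2:1), "at least 3")
})

test_that("distribution overlap follows the range-intersection definition", {
  expect_equal(distribution_overlap(c(0, 1), c(5, 6)), 0)
  expect_equal(distribution_overlap(c(1, 2, 3), c(1, 2, 3)), 100)
  expect_equal(distribution_overlap(c(0, 1, 2, 3), c(2, 3, 4, 5)), 50)
  # nested ranges cover the inner group entirely
  expect_equal(distribution_overlap(c(0, 10), c(4, 5, 6)), 60)
  # boundary values are inside the closed interval
  expect_equal(distribution_overlap(c(0, 2), c(2, 4)), 50)
})

test_that("roc_auc equals brute-force pair counting and handles ties", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(c(2, 2, 2, 2), c(0, 1, 0, 1))$auc, 0.5)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 1, 0, 1))$auc, 0.75)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")

  set.seed(23)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    scores <- sample(round(rnorm(n), sample(0:2, 1)))  # induce ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, brute_auc(scores, labels), tolerance = 1e-12)
    # complement and label-swap identities
    expect_equal(roc_auc(-scores, labels)$auc, 1 - r$auc, tolerance = 1e-12)
    expect_equal(roc_auc(scores, !labels)$auc, 1 - r$auc, tolerance = 1e-12)
    # curve is monotone from (0,0) to (1,1)
    expect_equal(r$roc_points$fpr[1], 0)
    expect_equal(r$roc_points$tpr[nrow(r$roc_points)], 1)
    expect_true(all(diff(r$roc_points$fpr) >= 0))
    expect_true(all(diff(r$roc_points$tpr) >= 0))
  }
})

test_that("roc_auc agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(29)
  for (i in 1:20) {
    scores <- rnorm(40)
    labels <- sample(c(TRUE, FALSE), 40, replace = TRUE)
    expect_equal(roc_auc(scores, labels)$auc,
                 as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                                direction = "<"))),
                 tolerance = 1e-12)
  }
})

test_that("optimal cutpoint maximizes sens + spec over observed scores", {
  r <- optimal_cutpoint(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(r$cutpoint, 3)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)

  d <- optimal_cutpoint(c(2, 2, 2, 2), c(0, 1, 0, 1))
  expect_true(d$degenerate)
  expect_equal(d$cutpoint, 2)
  expect_equal(d$sensitivity + d$specificity, 1)  # all called positive

  # translation equivariance
  set.seed(37)
  for (i in 1:30) {
    scores <- rnorm(20)
    labels <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    if (length(unique(labels)) < 2) next
    base <- optimal_cutpoint(scores, labels)
    shift <- runif(1, -5, 5)
    moved <- optimal_cutpoint(scores + shift, labels)
    expect_equal(moved$cutpoint, base$cutpoint + shift, tolerance = 1e-12)
    expect_equal(moved$sensitivity, base$sensitivity)
    expect_equal(moved$specificity, base$specificity)
    # (1 - spec, sens) lies on the ROC curve of the oriented scores
    pts <- roc_auc(if (base$direction == "ge") scores else -scores,
                   labels)$roc_points
    expect_true(any(abs(pts$fpr - (1 - base$specificity)) < 1e-12 &
                      abs(pts$tpr - base$sensitivity) < 1e-12))
    # auto direction achieves auc >= 0.5 orientation
    expect_gte(roc_auc(if (base$direction == "ge") scores else -scores,
                       labels)$auc, 0.5)
  }
})

test_that("stratification centres scores on the cutpoint with high at >= 0", {
  sc <- stats::setNames(c(1, 4), c("s1", "s2"))
  wf <- stratify_high_low(sc, 3)
  expect_equal(wf$centred, c(1, -2))
  expect_identical(wf$stratum, c("high", "low"))
  # exact boundary is high
  expect_identical(stratify_high_low(c(x = 3), 3)$stratum, "high")
  # waterfall ordering is descending
  set.seed(41)
  sc2 <- stats::setNames(rnorm(15), paste0("s", 1:15))
  wf2 <- stratify_high_low(sc2, 0.2)
  expect_true(all(diff(wf2$centred) <= 0))
  # agrees with the ge classification rule
  labels <- sc2 > 0
  cp <- optimal_cutpoint(sc2, labels, direction = "ge")
  wf3 <- stratify_high_low(sc2, cp$cutpoint)
  expect_identical(wf3$stratum == "high",
                   unname(sc2[wf3$sample] >= cp$cutpoint))
})

test_that("contingency summary counts and row percentages are conserved", {
  strata <- c("high", "high", "high", "low")
  groups <- c("a", "a", "b", "b")
  cs <- contingency_summary(strata, groups)
  expect_equal(unname(cs$counts["high", ]), c(2L, 1L))
  expect_equal(unname(cs$pcts["high", ]), c(66.7, 33.3))
  expect_equal(sum(cs$counts), 4)

  empty <- contingency_summary(rep("high", 4), groups)
  expect_true(empty$empty_stratum[["low"]])
  expect_equal(unname(empty$pcts["low", ]), c(0, 0))
})

test_that("dual report separates distinct from significant-but-overlapping regimes", {
  strong <- generate_cohort(fixture_spec(n_genes = 500, n_samples_a = 25,
                                         n_samples_b = 25, n_sets = 8,
                                         set_size_range = c(10, 25),
                                         planted_fraction = 1,
                                         effect_delta = 2, seed = 501))
  rep_s <- build_dual_report(strong$expr, strong$groups, "A", "B",
                             strong$collection, n_perm = 500, seed = 127)
  row <- rep_s$assessment[rep_s$assessment$set == "PLANTED", ]
  expect_identical(row$verdict, "distinct")
  expect_gt(row$auc, 0.95)
  expect_lt(row$overlap_pct, 30)
  expect_identical(row$auc_direction, "A")
  # counts conserve the cohort
  expect_equal(row$n_high_a + row$n_high_b + row$n_low_a + row$n_low_b, 50)
  # assessment padj is BH-monotone in pvalue
  a <- rep_s$assessment
  expect_true(all(a$padj >= a$pvalue - 1e-15))
  ord <- order(a$pvalue)
  expect_true(all(diff(cummax(a$padj[ord])) >= 0))

  null <- generate_cohort(fixture_spec(n_genes = 500, n_samples_a = 25,
                                       n_samples_b = 25, n_sets = 8,
                                       set_size_range = c(10, 25),
                                       effect_delta = 0, seed = 502))
  rep_n <- build_dual_report(null$expr, null$groups, "A", "B",
                             null$collection, n_perm = 500, seed = 127)
  expect_true(all(rep_n$assessment$verdict == "not_significant"))
})

test_that("ROC positive class follows the NES direction", {
  # plant the shift in group B by swapping labels at assessment time
  co <- generate_cohort(fixture_spec(n_genes = 400, n_samples_a = 20,
                                     n_samples_b = 20, n_sets = 6,
                                     set_size_range = c(10, 20),
                                     planted_fraction = 1,
                                     effect_delta = 2, seed = 77))
  rep <- build_dual_report(co$expr, co$groups, "B", "A", co$collection,
                           n_perm = 300, seed = 127)
  row <- rep$assessment[rep$assessment$set == "PLANTED", ]
  pw <- rep$pairwise$results[rep$pairwise$results$set == "PLANTED", ]
  expect_lt(pw$nes, 0)          # planted set is down in B vs A
  expect_identical(row$auc_direction, "A")
  expect_gt(row$auc, 0.9)       # direction-corrected AUC is high, not low
})
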
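test_that("confusion matrix at a threshold uses the strict > rule", {
  sc <- c(0.9, 0.6, 0.4, 0.2)
  lb <- c(TRUE, FALSE, TRUE, FALSE)
  cm <- confusion_at_threshold(sc, lb, 0.5)
  expect_equal(cm, list(tp = 1L, fp = 1L, fn = 1L, tn = 1L))
  low <- confusion_at_threshold(sc, lb, -1)
  expect_equal(low[c("fn", "tn")], list(fn = 0L, tn = 0L))
  expect_equal(low$tp, 2L); expect_equal(low$fp, 2L)
  hi <- confusion_at_threshold(sc, lb, 2)
  expect_equal(hi[c("tp", "fp")], list(tp = 0L, fp = 0L))
  # boundary: score equal to tau is predicted negative
  eq <- confusion_at_threshold(sc, lb, 0.4)
  expect_equal(eq$tp, 1L); expect_equal(eq$fn, 1L)
})

test_that("rates follow the confusion-matrix formulas and conventions", {
  expect_equal(recall(list(tp = 3, fn = 1, fp = 0, tn = 0)), 0.75)
  expect_equal(precision(list(tp = 0, fp = 0, fn = 2, tn = 3)), 1)
  expect_equal(fpr(list(tp = 0, fp = 0, fn = 0, tn = 5)), 0)
  expect_equal(precision(list(tp = 2, fp = 6, fn = 0, tn = 0)), 0.25)
  expect_error(recall(list(tp = 0, fn = 0, fp = 1, tn = 1)), "no observed")
  expect_error(fpr(list(tp = 1, fn = 1, fp = 0, tn = 0)), "undefined")
})

test_that("ROC-AUC: hand cases and degenerate-label error", {
  expect_equal(roc_auc(c(3, 2, 1), c(TRUE, TRUE, FALSE))$area, 1)
  expect_equal(roc_auc(rep(0.7, 6), rep(c(TRUE, FALSE), 3))$area, 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.3), c(TRUE, FALSE, TRUE))$area, 0.5)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "degenerate")
  r <- roc_auc(c(0.2, 0.8, 0.5, 0.5), c(FALSE, TRUE, TRUE, FALSE))
  expect_true(all(diff(r$points$fpr) >= 0))    # monotone sweep
  expect_true(all(diff(r$points$tpr) >= 0))
})

test_that("trapezoid AUC equals O(n^2) Mann-Whitney pair counting", {
  set.seed(88)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    scores <- sample(round(runif(n), sample(1:3, 1)))  # force ties often
    labels <- sample(c(TRUE, FALSE), n, TRUE)
    if (all(labels) || !any(labels)) labels[1:2] <- c(TRUE, FALSE)
    expect_equal(roc_auc(scores, labels)$area,
                 auc_pair_oracle(scores, labels), tolerance = 1e-12)
  }
})

test_that("average precision: hand case and rank-by-rank oracle", {
  expect_equal(pr_auc(c(3, 2, 1), c(TRUE, TRUE, FALSE))$area, 1)
  expect_equal(pr_auc(c(0.9, 0.8, 0.3), c(TRUE, FALSE, TRUE))$area,
               1 * 0.5 + (2 / 3) * 0.5, tolerance = 1e-12)
  expect_error(pr_auc(1:3, c(FALSE, FALSE, FALSE)), "no observed positives")
  set.seed(99)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    scores <- sample(round(runif(n), sample(1:3, 1)))
    labels <- sample(c(TRUE, FALSE), n, TRUE)
    if (!any(labels)) labels[1] <- TRUE
    expect_equal(pr_auc(scores, labels)$area,
                 ap_rank_oracle(scores, labels), tolerance = 1e-12)
  }
})

test_that("random scores give AP near the positive prevalence", {
  set.seed(4)
  n <- 1e4
  for (prev in c(0.15, 0.5)) {
    labels <- runif(n) < prev
    ap <- pr_auc(runif(n), labels)$area
    expect_lt(abs(ap - mean(labels)), 0.02)
  }
})

test_that("one_vs_rest extracts the target row and binarizes labels", {
  set.seed(61)
  P <- matrix(runif(30), 3, 10)
  P <- sweep(P, 2, colSums(P), "/")
  labs <- sample(1:3, 10, TRUE)
  sb <- one_vs_rest(P, toy_labeling(labs, target = 2), 2)
  expect_identical(sb$labels, labs == 2)
  expect_equal(sb$scores, P[2, ])
  expect_equal(roc_auc(sb$scores, sb$labels)$area,
               auc_pair_oracle(sb$scores, sb$labels), tolerance = 1e-12)
  expect_error(one_vs_rest(P, toy_labeling(labs), 5), "outside")
})

test_that("for S=2, AUC of one class mirrors the complement", {
  set.seed(14)
  m <- pnn_fit(matrix(rnorm(40), 10, 4), one_hot(rep(1:2, 5), 2), h = 2)
  labs_te <- rep(1:2, 4)
  P <- pnn_predict_proba(m, matrix(rnorm(32), 8, 4))
  a1 <- roc_auc(P[1, ], labs_te == 1)$area
  a2 <- roc_auc(P[2, ], labs_te == 2)$area
  expect_equal(a1, a2, tolerance = 1e-12)   # softmax: P[2,] = 1 - P[1,]
  expect_equal(roc_auc(1 - P[1, ], labs_te == 1)$area, 1 - a1,
               tolerance = 1e-12)
})

test_that("run_cv is deterministic, shares PINDX, formats mean(sd)", {
  cfg <- sim_config(n = 60, p = 40, n_qtl = 10, epistasis_pairs = 2,
                    h2 = 0.8, ld_rho = 0, seed = 2)
  X <- simulate_genotypes(cfg)
  sim <- simulate_phenotypes(X, cfg)
  lab <- assign_three_classes(sim$phenotype, 0.3, 0.7)
  pset <- stratified_partitions(lab, R = 3, test_frac = 0.15, seed = 2)
  ds <- align(X, sim$phenotype)
  r1 <- run_cv(ds, lab, pset, "pnn", seed = 2)
  r2 <- run_cv(ds, lab, pset, "pnn", seed = 2)
  expect_identical(r1$auc$per_partition, r2$auc$per_partition)
  expect_length(r1$auc$per_partition, 3L)
  expect_equal(r1$auc$mean, mean(r1$auc$per_partition))
  expect_equal(r1$auc$sd, sd(r1$auc$per_partition))
  expect_match(format(r1$auc), "^0\\.\\d{3}\\(0\\.\\d{3}\\)$")
  expect_identical(r1$aucpr$metric, "aucpr")

  fake <- structure(list(per_partition = c(0.2, 0.4), mean = 0.306,
                         sd = 0.118, metric = "aucpr", classifier = "pnn",
                         target_class = "upper", skipped = integer(0)),
                    class = "cv_result")
  expect_identical(format(fake), "0.306(0.118)")
})

test_that("run_cv skips partitions whose test fold is degenerate", {
  set.seed(9)
  X <- matrix(sample(0:2, 20 * 6, TRUE), 20, 6)
  labs <- rep(c(1L, 2L), c(17, 3))
  lab <- toy_labeling(labs, c("rest", "upper"), target = 2)
  codes <- matrix(1L, 20, 2)
  codes[c(18, 1), 1] <- 2L       # fold 1 contains a positive
  codes[c(1, 2), 2] <- 2L        # fold 2 has no positives -> skip
  pset <- partition_set(codes)
  expect_warning(res <- run_cv(X, lab, pset, "pnn", metrics = "auc",
                               seed = 1),
                 "degenerate")
  expect_equal(res$auc$skipped, 2L)
  expect_length(res$auc$per_partition, 1L)
})

test_that("an informative marker drives per-partition AUC to 1", {
  # oracle-style check: one marker separates the target class perfectly
  # and dominates the distance, so tuned PNN must rank it perfectly
  set.seed(123)
  n <- 30
  labs <- rep(1:2, each = 15)
  X <- cbind(ifelse(labs == 2, 2L, 0L), matrix(sample(0:1, n * 3, TRUE), n, 3))
  lab <- toy_labeling(labs, c("rest", "upper"), target = 2)
  pset <- stratified_partitions(lab, R = 2, test_frac = 0.2, seed = 7)
  res <- run_cv(X, lab, pset, "pnn", metrics = c("auc", "aucpr"), seed = 7)
  expect_equal(res$auc$per_partition, rep(1, 2))
  expect_equal(res$auc$sd, 0)
  expect_equal(res$aucpr$per_partition, rep(1, 2))
})
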
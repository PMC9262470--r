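test_that("confusion counting is exact and validates its input", {
  cm <- confusionCounts(c("cancer", "cancer", "noncancer"),
                        c("cancer", "noncancer", "noncancer"))
  expect_identical(as.integer(cm), c(1L, 0L, 1L, 1L))
  perfect <- confusionCounts(rep(c("cancer", "noncancer"), c(3, 2)),
                             rep(c("cancer", "noncancer"), c(3, 2)))
  expect_identical(as.integer(perfect), c(3L, 0L, 0L, 2L))
  expect_error(confusionCounts(character(0), character(0)), "empty")
  expect_error(confusionCounts(c("cancer", "x"), c("cancer", "cancer"),
                               classes = c("cancer", "noncancer")), "unknown")
  expect_error(confusionCounts("cancer", c("cancer", "cancer"),
                               classes = c("cancer", "noncancer")), "length")
})

test_that("every published-style metric cell reproduces from its confusion matrix", {
  cms <- studyConfusions()
  ref <- studyMetricTable()
  for (split in names(cms)) {
    m <- formatMetricsTable(metricsFromConfusion(cms[[split]]))
    got <- as.matrix(m[, c("accuracy", "precision", "recall", "fscore")])
    expect_equal(got, ref[[split]], ignore_attr = TRUE,
                 tolerance = 1e-12, label = split)
  }
})

test_that("macro averages come from unrounded per-class values", {
  m <- metricsFromConfusion(studyConfusions()[["70:30"]])
  # 24/26 = 92.3077...; averaging the rounded 92.31 with 100 would give 96.16
  expect_equal(m$precision[1], 2400 / 26, tolerance = 1e-12)
  expect_equal(roundHalfUp(m$precision[3]), 96.15)
  expect_false(isTRUE(all.equal(roundHalfUp((92.31 + 100) / 2, 2), 96.15)))
})

test_that("accuracy equals the support-weighted recall average", {
  for (cm in studyConfusions()) {
    m <- metricsFromConfusion(cm)
    support <- rowSums(cm)
    weighted <- sum(m$recall[1:2] * support) / sum(support)
    expect_equal(weighted, m$accuracy[1], tolerance = 1e-12)
  }
})

test_that("a perfect diagonal yields 100 everywhere", {
  m <- metricsFromConfusion(matrix(c(10L, 0L, 0L, 5L), 2, 2, byrow = TRUE,
                                   dimnames = list(c("cancer", "noncancer"),
                                                   c("cancer", "noncancer"))))
  expect_true(all(as.matrix(m[, -1]) == 100))
})

test_that("zero denominators flag instead of failing", {
  cm <- matrix(c(0L, 5L, 0L, 5L), 2, 2, byrow = TRUE,
               dimnames = list(c("cancer", "noncancer"),
                               c("cancer", "noncancer")))
  m <- metricsFromConfusion(cm)  # nothing predicted cancer
  expect_true(attr(m, "zero_denominator"))
  expect_equal(m$precision[1], 0)
})

test_that("F-scores recompute from printed precision/recall pairs", {
  expect_equal(roundHalfUp(fFromPR(92.31, 100.00)), 96.00)
  expect_equal(roundHalfUp(fFromPR(77.78, 100.00)), 87.50)
  expect_equal(fFromPR(100, 100), 100)
  f0 <- fFromPR(0, 0)
  expect_equal(as.numeric(f0), 0)
  expect_true(attr(f0, "zero_denominator"))
})

test_that("display rounding is half away from zero", {
  # binary-exact ties round away from zero
  expect_equal(roundHalfUp(0.125, 2), 0.13)
  expect_equal(roundHalfUp(-0.125, 2), -0.13)
  expect_equal(roundHalfUp(96.153846153846153, 2), 96.15)
  expect_equal(roundHalfUp(2400 / 26, 2), 92.31)
})

test_that("ROC endpoints, separation, and reversal behave canonically", {
  labels <- rep(c("cancer", "noncancer"), c(4, 6))
  sep <- c(0.9, 0.8, 0.85, 0.7, 0.3, 0.2, 0.1, 0.25, 0.15, 0.05)
  roc <- rocPoints(sep, labels)
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_equal(aucFromROC(roc), 1)                     # perfect separation
  expect_true(any(roc$fpr == 0 & roc$tpr == 1))
  rev <- rocPoints(1 - sep, labels)
  expect_equal(aucFromROC(rev), 0)                     # reversed scores
  expect_error(rocPoints(sep, rep("cancer", 10)), "both classes")
})

test_that("label-independent scores give chance-level AUROC", {
  set.seed(31)
  labels <- rep(c("cancer", "noncancer"), c(40, 60))
  aucs <- replicate(20, aucFromROC(rocPoints(runif(100), labels)))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("AUROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(17)
  labels <- rep(c("cancer", "noncancer"), c(12, 20))
  scores <- c(rnorm(12, 1), rnorm(20))
  mine <- aucFromROC(rocPoints(scores, labels))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("noncancer", "cancer"),
    direction = "<", quiet = TRUE)))
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("precision-recall sweeps share the ROC threshold convention", {
  labels <- rep(c("cancer", "noncancer"), c(3, 3))
  scores <- c(0.9, 0.6, 0.4, 0.5, 0.3, 0.1)
  pr <- prPoints(scores, labels)
  expect_equal(pr$recall[1], 1 / 3)                    # highest score is cancer
  expect_equal(pr$precision[1], 1)
  expect_equal(pr$recall[nrow(pr)], 1)                 # lowest threshold
  expect_equal(pr$precision[nrow(pr)], 0.5)
})
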
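resultsFrame <- function(truth, predicted, prob = NULL) {
  data.frame(case_id = sprintf("c%03d", seq_along(truth)), truth = truth,
             probability = if (is.null(prob)) as.numeric(predicted == "malignant") else prob,
             predicted = predicted, stringsAsFactors = FALSE)
}

test_that("stratified case-level folds: 27 benign + 33 malignant split 9/11 per fold", {
  df <- data.frame(case_id = sprintf("c%02d", 1:60),
                   label = c(rep("benign", 27), rep("malignant", 33)))
  folds <- makeFolds(df, k = 3L, seed = 1L)
  for (f in 1:3) {
    ids <- names(folds$assignment)[folds$assignment == f]
    expect_identical(sum(df$label[df$case_id %in% ids] == "benign"), 9L)
    expect_identical(sum(df$label[df$case_id %in% ids] == "malignant"), 11L)
  }
  # every case in exactly one fold
  expect_identical(sort(names(folds$assignment)), sort(df$case_id))
  # deterministic given the seed
  expect_identical(folds$assignment, makeFolds(df, 3L, seed = 1L)$assignment)
  # k = 1 puts everything in one fold
  expect_true(all(makeFolds(df, 1L, seed = 1L)$assignment == 1L))
  # more folds than cases of one class
  short <- data.frame(case_id = c("a", "b", "c", "d", "e"),
                      label = c("benign", "benign", "benign", "malignant",
                                "malignant"))
  expect_error(makeFolds(short, k = 3L, seed = 1L), "fewer malignant")
})

test_that("case aggregation: mean rule, >= 0.5 decides malignant", {
  expect_equal(aggregateCase(0.9), list(probability = 0.9, predicted = "malignant"))
  agg <- aggregateCase(c(0.2, 0.4))
  expect_equal(agg$probability, 0.3)
  expect_identical(agg$predicted, "benign")
  # 256 identical probabilities aggregate exactly
  expect_equal(aggregateCase(rep(0.37, 256))$probability, 0.37)
  # tie at 0.5 goes to malignant
  expect_identical(aggregateCase(0.5)$predicted, "malignant")
  expect_equal(aggregateCase(c(0.1, 0.9, 0.3), method = "median")$probability, 0.3)
  expect_error(aggregateCase(numeric(0)), "empty")
  expect_error(aggregateCase(c(0.2, 1.4)), "0, 1")
})

test_that("per-class accuracy prints the tabulated one-decimal percentages", {
  truth <- c(rep("benign", 27), rep("malignant", 33))
  predicted <- c(rep("benign", 18), rep("malignant", 9),    # 18/27 benign correct
                 rep("malignant", 31), rep("benign", 2))    # 31/33 malignant correct
  m <- classificationMetrics(resultsFrame(truth, predicted))
  expect_identical(m$benign_pct, 66.7)
  expect_identical(m$malignant_pct, 93.9)
  expect_equal(m$counts[["benign_correct"]], 18)
  # all correct -> 100 each
  m2 <- classificationMetrics(resultsFrame(truth, truth))
  expect_identical(c(m2$benign_pct, m2$malignant_pct, m2$overall_pct),
                   c(100, 100, 100))
  # swapping the labels swaps the two per-class columns
  swap <- function(x) ifelse(x == "benign", "malignant", "benign")
  m3 <- classificationMetrics(resultsFrame(swap(truth), swap(predicted)))
  expect_identical(m3$benign_pct, m$malignant_pct)
  expect_identical(m3$malignant_pct, m$benign_pct)
  expect_error(classificationMetrics(resultsFrame(rep("benign", 3),
                                                  rep("benign", 3))), "malignant")
})

test_that("ROC: perfect separation gives AUC 1, all-tied scores give the diagonal", {
  truth <- c(rep("benign", 10), rep("malignant", 10))
  perfect <- c(runif(10, 0, 0.4), runif(10, 0.6, 1))
  expect_identical(rocCurve(perfect, truth)$auc, 1)
  tied <- rocCurve(rep(0.5, 20), truth)
  expect_equal(tied$auc, 0.5)
  expect_identical(nrow(tied$points), 2L)   # single diagonal segment
  expect_error(rocCurve(runif(5), rep("benign", 5)), "both classes")
})

test_that("ROC points are monotone and AUC is invariant under monotone transforms", {
  set.seed(10)
  truth <- sample(c("benign", "malignant"), 50, replace = TRUE,
                  prob = c(0.4, 0.6))
  scores <- runif(50)
  roc <- rocCurve(scores, truth)
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_true(all(diff(roc$points$tpr) >= 0))
  expect_equal(roc$points$fpr[1], 0); expect_equal(roc$points$tpr[nrow(roc$points)], 1)
  expect_equal(rocCurve(qlogis(scores * 0.98 + 0.01), truth)$auc, roc$auc)
})

test_that("AUC agrees with an independent implementation on random data", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (i in 1:5) {
    truth <- sample(c("benign", "malignant"), 40, replace = TRUE)
    if (length(unique(truth)) < 2) next
    scores <- round(runif(40), 2)  # rounding forces ties
    ours <- rocCurve(scores, truth)$auc
    ref <- suppressMessages(as.numeric(pROC::auc(
      pROC::roc(response = truth, predictor = scores,
                levels = c("benign", "malignant"), direction = "<"))))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("label-independent scores give chance-level AUC over permutations", {
  set.seed(12)
  scores <- runif(200)
  aucs <- replicate(100, {
    truth <- sample(rep(c("benign", "malignant"), each = 100))
    rocCurve(scores, truth)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("the leakage audit rejects case overlap between training and test patches", {
  p1 <- toyPatches(n = 2L, size = 8L)
  expect_error(noduleGAN:::auditNoLeakage(p1, p1), "leakage")
  expect_true(noduleGAN:::auditNoLeakage(p1[1:2], p1[3:4]))
})

test_that("strategy comparison is deterministic and shaped one row per strategy", {
  cohort <- generateCohort(3L, 3L, quietPhantomConfig(), seed = 21L)
  augCfg <- augmentConfig(angleMin = -40, angleMax = 40, angleStep = 80,
                          tiltAxes = "x", symmetryOps = c("r0", "r90"),
                          outSize = 32L)
  run <- function() compareStrategies(
    cohort, strategies = "scratch", k = 3L, seed = 5L, augCfg = augCfg,
    preCfg = pretrainConfig(epochs = 1L, batchSize = 4L),
    ftCfg = finetuneConfig(epochs = 1L, lr = 0.02, batchSize = 4L),
    foldSubset = 1L)
  a <- run(); b <- run()
  expect_identical(a$table, b$table)
  expect_identical(names(a$table),
                   c("strategy", "pretraining", "benign_pct", "malignant_pct",
                     "overall_pct", "auc"))
  expect_identical(a$table$pretraining, "None")
  # each held-out case appears exactly once
  expect_false(anyDuplicated(a$results$scratch$case_id) > 0)
})
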
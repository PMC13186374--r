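test_that("fold plans partition patients with class stratification", {
  ids <- c(sprintf("M%03d", 1:19), sprintf("N%03d", 1:19),
           sprintf("L%03d", 1:19))
  dx <- rep(c("M", "N", "NL"), each = 19)
  fp <- makeFoldPlan(ids, dx, seed = 4)
  # every patient in exactly one outer fold; sizes 11 or 12
  expect_setequal(names(fp@outer), ids)
  expect_true(all(table(fp@outer) %in% c(11, 12)))
  # per-class outer counts differ by at most 1
  byClass <- table(fp@outer, dx[match(names(fp@outer), ids)])
  expect_true(all(apply(byClass, 2, function(x) diff(range(x))) <= 1))
  for (k in 1:5) {
    testPat <- names(fp@outer)[fp@outer == k]
    inner <- fp@inner[[k]]
    # inner folds partition exactly the non-test patients
    expect_setequal(c(names(inner), testPat), ids)
    expect_length(intersect(names(inner), testPat), 0)
    innerClass <- table(inner, dx[match(names(inner), ids)])
    expect_true(all(apply(innerClass, 2,
                          function(x) diff(range(x))) <= 1))
    # train/val/test triples are pairwise disjoint and exhaustive
    for (j in 1:3) {
      val <- names(inner)[inner == j]
      train <- names(inner)[inner != j]
      expect_length(intersect(train, val), 0)
      expect_length(intersect(train, testPat), 0)
      expect_setequal(c(train, val, testPat), ids)
    }
  }
  # reproducible from seed
  fp2 <- makeFoldPlan(ids, dx, seed = 4)
  expect_identical(fp@outer, fp2@outer)
  expect_identical(fp@inner, fp2@inner)
  expect_error(makeFoldPlan(ids[1:8], dx[1:8], seed = 1), "at least")
})

test_that("nested CV produces one prediction per run and test item", {
  # miniature setting: 2x2 folds, 2 seeds -> 4 runs, 16 trainings
  coh <- simulateCohort(nPerClass = 4, signalsPerPatient = c(1, 2),
                        durationRange = c(0.45, 0.9), seed = 31)
  se <- segmentCohort(coh)
  pt <- patientTable(coh)
  fp <- makeFoldPlan(pt$patient_id, pt$diagnosis, nOuter = 2, nInner = 2,
                     seed = 5)
  tc <- emgTrainConfig(evalEvery = 10, patience = 2, maxUpdates = 40,
                       batchSize = 16, seed = 77)
  pred <- runNestedCV(se, fp, smokeModelConfig(), tc, seeds = c(1, 2))
  expect_setequal(unique(pred$run_id),
                  c("seed1.inner1", "seed1.inner2",
                    "seed2.inner1", "seed2.inner2"))
  pp <- pred[pred$level == "patient", ]
  # every patient predicted exactly once per run
  expect_true(all(table(pp$item_id, pp$run_id) == 1))
  expect_setequal(unique(pp$item_id), pt$patient_id)
  # signals likewise
  ps <- pred[pred$level == "signal", ]
  expect_true(all(table(ps$item_id, ps$run_id) == 1))
  # no patient appears in the train side of its own test run: re-derive
  # from the plan
  for (k in 1:2) {
    testPat <- names(fp@outer)[fp@outer == k]
    expect_length(intersect(testPat, names(fp@inner[[k]])), 0)
  }
  # determinism: identical call -> identical table
  pred2 <- runNestedCV(se, fp, smokeModelConfig(), tc, seeds = c(1, 2))
  expect_identical(pred, pred2)
})

test_that("confusion matrices count true-by-predicted pairs", {
  truth <- rep(c("M", "N", "NL"), each = 10)
  cmPerfect <- confusionMatrix3(truth, truth)
  expect_equal(unname(diag(cmPerfect)), c(10, 10, 10))
  expect_equal(sum(cmPerfect), 30)
  cmAllN <- confusionMatrix3(truth, rep("N", 30))
  expect_true(all(cmAllN[, c(1, 3)] == 0))
  expect_equal(unname(cmAllN[, 2]), c(10, 10, 10))
  set.seed(9)
  pred <- sample(diagnosisLevels(), 30, replace = TRUE)
  cm <- confusionMatrix3(truth, pred)
  expect_equal(unname(rowSums(cm)), c(10, 10, 10))
  expect_error(confusionMatrix3(truth, pred[1:10]), "length")
  expect_error(confusionMatrix3("X", "M"), "invalid diagnosis")
})

test_that("macro one-vs-rest metrics match hand-worked cases and oracle", {
  # perfect predictions
  m <- metricsFromConfusion(diag(c(5, 5, 5)))
  expect_equal(unlist(m[c("accuracy", "precision", "recall",
                          "specificity", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1,
                 specificity = 1, f1 = 1))
  # everything predicted as class M, with the 0/0 -> 0 convention
  cm <- matrix(0, 3, 3); cm[, 1] <- 10
  m2 <- metricsFromConfusion(cm)
  expect_equal(m2$accuracy, 1 / 3)
  expect_equal(m2$precision, 1 / 9)
  expect_equal(m2$recall, 1 / 3)
  expect_equal(m2$specificity, 2 / 3)
  # random confusion matrices vs brute-force item-level counter
  set.seed(12)
  for (i in 1:200) {
    cm <- matrix(rpois(9, 4), 3, 3)
    if (sum(cm) == 0) next
    got <- metricsFromConfusion(cm)
    want <- oracleMetrics(cm)
    for (nm in names(want))
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-12, label = nm)
  }
  expect_error(metricsFromConfusion(matrix(0, 3, 3)), "all-zero")
})

test_that("rater scores travel through the same metric path as model runs", {
  # identical label tables must give identical metric rows
  set.seed(15)
  truth <- sample(diagnosisLevels(), 40, replace = TRUE)
  pred <- sample(diagnosisLevels(), 40, replace = TRUE)
  runsDf <- data.frame(run_id = "r1", level = "signal",
                       true_label = truth, pred_label = pred)
  mRun <- evaluateRuns(runsDf)
  panel <- new("RaterPanel", nRaters = 1L,
               confusion = list(diag(3)),
               labels = data.frame(rater_id = "R1", item_type = "signal",
                                   item_id = sprintf("s%d", 1:40),
                                   true_label = truth, label = pred))
  mRater <- evaluateRaters(panel)
  for (nm in c("accuracy", "precision", "recall", "specificity", "f1"))
    expect_equal(mRater[[nm]], mRun[[nm]])
})

test_that("ROC and PR point sets match exhaustive threshold enumeration", {
  # perfectly separated scores: ROC passes through (0, 1)
  truth <- c("M", "M", "N", "NL")
  probs <- rbind(c(.9, .05, .05), c(.8, .1, .1),
                 c(.2, .7, .1), c(.1, .2, .7))
  cur <- rocPrCurves(truth, probs)
  rocM <- cur[cur$class == "M" & cur$curve == "roc", ]
  expect_true(any(rocM$x == 0 & rocM$y == 1))
  # identical scores for all items: ROC is {(0,0), (1,1)}
  flat <- matrix(1 / 3, 4, 3)
  curF <- rocPrCurves(truth, flat)
  rocF <- curF[curF$class == "M" & curF$curve == "roc", ]
  expect_equal(rocF$x, c(0, 1))
  expect_equal(rocF$y, c(0, 1))
  # n = 6: agree with brute-force enumeration over all thresholds
  set.seed(17)
  t6 <- c("M", "N", "M", "NL", "N", "M")
  p6 <- emgdx:::.softmaxRows(matrix(rnorm(18), 6, 3))
  cur6 <- rocPrCurves(t6, p6)
  pos <- t6 == "M"; sc <- p6[, 1]
  for (thr in sort(unique(sc), decreasing = TRUE)) {
    tp <- sum(sc >= thr & pos); fp <- sum(sc >= thr & !pos)
    rocRow <- cur6[cur6$class == "M" & cur6$curve == "roc" &
                     cur6$threshold == thr, ]
    expect_equal(rocRow$x, fp / sum(!pos))
    expect_equal(rocRow$y, tp / sum(pos))
    prRow <- cur6[cur6$class == "M" & cur6$curve == "pr" &
                    cur6$threshold == thr, ]
    expect_equal(prRow$x, tp / sum(pos))
    expect_equal(prRow$y, tp / (tp + fp))
  }
  # cross-check ROC operating points against pROC
  r <- pROC::roc(response = pos, predictor = sc, quiet = TRUE,
                 direction = "<")
  ours <- cur6[cur6$class == "M" & cur6$curve == "roc", c("x", "y")]
  theirs <- data.frame(x = rev(1 - r$specificities),
                       y = rev(r$sensitivities))
  expect_true(all(apply(theirs, 1, function(pt)
    any(abs(ours$x - pt[1]) < 1e-9 & abs(ours$y - pt[2]) < 1e-9))))
  # a class missing from the truth has no curve and is flagged
  cur2 <- rocPrCurves(c("M", "M", "N"), probs[1:3, ])
  expect_equal(attr(cur2, "undefined"), "NL")
  expect_false("NL" %in% cur2$class)
})

test_that("rank comparison is exact for small untied score sets", {
  cs <- compareScoreSets(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cs$U, 0)
  expect_equal(cs$pValue, 0.1)
  expect_true(cs$exact)
  # enumeration oracle: all C(6,3) = 20 rank splits
  allU <- apply(combn(6, 3), 2, function(idx) {
    ranks <- 1:6
    sum(ranks[idx]) - 3 * 4 / 2
  })
  pEnum <- mean(abs(allU - 4.5) >= abs(0 - 4.5))
  expect_equal(cs$pValue, pEnum)
  # identical sets: p = 1
  expect_equal(compareScoreSets(c(1, 2, 3), c(1, 2, 3))$pValue, 1)
  # smallest attainable two-sided p for sizes (9, 6)
  cs96 <- compareScoreSets(7:15, 1:6)
  expect_equal(cs96$pValue, 2 / choose(15, 6), tolerance = 1e-12)
  # medians and quartiles reported per set
  expect_equal(cs$medianA, 2)
  expect_equal(cs$medianB, 5)
  expect_error(compareScoreSets(numeric(0), 1:3), "non-empty")
})

test_that("results directory writer emits the four standard artifacts", {
  fx <- fixtureCohort()
  d <- tempfile()
  pred <- data.frame(run_id = "seed1.inner1", level = "patient",
                     item_id = "M001", true_label = "M", pred_label = "M")
  metrics <- evaluateRuns(pred)
  comparison <- compareScoreSets(c(1, 2, 3), c(4, 5, 6))
  writeResults(pred, metrics, curves = NULL, comparison = comparison,
               directory = d)
  expect_true(file.exists(file.path(d, "predictions.csv")))
  expect_true(file.exists(file.path(d, "metrics.csv")))
  expect_true(file.exists(file.path(d, "comparison.json")))
  back <- jsonlite::read_json(file.path(d, "comparison.json"))
  expect_equal(back$pValue, 0.1)
})
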
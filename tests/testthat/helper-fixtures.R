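# Shared fixtures, built lazily once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Compact model/training settings used for desk-scale evaluation runs:
# decimating stem (inputPool 8), narrow channels, capped updates. The
# synthetic classes are strongly separable, so these converge well before
# the cap.
smokeModelConfig <- function() {
  emgNetConfig(channels = c(6, 12), inputPool = 8, stemPool = 1)
}

smokeTrainConfig <- function(seed = 303) {
  emgTrainConfig(evalEvery = 25, patience = 3, maxUpdates = 180, seed = seed)
}

# Small default-physiology cohort (9 patients) plus its segments.
fixtureCohort <- function() {
  if (is.null(.fixtures$coh)) {
    .fixtures$coh <- simulateCohort(nPerClass = 3,
                                    signalsPerPatient = c(2, 3),
                                    durationRange = c(0.8, 1.4), seed = 11)
    .fixtures$se <- segmentCohort(.fixtures$coh)
  }
  list(cohort = .fixtures$coh, segments = .fixtures$se)
}

# A model trained on the small cohort (patients *01..*02 train, *03 val).
fixtureTrainedModel <- function() {
  if (is.null(.fixtures$model)) {
    fx <- fixtureCohort()
    cd <- SummarizedExperiment::colData(fx$segments)
    X <- SummarizedExperiment::assay(fx$segments)
    valPat <- grepl("003$", cd$patient_id)
    m <- buildModel(smokeModelConfig(), seed = 42)
    .fixtures$model <- trainModel(
      m, X[, !valPat], X[, valPat],
      trainLabels = cd$diagnosis[!valPat],
      valLabels = cd$diagnosis[valPat],
      trainConfig = emgTrainConfig(evalEvery = 20, patience = 4,
                                   maxUpdates = 400, seed = 7))
  }
  .fixtures$model
}

# Full-scale evaluation: default 57-patient cohort, nested 5x3 CV with
# 3 seeds (9 runs), and a matched rater panel. Computed once; reused by
# several acceptance checks.
fixtureNestedCV <- function() {
  if (is.null(.fixtures$cv)) {
    coh <- simulateCohort(seed = 101)
    se <- segmentCohort(coh)
    pt <- patientTable(coh)
    fp <- makeFoldPlan(pt$patient_id, pt$diagnosis, seed = 202)
    pred <- runNestedCV(se, fp, smokeModelConfig(), smokeTrainConfig(),
                        seeds = c(1, 2, 3))
    panel <- simulateRaterPanel(coh, seed = 404)
    .fixtures$cv <- list(cohort = coh, plan = fp, predictions = pred,
                         metrics = evaluateRuns(pred), panel = panel)
  }
  .fixtures$cv
}

# Independent brute-force oracle for the one-vs-rest metrics: expand the
# confusion matrix into item-level label pairs and count TP/FP/FN/TN per
# class by direct comparison.
oracleMetrics <- function(cm) {
  truth <- rep(rep(1:3, each = 3), times = as.vector(t(cm)))
  pred <- rep(rep(1:3, times = 3), times = as.vector(t(cm)))
  safe <- function(a, b) if (b == 0) 0 else a / b
  per <- sapply(1:3, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    tn <- sum(truth != cl & pred != cl)
    prec <- safe(tp, tp + fp); rec <- safe(tp, tp + fn)
    c(precision = prec, recall = rec,
      specificity = safe(tn, tn + fp),
      f1 = safe(2 * prec * rec, prec + rec))
  })
  list(accuracy = sum(truth == pred) / length(truth),
       precision = mean(per["precision", ]),
       recall = mean(per["recall", ]),
       specificity = mean(per["specificity", ]),
       f1 = mean(per["f1", ]))
}

# Independent majority+tie oracle over argmax patterns.
oracleVote <- function(probRows) {
  votes <- apply(probRows, 1, which.max)
  counts <- sapply(1:3, function(c) sum(votes == c))
  top <- which(counts == max(counts))
  if (length(top) == 1L) {
    list(label = diagnosisLevels()[top], tie = FALSE)
  } else {
    mass <- sapply(top, function(c) sum(probRows[, c]))
    list(label = diagnosisLevels()[top[which.max(mass)]], tie = TRUE)
  }
}
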
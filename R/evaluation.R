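#' Build a nested cross-validation fold plan
#'
#' Patient-level, class-stratified partition: `nOuter` outer test folds,
#' and for each outer fold a partition of the remaining patients into
#' `nInner` inner folds that rotate as validation sets. Splits are always
#' by patient -- never by signal or segment -- so no patient ever appears
#' in both the train and validation/test side of a run. Per-class fold
#' counts differ by at most one; remainder patients are placed greedily to
#' balance total fold sizes.
#'
#' @param patientIds Character vector of patient identifiers.
#' @param diagnoses Matching diagnosis labels.
#' @param nOuter,nInner Fold counts (default 5 and 3).
#' @param seed Seed; plans are reproducible.
#' @return A [FoldPlan-class].
#' @export
makeFoldPlan <- function(patientIds, diagnoses, nOuter = 5, nInner = 3,
                         seed = 1) {
  stopifnot(length(patientIds) == length(diagnoses),
            !anyDuplicated(patientIds))
  diagnoses <- as.character(diagnoses)
  .checkDiagnosis(diagnoses)
  perClass <- table(factor(diagnoses, levels = diagnosisLevels()))
  if (any(perClass < nOuter))
    stop("need at least ", nOuter, " patients per class for stratification",
         call. = FALSE)
  assignStratified <- function(ids, dx, k) {
    out <- integer(length(ids)); names(out) <- ids
    total <- integer(k)
    for (cls in unique(dx)) {
      cid <- sample(ids[dx == cls])
      base <- length(cid) %/% k
      rem <- length(cid) %% k
      counts <- rep(base, k)
      if (rem > 0) {
        # give extras to the currently smallest folds, random tie-break
        ord <- order(total + counts, sample(k))
        counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1L
      }
      folds <- rep(seq_len(k), counts)
      out[cid] <- folds
      total <- total + counts
    }
    out
  }
  withSeed(seed, {
    outer <- assignStratified(patientIds, diagnoses, nOuter)
    inner <- lapply(seq_len(nOuter), function(k) {
      keep <- outer != k
      rest <- patientIds[match(names(outer)[keep], patientIds)]
      restDx <- diagnoses[match(rest, patientIds)]
      if (any(table(restDx) < nInner))
        stop("too few patients per class for ", nInner, " inner folds",
             call. = FALSE)
      assignStratified(rest, restDx, nInner)
    })
    new("FoldPlan", outer = outer, inner = inner,
        nOuter = as.integer(nOuter), nInner = as.integer(nInner),
        seed = as.integer(seed))
  })
}

#' Run the nested cross-validation evaluation
#'
#' For every outer test fold, every inner validation fold, and every model
#' seed: train on the remaining inner folds, early-stop on the validation
#' fold, and predict the outer test fold. A (seed, inner fold) pair
#' defines one prediction run spanning all outer folds, so each test
#' patient and signal receives exactly `length(seeds) * nInner`
#' predictions (9 for the default 3 seeds x 3 inner folds).
#'
#' @param segments `SummarizedExperiment` from [segmentCohort()].
#' @param foldPlan A [FoldPlan-class] over the cohort's patients.
#' @param modelConfig An [emgNetConfig()].
#' @param trainConfig An [emgTrainConfig()]; per-run seeds are derived
#'   from `trainConfig$seed` and the run indices.
#' @param seeds Model seeds (default `c(1, 2, 3)`).
#' @param patientPooled Passed to [aggregatePredictions()].
#' @param verbose Print per-run progress.
#' @return `data.frame` of predictions with columns `run_id`, `seed`,
#'   `inner_fold`, `outer_fold`, `level`, `item_id`, `patient_id`,
#'   `true_label`, `pred_label`, `p_M`, `p_N`, `p_NL`, `tie_broken`.
#' @export
runNestedCV <- function(segments, foldPlan, modelConfig = emgNetConfig(),
                        trainConfig = emgTrainConfig(), seeds = c(1, 2, 3),
                        patientPooled = FALSE, verbose = FALSE) {
  stopifnot(is(segments, "SummarizedExperiment"), is(foldPlan, "FoldPlan"))
  cd <- SummarizedExperiment::colData(segments)
  X <- SummarizedExperiment::assay(segments, "segments")
  pat <- as.character(cd$patient_id)
  missing <- setdiff(unique(pat), names(foldPlan@outer))
  if (length(missing))
    stop("fold plan does not cover patient(s): ",
         paste(head(missing, 3), collapse = ", "), call. = FALSE)
  out <- list()
  for (k in seq_len(foldPlan@nOuter)) {
    testPat <- names(foldPlan@outer)[foldPlan@outer == k]
    testIdx <- which(pat %in% testPat)
    innerMap <- foldPlan@inner[[k]]
    for (j in seq_len(foldPlan@nInner)) {
      valPat <- names(innerMap)[innerMap == j]
      trainPat <- names(innerMap)[innerMap != j]
      trIdx <- which(pat %in% trainPat)
      vaIdx <- which(pat %in% valPat)
      for (si in seq_along(seeds)) {
        s <- seeds[si]
        tc <- trainConfig
        tc$seed <- childSeed(trainConfig$seed, k, j, s)
        model <- buildModel(modelConfig, seed = childSeed(s, k, j))
        model <- trainModel(model,
                            X[, trIdx, drop = FALSE],
                            X[, vaIdx, drop = FALSE],
                            trainLabels = cd$diagnosis[trIdx],
                            valLabels = cd$diagnosis[vaIdx],
                            trainConfig = tc)
        probs <- predictSegments(model, X[, testIdx, drop = FALSE])
        agg <- aggregatePredictions(probs,
                                    signalIds = cd$signal_id[testIdx],
                                    patientIds = pat[testIdx],
                                    trueLabels = cd$diagnosis[testIdx],
                                    patientPooled = patientPooled)
        agg$run_id <- sprintf("seed%d.inner%d", si, j)
        agg$seed <- s
        agg$inner_fold <- j
        agg$outer_fold <- k
        out[[length(out) + 1L]] <- agg
        if (verbose)
          message(sprintf("outer %d inner %d seed %d: %d test items",
                          k, j, s, nrow(agg)))
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[c("run_id", "seed", "inner_fold", "outer_fold", "level", "item_id",
        "patient_id", "true_label", "pred_label", "p_M", "p_N", "p_NL",
        "tie_broken")]
}

#' 3x3 confusion matrix
#'
#' Entry (i, j) counts items with true class i predicted as class j
#' (order M, N, NL).
#'
#' @param trueLabels,predLabels Equal-length label vectors.
#' @return 3x3 integer matrix with dimnames.
#' @export
confusionMatrix3 <- function(trueLabels, predLabels) {
  if (length(trueLabels) != length(predLabels))
    stop("label vectors differ in length", call. = FALSE)
  tf <- diagnosisFactor(trueLabels)
  pf <- diagnosisFactor(predLabels)
  m <- table(true = tf, predicted = pf)
  matrix(as.integer(m), 3, 3,
         dimnames = list(true = diagnosisLevels(),
                         predicted = diagnosisLevels()))
}

.safeRatio <- function(num, den) ifelse(den == 0, 0, num / den)

#' One-vs-rest multiclass metrics from a confusion matrix
#'
#' Accuracy plus macro-averaged one-vs-rest precision, recall (sensitivity),
#' specificity and F1: each class in turn is treated as positive and the
#' other two as negative, the binary metric is computed from the resulting
#' TP/FP/FN/TN, and the three values are averaged. Ratios with a zero
#' denominator are defined as 0.
#'
#' @param confusion 3x3 count matrix (true in rows, predicted in columns).
#' @return List with `accuracy`, `precision`, `recall`, `specificity`,
#'   `f1` (macro), `perClass` (`data.frame` of the one-vs-rest values) and
#'   the `confusion` matrix.
#' @export
metricsFromConfusion <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(dim(confusion) != 3L) || any(confusion < 0))
    stop("confusion must be a non-negative 3x3 matrix", call. = FALSE)
  total <- sum(confusion)
  if (total == 0) stop("confusion matrix is all-zero", call. = FALSE)
  per <- lapply(1:3, function(i) {
    tp <- confusion[i, i]
    fn <- sum(confusion[i, ]) - tp
    fp <- sum(confusion[, i]) - tp
    tn <- total - tp - fn - fp
    prec <- .safeRatio(tp, tp + fp)
    rec <- .safeRatio(tp, tp + fn)
    spec <- .safeRatio(tn, tn + fp)
    f1 <- .safeRatio(2 * prec * rec, prec + rec)
    data.frame(class = diagnosisLevels()[i], precision = prec, recall = rec,
               specificity = spec, f1 = f1, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(accuracy = sum(diag(confusion)) / total,
       precision = mean(per$precision),
       recall = mean(per$recall),
       specificity = mean(per$specificity),
       f1 = mean(per$f1),
       perClass = per,
       confusion = confusion)
}

# Shared scoring path for DL runs and raters: one row of macro metrics per
# (id, level) group of a long label table.
.scoreLabelTable <- function(df, idCol) {
  rows <- list()
  for (id in unique(df[[idCol]])) {
    for (lv in unique(df$level)) {
      sel <- df[[idCol]] == id & df$level == lv
      if (!any(sel)) next
      m <- metricsFromConfusion(
        confusionMatrix3(df$true_label[sel], df$pred_label[sel]))
      rows[[length(rows) + 1L]] <- data.frame(
        id = id, level = lv, accuracy = m$accuracy, precision = m$precision,
        recall = m$recall, specificity = m$specificity, f1 = m$f1,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  names(out)[1] <- idCol
  out
}

#' Per-run metrics from a nested-CV prediction table
#'
#' @param predictions Output of [runNestedCV()].
#' @return `data.frame`: one row per (run_id, level) with accuracy and the
#'   macro one-vs-rest metrics.
#' @export
evaluateRuns <- function(predictions) {
  .scoreLabelTable(predictions, "run_id")
}

#' Per-rater metrics from a rater panel
#'
#' Uses exactly the same scoring path as [evaluateRuns()], so physician
#' and model scores are directly comparable.
#'
#' @param panel A [RaterPanel-class].
#' @return `data.frame`: one row per (rater_id, level).
#' @export
evaluateRaters <- function(panel) {
  stopifnot(is(panel, "RaterPanel"))
  df <- raterLabels(panel)
  df$level <- ifelse(df$item_type == "signal", "signal", "patient")
  df$pred_label <- df$label
  .scoreLabelTable(df, "rater_id")
}

#' One-vs-rest ROC and precision-recall curve points
#'
#' For each class, the class probability is swept over every observed
#' score as the decision threshold (predict positive when score >=
#' threshold). ROC points run from (0, 0) to (1, 1); PR points start at
#' (0, 1) by the usual convention that precision is 1 when nothing is
#' predicted positive. A class absent from (or filling all of) the truth
#' vector has no defined curve and is flagged.
#'
#' @param trueLabels Label vector.
#' @param probs n x 3 probability matrix (columns M, N, NL).
#' @return `data.frame` with columns `class`, `curve` (`"roc"`/`"pr"`),
#'   `threshold`, `x`, `y`; attribute `undefined` lists classes without a
#'   curve.
#' @export
rocPrCurves <- function(trueLabels, probs) {
  probs <- rbind(probs)
  y <- diagnosisFactor(trueLabels)
  stopifnot(nrow(probs) == length(y), ncol(probs) == 3L)
  out <- list(); undef <- character()
  for (i in 1:3) {
    cls <- diagnosisLevels()[i]
    pos <- y == cls
    if (!any(pos) || all(pos)) {
      undef <- c(undef, cls)
      next
    }
    sc <- probs[, i]
    thr <- sort(unique(sc), decreasing = TRUE)
    P <- sum(pos); Nn <- sum(!pos)
    roc <- data.frame(class = cls, curve = "roc", threshold = Inf,
                      x = 0, y = 0, stringsAsFactors = FALSE)
    pr <- data.frame(class = cls, curve = "pr", threshold = Inf,
                     x = 0, y = 1, stringsAsFactors = FALSE)
    for (t in thr) {
      pred <- sc >= t
      tp <- sum(pred & pos); fp <- sum(pred & !pos)
      roc <- rbind(roc, data.frame(class = cls, curve = "roc",
                                   threshold = t, x = fp / Nn, y = tp / P,
                                   stringsAsFactors = FALSE))
      prec <- if (tp + fp == 0) 1 else tp / (tp + fp)
      pr <- rbind(pr, data.frame(class = cls, curve = "pr", threshold = t,
                                 x = tp / P, y = prec,
                                 stringsAsFactors = FALSE))
    }
    out[[length(out) + 1L]] <- rbind(roc, pr)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(class = character(), curve = character(),
               threshold = numeric(), x = numeric(), y = numeric())
  rownames(res) <- NULL
  attr(res, "undefined") <- undef
  res
}

#' Compare two score sets with an exact rank test
#'
#' Reports median and quartiles per set and a two-sided Mann-Whitney U
#' p-value: exact (full enumeration of rank splits) whenever there are no
#' ties and both sides have fewer than 50 observations, otherwise the
#' normal approximation with continuity correction.
#'
#' @param scoresA,scoresB Numeric score vectors (e.g. per-run and
#'   per-rater accuracies).
#' @return List with `medianA`, `q1A`, `q3A`, `medianB`, `q1B`, `q3B`,
#'   `U`, `pValue`, `exact`.
#' @export
#' @examples
#' compareScoreSets(c(1, 2, 3), c(4, 5, 6))$pValue  # exactly 0.1
compareScoreSets <- function(scoresA, scoresB) {
  if (!length(scoresA) || !length(scoresB))
    stop("both score sets must be non-empty", call. = FALSE)
  qa <- quantile(scoresA, c(.25, .5, .75), names = FALSE)
  qb <- quantile(scoresB, c(.25, .5, .75), names = FALSE)
  exact <- !anyDuplicated(c(scoresA, scoresB)) &&
    length(scoresA) < 50 && length(scoresB) < 50
  wt <- suppressWarnings(wilcox.test(scoresA, scoresB, exact = exact,
                                     correct = TRUE))
  list(medianA = qa[2], q1A = qa[1], q3A = qa[3],
       medianB = qb[2], q1B = qb[1], q3B = qb[3],
       U = unname(wt$statistic), pValue = wt$p.value, exact = exact)
}

#' Write an evaluation results directory
#'
#' Writes `predictions.csv`, `metrics.csv`, `curves.csv` and
#' `comparison.json` under `directory`.
#'
#' @param predictions Output of [runNestedCV()].
#' @param metrics Output of [evaluateRuns()] (optionally rbind-ed with
#'   rater metrics).
#' @param curves Output of [rocPrCurves()], or `NULL`.
#' @param comparison Output of [compareScoreSets()], or `NULL`.
#' @param directory Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeResults <- function(predictions, metrics, curves = NULL,
                         comparison = NULL, directory = ".") {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  write.csv(predictions, file.path(directory, "predictions.csv"),
            row.names = FALSE)
  write.csv(metrics, file.path(directory, "metrics.csv"), row.names = FALSE)
  if (!is.null(curves))
    write.csv(curves, file.path(directory, "curves.csv"), row.names = FALSE)
  if (!is.null(comparison))
    jsonlite::write_json(comparison, file.path(directory, "comparison.json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(directory)
}
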
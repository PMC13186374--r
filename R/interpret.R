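# Consensus and failure analysis between the model ensemble and the rater
# panel, plus activation-maximization prototypes of what the trained
# network considers most typical of each class.

.consensusThresholds <- c(dl = 8L, raters = 5L)
.consensusColumns <- c(dl = 9L, raters = 6L)

#' Highly consistent consensus labels
#'
#' An item receives a consensus label when at least `threshold` of the
#' available labels agree: 8 of the 9 model runs, or 5 of the 6 raters.
#' Items with missing labels are skipped with a warning.
#'
#' @param labelTable Matrix or `data.frame` of labels, items in rows
#'   (rownames are the item ids), one column per run or rater.
#' @param source `"dl"` or `"raters"`; fixes the required column count and
#'   the default threshold.
#' @param threshold Override the agreement threshold.
#' @return `data.frame` with `item_id`, `source`, `label` (`NA` when no
#'   consensus), `agreeing` (modal count), `total`.
#' @export
consensusLabels <- function(labelTable, source = c("dl", "raters"),
                            threshold = NULL) {
  source <- match.arg(source)
  m <- as.matrix(labelTable)
  if (ncol(m) != .consensusColumns[[source]])
    stop("a complete ", source, " label table has ",
         .consensusColumns[[source]], " columns, got ", ncol(m),
         call. = FALSE)
  if (is.null(threshold)) threshold <- .consensusThresholds[[source]]
  ids <- rownames(m)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(m)))
  keep <- !apply(m, 1, anyNA)
  if (any(!keep))
    warning(sum(!keep), " item(s) with missing labels skipped",
            call. = FALSE)
  rows <- lapply(which(keep), function(i) {
    tab <- table(factor(m[i, ], levels = diagnosisLevels()))
    top <- max(tab)
    # a tied modal count never yields a consensus label
    lab <- if (top >= threshold && sum(tab == top) == 1L)
      names(tab)[which.max(tab)] else NA_character_
    data.frame(item_id = ids[i], source = source, label = lab,
               agreeing = as.integer(top), total = ncol(m),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cross-failure tables between model consensus and rater consensus
#'
#' Over the items holding a consensus label from both sources: table
#' `dlCorrectRaterWrong` counts items the model consensus classified
#' correctly and the rater consensus did not, broken down by (true class,
#' rater label); `raterCorrectDlWrong` is the converse, broken down by
#' (true class, model label).
#'
#' @param dlConsensus,raterConsensus Outputs of [consensusLabels()].
#' @param truth Named vector mapping item ids to true labels.
#' @return List of two 3x3 count matrices.
#' @export
crossFailureTable <- function(dlConsensus, raterConsensus, truth) {
  both <- merge(dlConsensus[!is.na(dlConsensus$label),
                            c("item_id", "label")],
                raterConsensus[!is.na(raterConsensus$label),
                               c("item_id", "label")],
                by = "item_id", suffixes = c("_dl", "_rater"))
  both$true <- unname(truth[both$item_id])
  if (anyNA(both$true))
    stop("truth is missing for item(s): ",
         paste(head(both$item_id[is.na(both$true)], 3), collapse = ", "),
         call. = FALSE)
  lev <- diagnosisLevels()
  empty <- matrix(0L, 3, 3, dimnames = list(true = lev, label = lev))
  tabA <- tabB <- empty
  selA <- both$label_dl == both$true & both$label_rater != both$true
  selB <- both$label_rater == both$true & both$label_dl != both$true
  if (any(selA)) {
    t <- table(factor(both$true[selA], lev),
               factor(both$label_rater[selA], lev))
    tabA[] <- as.integer(t)
  }
  if (any(selB)) {
    t <- table(factor(both$true[selB], lev),
               factor(both$label_dl[selB], lev))
    tabB[] <- as.integer(t)
  }
  list(dlCorrectRaterWrong = tabA, raterCorrectDlWrong = tabB,
       nDualConsensus = nrow(both))
}

#' Activation-maximization class prototype
#'
#' Synthesizes the input waveform the trained network scores highest for
#' a target class: gradient ascent on the pre-softmax class score from a
#' small-noise initialization, regularized by a squared-first-difference
#' smoothness penalty (nEMG prototypes should stay band-limited
#' plausible). Steps are improvement-gated: a candidate step is accepted
#' only if it does not decrease the objective, otherwise the step size is
#' halved, so the objective trace is non-decreasing.
#'
#' @param model A trained [EMGNet-class].
#' @param targetClass `"M"`, `"N"` or `"NL"`.
#' @param steps Number of gradient steps.
#' @param stepSize Initial step size.
#' @param smoothnessWeight Weight of the squared first-difference penalty.
#' @param initSd Standard deviation of the noise initialization.
#' @param seed Seed for the initialization.
#' @return A [ClassPrototype-class].
#' @export
featureVisualization <- function(model, targetClass, steps = 200,
                                 stepSize = 1, smoothnessWeight = 1e-3,
                                 initSd = 0.01, seed = 1) {
  stopifnot(is(model, "EMGNet"))
  ci <- match(targetClass, diagnosisLevels())
  if (is.na(ci)) stop("targetClass must be M, N or NL", call. = FALSE)
  cfg <- model@config
  L <- cfg$inputLength
  x <- withSeed(seed, rnorm(L, sd = initSd))
  onehot <- matrix(0, 1, cfg$nClasses); onehot[1, ci] <- 1

  evalPoint <- function(x) {
    fw <- .forward(model@params, cfg, matrix(x, ncol = 1))
    obj <- fw$logits[1, ci] - smoothnessWeight * sum(diff(x)^2)
    list(obj = obj, prob = fw$probs[1, ci], cache = fw$cache)
  }
  # d/dx of sum(diff(x)^2) is 2*(c(0,d) - c(d,0)) with d = diff(x)
  cur <- evalPoint(x)
  initialProb <- cur$prob
  trace <- cur$obj
  eta <- stepSize
  if (steps > 0) {
    for (s in seq_len(steps)) {
      d <- diff(x)
      gSmooth <- 2 * (c(0, d) - c(d, 0))
      gx <- .backward(model@params, cfg, cur$cache, onehot)$dInput[, 1] -
        smoothnessWeight * gSmooth
      cand <- x + eta * gx
      nxt <- evalPoint(cand)
      if (nxt$obj >= cur$obj) {
        x <- cand; cur <- nxt
        eta <- eta * 1.1
      } else {
        eta <- eta / 2
      }
      trace <- c(trace, cur$obj)
    }
  }
  if (steps > 0 && cur$prob <= initialProb)
    warning("prototype did not raise the target-class probability; ",
            "the model may be untrained or degenerate", call. = FALSE)
  new("ClassPrototype", targetClass = targetClass, waveform = x,
      trace = trace, initialProb = initialProb, finalProb = cur$prob)
}

#' Write a prototype waveform and its objective trace
#'
#' @param prototype A [ClassPrototype-class].
#' @param directory Output directory.
#' @param fs Working sampling rate of the waveform (Hz).
#' @return The directory, invisibly.
#' @export
writePrototype <- function(prototype, directory = ".", fs = 10000) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  base <- paste0("prototype_", prototype@targetClass)
  .writeWave(prototype@waveform, fs, file.path(directory,
                                               paste0(base, ".wav")))
  write.csv(data.frame(step = seq_along(prototype@trace) - 1L,
                       objective = prototype@trace),
            file.path(directory, paste0(base, "_trace.csv")),
            row.names = FALSE)
  invisible(directory)
}
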
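#' @import methods
#' @importFrom stats rnorm runif rgamma quantile wilcox.test sd
#' @importFrom utils read.csv write.csv head
#' @useDynLib emgdx, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Diagnosis classes
#'
#' The three diagnosis labels used throughout the package, in their fixed
#' order: `"M"` (myopathy), `"N"` (neuropathy), `"NL"` (normal). Integer
#' codes 0/1/2 follow this order everywhere downstream.
#'
#' @return Character vector `c("M", "N", "NL")`.
#' @export
#' @examples
#' diagnosisLevels()
diagnosisLevels <- function() c("M", "N", "NL")

.checkDiagnosis <- function(x) {
  bad <- !x %in% diagnosisLevels()
  if (any(bad)) {
    stop("invalid diagnosis label(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (expected M, N or NL)", call. = FALSE)
  }
  invisible(x)
}

#' Coerce labels to the canonical diagnosis factor
#'
#' @param x Character or factor vector of labels.
#' @return Factor with levels `M`, `N`, `NL`.
#' @export
diagnosisFactor <- function(x) {
  x <- as.character(x)
  .checkDiagnosis(x)
  factor(x, levels = diagnosisLevels())
}

#' EMGSignal: a single needle-EMG waveform
#'
#' One mono nEMG recording in microvolts, linked to a patient and carrying
#' the patient's diagnosis label.
#'
#' @slot signalId Unique signal identifier.
#' @slot patientId Identifier of the patient the signal belongs to.
#' @slot diagnosis One of `"M"`, `"N"`, `"NL"`.
#' @slot muscle Free-text muscle label.
#' @slot fs Sampling rate in Hz.
#' @slot samples Numeric waveform in microvolts.
#' @slot drive Voluntary-contraction level in `[0, 1]` used when the signal
#'   was simulated (`NA` for signals of unknown provenance).
#'
#' @export
setClass("EMGSignal",
  representation(signalId = "character", patientId = "character",
                 diagnosis = "character", muscle = "character",
                 fs = "numeric", samples = "numeric", drive = "numeric"),
  prototype(muscle = "unknown", drive = NA_real_))

setValidity("EMGSignal", function(object) {
  msg <- character()
  if (length(object@signalId) != 1L || !nzchar(object@signalId))
    msg <- c(msg, "signalId must be a single non-empty string")
  if (!object@diagnosis %in% diagnosisLevels())
    msg <- c(msg, "diagnosis must be one of M, N, NL")
  if (length(object@fs) != 1L || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' EMGCohort: a set of patients with their nEMG signals
#'
#' @slot signals List of [EMGSignal-class] objects.
#' @slot metadata List of free-form provenance information (seed,
#'   physiology used, ...).
#'
#' @export
setClass("EMGCohort",
  representation(signals = "list", metadata = "list"),
  prototype(metadata = list()))

setValidity("EMGCohort", function(object) {
  msg <- character()
  if (!all(vapply(object@signals, is, logical(1), "EMGSignal")))
    return("all elements of signals must be EMGSignal objects")
  ids <- vapply(object@signals, function(s) s@signalId, character(1))
  if (anyDuplicated(ids))
    msg <- c(msg, paste0("duplicate signal_id: ",
                         paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  pid <- vapply(object@signals, function(s) s@patientId, character(1))
  dx <- vapply(object@signals, function(s) s@diagnosis, character(1))
  ndx <- tapply(dx, pid, function(d) length(unique(d)))
  if (any(ndx > 1))
    msg <- c(msg, paste0("patients with conflicting diagnosis labels: ",
                         paste(names(ndx)[ndx > 1], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' RaterPanel: simulated physician labels for a cohort
#'
#' @slot nRaters Number of raters.
#' @slot confusion List of per-rater 3x3 row-stochastic confusion matrices
#'   (true class in rows, assigned class in columns, order M/N/NL).
#' @slot labels `data.frame` with columns `rater_id`, `item_type`
#'   (`"signal"` or `"patient"`), `item_id`, `true_label`, `label`.
#'
#' @export
setClass("RaterPanel",
  representation(nRaters = "integer", confusion = "list",
                 labels = "data.frame"))

setValidity("RaterPanel", function(object) {
  msg <- character()
  for (cm in object@confusion) {
    if (!is.matrix(cm) || any(dim(cm) != 3L) || any(cm < 0) ||
        any(abs(rowSums(cm) - 1) > 1e-8))
      msg <- c(msg, "each confusion matrix must be 3x3 row-stochastic")
  }
  need <- c("rater_id", "item_type", "item_id", "true_label", "label")
  if (!all(need %in% names(object@labels)))
    msg <- c(msg, paste("labels must have columns:",
                        paste(need, collapse = ", ")))
  if (length(msg)) unique(msg) else TRUE
})

#' FoldPlan: nested cross-validation partition at the patient level
#'
#' @slot outer Named integer vector mapping each patient to an outer fold.
#' @slot inner List (one element per outer fold) of named integer vectors
#'   mapping the remaining patients to inner folds.
#' @slot nOuter,nInner Fold counts.
#' @slot seed Seed the plan was built from.
#'
#' @export
setClass("FoldPlan",
  representation(outer = "integer", inner = "list",
                 nOuter = "integer", nInner = "integer", seed = "integer"))

setValidity("FoldPlan", function(object) {
  msg <- character()
  if (!all(object@outer %in% seq_len(object@nOuter)))
    msg <- c(msg, "outer assignments out of range")
  if (length(object@inner) != object@nOuter)
    msg <- c(msg, "inner must have one element per outer fold")
  for (k in seq_along(object@inner)) {
    rest <- names(object@outer)[object@outer != k]
    if (!setequal(names(object@inner[[k]]), rest))
      msg <- c(msg, sprintf("inner folds of outer fold %d do not partition the remaining patients", k))
  }
  if (length(msg)) msg else TRUE
})

#' EMGNet: a compact 1-D residual network over 0.4-s segments
#'
#' Weights are held as a flat named list of numeric arrays; `config` is the
#' list returned by [emgNetConfig()]. `history` records the training curve
#' (update index, smoothed training loss, validation accuracy).
#'
#' @slot config Model configuration list.
#' @slot params Named list of weight arrays.
#' @slot history `data.frame` training history.
#' @slot bestUpdate Update index of the restored best checkpoint.
#' @slot trained Logical.
#'
#' @export
setClass("EMGNet",
  representation(config = "list", params = "list", history = "data.frame",
                 bestUpdate = "integer", trained = "logical"),
  prototype(history = data.frame(), bestUpdate = NA_integer_,
            trained = FALSE))

#' VoteResult: one divide-and-vote decision
#'
#' @slot itemId Signal or patient identifier.
#' @slot patientId Patient the item belongs to.
#' @slot level `"signal"` or `"patient"`.
#' @slot label Winning diagnosis label.
#' @slot voteCounts Named 3-vector of votes per class.
#' @slot meanProbs Named 3-vector of mean class probabilities.
#' @slot tieBroken Whether the probability tie-break was used.
#'
#' @export
setClass("VoteResult",
  representation(itemId = "character", patientId = "character",
                 level = "character", label = "character",
                 voteCounts = "numeric", meanProbs = "numeric",
                 tieBroken = "logical"))

#' ClassPrototype: an activation-maximization waveform
#'
#' @slot targetClass Diagnosis class the prototype maximizes.
#' @slot waveform Optimized 0.4-s input at the working rate.
#' @slot trace Objective value after initialization and after each step
#'   (non-decreasing: rejected steps repeat the previous value).
#' @slot initialProb,finalProb Target-class probability before/after.
#'
#' @export
setClass("ClassPrototype",
  representation(targetClass = "character", waveform = "numeric",
                 trace = "numeric", initialProb = "numeric",
                 finalProb = "numeric"))
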
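#' @rdname EMGSignal-class
#' @param object An object.
#' @export
setGeneric("signalId", function(object) standardGeneric("signalId"))
#' @rdname EMGSignal-class
#' @export
setGeneric("patientId", function(object) standardGeneric("patientId"))
#' @rdname EMGSignal-class
#' @export
setGeneric("diagnosis", function(object) standardGeneric("diagnosis"))
#' @rdname EMGSignal-class
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))
#' @rdname EMGSignal-class
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' @rdname EMGCohort-class
#' @param object An object.
#' @export
setGeneric("nSignals", function(object) standardGeneric("nSignals"))
#' @rdname EMGCohort-class
#' @export
setGeneric("nPatients", function(object) standardGeneric("nPatients"))
#' @rdname EMGCohort-class
#' @export
setGeneric("patientTable", function(object) standardGeneric("patientTable"))
#' @rdname EMGCohort-class
#' @export
setGeneric("signalTable", function(object) standardGeneric("signalTable"))
#' @rdname EMGCohort-class
#' @export
setGeneric("cohortSignals", function(object) standardGeneric("cohortSignals"))

#' @rdname RaterPanel-class
#' @param object An object.
#' @export
setGeneric("raterLabels", function(object) standardGeneric("raterLabels"))
#' @rdname RaterPanel-class
#' @export
setGeneric("nRaters", function(object) standardGeneric("nRaters"))

#' @rdname EMGNet-class
#' @param object An object.
#' @export
setGeneric("nParams", function(object) standardGeneric("nParams"))
#' @rdname EMGNet-class
#' @export
setGeneric("trainingHistory", function(object) standardGeneric("trainingHistory"))

setMethod("signalId", "EMGSignal", function(object) object@signalId)
setMethod("patientId", "EMGSignal", function(object) object@patientId)
setMethod("diagnosis", "EMGSignal", function(object) object@diagnosis)
setMethod("samplingRate", "EMGSignal", function(object) object@fs)
setMethod("samples", "EMGSignal", function(object) object@samples)

#' Duration of a signal in seconds
#' @param object An [EMGSignal-class].
#' @return Numeric duration in seconds.
#' @export
signalDuration <- function(object) {
  stopifnot(is(object, "EMGSignal"))
  length(object@samples) / object@fs
}

setMethod("show", "EMGSignal", function(object) {
  cat(sprintf("EMGSignal %s (patient %s, %s, %s): %.3f s at %g Hz\n",
              object@signalId, object@patientId, object@diagnosis,
              object@muscle, signalDuration(object), object@fs))
})

setMethod("cohortSignals", "EMGCohort", function(object) object@signals)
setMethod("nSignals", "EMGCohort", function(object) length(object@signals))
setMethod("nPatients", "EMGCohort", function(object)
  length(unique(vapply(object@signals, patientId, character(1)))))

setMethod("signalTable", "EMGCohort", function(object) {
  data.frame(
    patient_id = vapply(object@signals, patientId, character(1)),
    signal_id = vapply(object@signals, signalId, character(1)),
    diagnosis = vapply(object@signals, diagnosis, character(1)),
    muscle = vapply(object@signals, function(s) s@muscle, character(1)),
    fs = vapply(object@signals, samplingRate, numeric(1)),
    n_samples = vapply(object@signals, function(s) length(s@samples),
                       integer(1)),
    duration = vapply(object@signals, signalDuration, numeric(1)),
    drive = vapply(object@signals, function(s) s@drive, numeric(1)),
    stringsAsFactors = FALSE)
})

setMethod("patientTable", "EMGCohort", function(object) {
  st <- signalTable(object)
  agg <- aggregate(st["signal_id"], by = st[c("patient_id", "diagnosis")],
                   FUN = length)
  names(agg)[3] <- "n_signals"
  agg[order(agg$patient_id), , drop = FALSE]
})

setMethod("show", "EMGCohort", function(object) {
  st <- signalTable(object)
  tab <- table(patientTable(object)$diagnosis)
  cat(sprintf("EMGCohort: %d patients (%s), %d signals, %.1f s total\n",
              nPatients(object),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              nSignals(object), sum(st$duration)))
})

setMethod("raterLabels", "RaterPanel", function(object) object@labels)
setMethod("nRaters", "RaterPanel", function(object) object@nRaters)

setMethod("show", "RaterPanel", function(object) {
  cat(sprintf("RaterPanel: %d raters, %d signal labels, %d patient labels\n",
              object@nRaters,
              sum(object@labels$item_type == "signal"),
              sum(object@labels$item_type == "patient")))
})

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d patients, %d outer x %d inner folds (seed %d)\n",
              length(object@outer), object@nOuter, object@nInner,
              object@seed))
  print(table(outer = object@outer))
})

setMethod("nParams", "EMGNet", function(object)
  sum(vapply(object@params, length, integer(1))))
setMethod("trainingHistory", "EMGNet", function(object) object@history)

setMethod("show", "EMGNet", function(object) {
  cfg <- object@config
  cat(sprintf("EMGNet: %d residual block(s), channels %s, kernel %d, input %d\n",
              cfg$nBlocks, paste(cfg$channels, collapse = "->"),
              cfg$kernel, cfg$inputLength))
  cat(sprintf("  %d parameters; %s\n", nParams(object),
              if (object@trained)
                sprintf("trained (best checkpoint at update %d)",
                        object@bestUpdate)
              else "untrained"))
})

setMethod("show", "VoteResult", function(object) {
  cat(sprintf("VoteResult [%s] %s -> %s (votes %s%s)\n", object@level,
              object@itemId, object@label,
              paste(sprintf("%s:%g", names(object@voteCounts),
                            object@voteCounts), collapse = " "),
              if (object@tieBroken) ", tie broken" else ""))
})

setMethod("show", "ClassPrototype", function(object) {
  cat(sprintf("ClassPrototype for %s: p %.3f -> %.3f over %d accepted-state trace points\n",
              object@targetClass, object@initialProb, object@finalProb,
              length(object@trace)))
})
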
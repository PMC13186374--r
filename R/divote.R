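# Divide-and-vote: each 0.4-s segment casts one argmax vote for its
# signal; each signal casts one vote for its patient (signals weigh
# equally regardless of duration or segment count). Ties are broken by
# the summed probability mass over the tied classes.

.majorityVote <- function(votes, probRows) {
  lev <- diagnosisLevels()
  counts <- tabulate(votes, nbins = 3L)
  names(counts) <- lev
  meanProbs <- colMeans(probRows)
  names(meanProbs) <- lev
  top <- which(counts == max(counts))
  if (length(top) == 1L) {
    list(label = lev[top], counts = counts, meanProbs = meanProbs,
         tie = FALSE)
  } else {
    mass <- colSums(probRows[, top, drop = FALSE])
    list(label = lev[top[which.max(mass)]], counts = counts,
         meanProbs = meanProbs, tie = TRUE)
  }
}

#' Signal diagnosis by segment majority vote
#'
#' Each segment casts one vote for its argmax class; the majority label
#' wins. A tied vote count is broken in favour of the tied class with the
#' larger summed probability over the signal's segments.
#'
#' @param segmentProbs n x 3 matrix of segment class probabilities
#'   (columns M, N, NL).
#' @param itemId Signal identifier.
#' @param patientId Patient the signal belongs to.
#' @return A [VoteResult-class] at level `"signal"`.
#' @export
#' @examples
#' p <- rbind(c(.6, .3, .1), c(.1, .8, .1))
#' voteSignal(p)  # N by tie-break: summed mass .7 vs 1.1
voteSignal <- function(segmentProbs, itemId = "signal",
                       patientId = NA_character_) {
  segmentProbs <- rbind(segmentProbs)
  if (nrow(segmentProbs) == 0L)
    stop("voteSignal requires at least one segment", call. = FALSE)
  if (ncol(segmentProbs) != 3L)
    stop("segmentProbs must have 3 columns (M, N, NL)", call. = FALSE)
  votes <- max.col(segmentProbs, ties.method = "first")
  v <- .majorityVote(votes, segmentProbs)
  new("VoteResult", itemId = itemId, patientId = patientId,
      level = "signal", label = v$label, voteCounts = v$counts,
      meanProbs = v$meanProbs, tieBroken = v$tie)
}

#' Patient diagnosis by signal majority vote
#'
#' One vote per signal, regardless of each signal's duration or segment
#' count; the same tie rule as [voteSignal()], applied to the signal-level
#' mean probabilities.
#'
#' @param signalVotes List of signal-level [VoteResult-class] objects for
#'   one patient.
#' @return A [VoteResult-class] at level `"patient"`.
#' @export
votePatient <- function(signalVotes) {
  if (!length(signalVotes))
    stop("votePatient requires at least one signal vote", call. = FALSE)
  if (!all(vapply(signalVotes, function(v) v@level == "signal", logical(1))))
    stop("all inputs must be signal-level votes", call. = FALSE)
  pids <- unique(vapply(signalVotes, function(v) v@patientId, character(1)))
  if (length(pids) != 1L)
    stop("signal votes mix patients: ", paste(pids, collapse = ", "),
         call. = FALSE)
  lev <- diagnosisLevels()
  votes <- match(vapply(signalVotes, function(v) v@label, character(1)), lev)
  probRows <- do.call(rbind, lapply(signalVotes, function(v) v@meanProbs))
  v <- .majorityVote(votes, probRows)
  new("VoteResult", itemId = pids, patientId = pids, level = "patient",
      label = v$label, voteCounts = v$counts, meanProbs = v$meanProbs,
      tieBroken = v$tie)
}

.voteRow <- function(v, trueLabel) {
  data.frame(level = v@level, item_id = v@itemId, patient_id = v@patientId,
             true_label = trueLabel, pred_label = v@label,
             p_M = v@meanProbs[1], p_N = v@meanProbs[2],
             p_NL = v@meanProbs[3], tie_broken = v@tieBroken,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate segment probabilities to signal- and patient-level diagnoses
#'
#' Runs the full divide-and-vote chain over a prediction table. In the
#' default mode patients are diagnosed from one vote per signal; with
#' `patientPooled = TRUE` all of a patient's segments vote directly
#' (signals with more segments then weigh more), provided for comparison.
#'
#' @param probs n x 3 segment probability matrix.
#' @param signalIds,patientIds,trueLabels Per-segment annotation vectors.
#' @param patientPooled Pool segments across signals for the patient vote.
#' @return `data.frame` with one row per signal and per patient: columns
#'   `level`, `item_id`, `patient_id`, `true_label`, `pred_label`,
#'   `p_M`, `p_N`, `p_NL`, `tie_broken`.
#' @export
aggregatePredictions <- function(probs, signalIds, patientIds, trueLabels,
                                 patientPooled = FALSE) {
  probs <- rbind(probs)
  stopifnot(nrow(probs) == length(signalIds),
            length(signalIds) == length(patientIds),
            length(patientIds) == length(trueLabels))
  rows <- list()
  sigVotes <- list()
  for (sid in unique(signalIds)) {
    sel <- signalIds == sid
    v <- voteSignal(probs[sel, , drop = FALSE], itemId = sid,
                    patientId = patientIds[sel][1])
    sigVotes[[sid]] <- v
    rows[[length(rows) + 1L]] <- .voteRow(v, trueLabels[sel][1])
  }
  for (pid in unique(patientIds)) {
    sel <- patientIds == pid
    pv <- if (patientPooled) {
      v <- voteSignal(probs[sel, , drop = FALSE], itemId = pid,
                      patientId = pid)
      v@level <- "patient"
      v
    } else {
      votePatient(unname(sigVotes[unique(signalIds[sel])]))
    }
    rows[[length(rows) + 1L]] <- .voteRow(pv, trueLabels[sel][1])
  }
  do.call(rbind, rows)
}
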
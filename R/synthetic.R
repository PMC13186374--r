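#' Class-conditional MUAP physiology
#'
#' Parameter distributions for one diagnosis class: ranges for the motor
#' unit action potential (MUAP) amplitude and duration, motor unit pool
#' size, recruitment-threshold spread, firing rates, and the additive
#' band-limited noise level.
#'
#' The defaults in [defaultPhysiology()] encode the classic
#' electrodiagnostic picture: myopathic MUAPs are small and short with
#' early recruitment (many low-threshold units), neuropathic MUAPs are
#' large and long with reduced recruitment (few units, high thresholds),
#' normal muscle sits in between. Their only contract is that ordering;
#' every value is overridable.
#'
#' @param amplitude Range of MUAP peak-to-peak amplitudes, microvolts.
#' @param duration Range of MUAP durations, milliseconds.
#' @param poolSize Integer range of motor units per pool.
#' @param thresholdMax Upper end of the recruitment-threshold spread:
#'   thresholds are drawn uniformly on `[0, thresholdMax]`. Small values
#'   mean early recruitment.
#' @param firingRate Range of per-unit mean firing rates at full drive, Hz.
#' @param isiCv Coefficient of variation of inter-spike intervals.
#' @param nPhases Integer range of MUAP phase counts (>= 2).
#' @param noiseRms RMS of the additive 20 Hz - 10 kHz noise, microvolts.
#' @return A `ClassPhysiology` list.
#' @export
classPhysiology <- function(amplitude, duration, poolSize, thresholdMax,
                            firingRate = c(8, 20), isiCv = 0.15,
                            nPhases = c(2, 4), noiseRms = 10) {
  .assertRange(amplitude, "amplitude"); .assertRange(duration, "duration")
  .assertRange(poolSize, "poolSize"); .assertRange(firingRate, "firingRate")
  .assertRange(nPhases, "nPhases")
  if (amplitude[1] <= 0 || duration[1] <= 0)
    stop("amplitude and duration ranges must be positive", call. = FALSE)
  if (poolSize[1] < 1) stop("poolSize must be >= 1", call. = FALSE)
  if (nPhases[1] < 2) stop("nPhases must be >= 2", call. = FALSE)
  .assertScalarNum(thresholdMax, "thresholdMax")
  if (thresholdMax <= 0 || thresholdMax > 1)
    stop("thresholdMax must be in (0, 1]", call. = FALSE)
  .assertScalarNum(isiCv, "isiCv"); .assertScalarNum(noiseRms, "noiseRms")
  if (isiCv < 0 || noiseRms < 0)
    stop("isiCv and noiseRms must be non-negative", call. = FALSE)
  structure(list(amplitude = amplitude, duration = duration,
                 poolSize = poolSize, thresholdMax = thresholdMax,
                 firingRate = firingRate, isiCv = isiCv,
                 nPhases = nPhases, noiseRms = noiseRms),
            class = "ClassPhysiology")
}

#' Default per-class physiology
#'
#' @return Named list with elements `M`, `N`, `NL`, each a
#'   `ClassPhysiology`. Interval medians satisfy the amplitude and
#'   duration orderings M < NL < N and the recruitment-threshold spread
#'   ordering M < NL < N.
#' @export
#' @examples
#' defaultPhysiology()$M$amplitude
defaultPhysiology <- function() {
  list(
    M = classPhysiology(amplitude = c(100, 400), duration = c(3, 7),
                        poolSize = c(15, 25), thresholdMax = 0.30,
                        firingRate = c(10, 25)),
    N = classPhysiology(amplitude = c(800, 3000), duration = c(10, 20),
                        poolSize = c(4, 8), thresholdMax = 0.95,
                        firingRate = c(12, 30)),
    NL = classPhysiology(amplitude = c(300, 800), duration = c(6, 12),
                         poolSize = c(8, 15), thresholdMax = 0.65,
                         firingRate = c(8, 20))
  )
}

#' Class-indistinguishable physiology (negative control)
#'
#' All three classes share the stated physiology, so diagnosis labels
#' carry no waveform information. Used as a leakage guard: any classifier
#' evaluated under a patient-level split must fall to chance accuracy.
#'
#' @param base Which default class physiology to copy to all classes.
#' @return Named list with identical `M`, `N`, `NL` physiologies.
#' @export
collapsedPhysiology <- function(base = "NL") {
  p <- defaultPhysiology()[[match.arg(base, diagnosisLevels())]]
  list(M = p, N = p, NL = p)
}

#' Generate a MUAP template
#'
#' Builds a multiphasic waveform as a sum of alternating-sign Gaussian
#' lobes spread over the requested support, baseline-corrected to
#' integrate to zero (biphasic/triphasic charge balance) and rescaled to
#' the exact peak-to-peak amplitude. Lobe magnitudes are jittered from the
#' session RNG; set the seed for reproducibility.
#'
#' @param amplitude Peak-to-peak amplitude, microvolts.
#' @param duration Support duration, milliseconds.
#' @param nPhases Number of phases (>= 2).
#' @param fs Sampling rate, Hz (must exceed twice the 10 kHz recording
#'   band).
#' @return List with elements `amplitude`, `duration`, `nPhases`, `fs` and
#'   `waveform` (numeric vector of `round(duration / 1000 * fs)` samples,
#'   implicitly zero outside its support).
#' @export
#' @examples
#' set.seed(1)
#' tpl <- makeMuapTemplate(500, 10, 3, 48000)
#' length(tpl$waveform)  # 480 samples
makeMuapTemplate <- function(amplitude, duration, nPhases, fs) {
  .assertScalarNum(amplitude, "amplitude", positive = TRUE)
  .assertScalarNum(duration, "duration", positive = TRUE)
  .assertScalarNum(fs, "fs", positive = TRUE)
  if (nPhases < 2) stop("nPhases must be >= 2", call. = FALSE)
  if (fs <= 2 * 10000)
    stop("fs must exceed twice the 10 kHz recording band", call. = FALSE)
  n <- max(4L, as.integer(round(duration / 1000 * fs)))
  t <- (seq_len(n) - 0.5) / n                       # in (0, 1)
  centres <- (seq_len(nPhases) - 0.5) / nPhases
  sigma <- 1 / (5 * nPhases)
  mags <- runif(nPhases, 0.7, 1.3) *
    exp(-((centres - 0.5)^2) / (2 * 0.18^2))        # central lobes dominate
  w <- numeric(n)
  for (i in seq_len(nPhases)) {
    w <- w + (-1)^(i - 1) * mags[i] *
      exp(-((t - centres[i])^2) / (2 * sigma^2))
  }
  # smooth edges, then remove the net area with a broad positive envelope
  # so the template integrates to zero without losing its support
  taper <- 0.5 * (1 - cos(2 * pi * pmin(t, 1 - t) / 0.25))
  taper[t > 0.125 & t < 0.875] <- 1
  w <- w * taper
  env <- exp(-((t - 0.5)^2) / (2 * 0.22^2)) * taper
  w <- w - sum(w) / sum(env) * env
  w <- w * (amplitude / (max(w) - min(w)))
  list(amplitude = amplitude, duration = duration, nPhases = as.integer(nPhases),
       fs = fs, waveform = w)
}

#' Sample a motor unit pool
#'
#' Draws a pool of motor units for one signal from the class physiology:
#' pool size, per-unit MUAP template (amplitude, duration, phase count),
#' recruitment threshold uniform on `[0, thresholdMax]`, and firing
#' statistics. Uses the session RNG.
#'
#' @param physiology Named list of `ClassPhysiology` (as from
#'   [defaultPhysiology()]), or a single `ClassPhysiology`.
#' @param diagnosis Diagnosis class selecting the physiology
#'   (ignored when `physiology` is a single `ClassPhysiology`).
#' @param fs Simulator sampling rate, Hz.
#' @return List of motor units, each a list with `template`, `threshold`,
#'   `rate`, `isiCv`.
#' @export
sampleMotorUnitPool <- function(physiology, diagnosis, fs) {
  phys <- if (inherits(physiology, "ClassPhysiology")) physiology
          else physiology[[.checkDiagnosis(diagnosis)]]
  if (is.null(phys)) stop("no physiology for class ", diagnosis, call. = FALSE)
  nUnits <- if (phys$poolSize[1] == phys$poolSize[2]) as.integer(phys$poolSize[1])
            else sample(phys$poolSize[1]:phys$poolSize[2], 1L)
  lapply(seq_len(nUnits), function(i) {
    amp <- runif(1, phys$amplitude[1], phys$amplitude[2])
    dur <- runif(1, phys$duration[1], phys$duration[2])
    nph <- if (phys$nPhases[1] == phys$nPhases[2]) as.integer(phys$nPhases[1])
           else sample(phys$nPhases[1]:phys$nPhases[2], 1L)
    list(template = makeMuapTemplate(amp, dur, nph, fs),
         threshold = runif(1, 0, phys$thresholdMax),
         rate = runif(1, phys$firingRate[1], phys$firingRate[2]),
         isiCv = phys$isiCv)
  })
}

# Gaussian noise band-limited to the recording filter (20 Hz - 10 kHz),
# rescaled to the requested RMS after filtering.
.bandlimitedNoise <- function(n, fs, rms) {
  if (rms <= 0 || n == 0) return(numeric(n))
  lo <- 20 / (fs / 2)
  hi <- min(10000 / (fs / 2), 0.99)
  bf <- signal::butter(4, c(lo, hi), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  x * (rms / sd(x))
}

# Spike onset times (seconds) of a renewal process with gamma ISIs.
.renewalSpikes <- function(rate, isiCv, duration) {
  if (rate <= 0) return(numeric(0))
  meanIsi <- 1 / rate
  drawIsi <- function(k) {
    if (isiCv <= 0) rep(meanIsi, k)
    else rgamma(k, shape = 1 / isiCv^2, scale = meanIsi * isiCv^2)
  }
  t0 <- runif(1, 0, meanIsi)
  times <- t0
  while (tail(times, 1) < duration) {
    times <- c(times, tail(times, 1) + cumsum(drawIsi(
      max(8L, ceiling((duration - tail(times, 1)) * rate * 1.5)))))
  }
  times[times < duration]
}

#' Render a needle-EMG signal from a motor unit pool
#'
#' Units whose recruitment threshold does not exceed the voluntary drive
#' fire as independent renewal processes (gamma inter-spike intervals,
#' mean rate scaled by drive); their MUAP templates are summed at the
#' spike onsets and band-limited Gaussian noise (20 Hz - 10 kHz) of the
#' stated RMS is added. Uses the session RNG.
#'
#' @param pool Motor unit pool from [sampleMotorUnitPool()].
#' @param drive Contraction level in `[0, 1]` (models minimal to maximal
#'   voluntary contraction).
#' @param duration Signal duration, seconds.
#' @param fs Sampling rate, Hz.
#' @param noiseRms Additive noise RMS, microvolts.
#' @param signalId,patientId,diagnosis,muscle Metadata for the returned
#'   [EMGSignal-class].
#' @return An [EMGSignal-class] in microvolts.
#' @export
renderSignal <- function(pool, drive, duration, fs, noiseRms = 0,
                         signalId = "sig", patientId = "pat",
                         diagnosis = "NL", muscle = "unknown") {
  .assertScalarNum(duration, "duration", positive = TRUE)
  .assertScalarNum(fs, "fs", positive = TRUE)
  if (drive < 0 || drive > 1) stop("drive must be in [0, 1]", call. = FALSE)
  maxDur <- max(c(0, vapply(pool, function(u) u$template$duration,
                            numeric(1))))
  if (length(pool) && fs <= 2 * 10000)
    stop("fs below the Nyquist requirement of the 10 kHz template band",
         call. = FALSE)
  n <- as.integer(round(duration * fs))
  x <- numeric(n)
  for (u in pool) {
    if (u$threshold > drive) next
    w <- u$template$waveform
    for (t0 in .renewalSpikes(u$rate * drive, u$isiCv, duration)) {
      i0 <- as.integer(floor(t0 * fs)) + 1L
      i1 <- min(n, i0 + length(w) - 1L)
      if (i0 <= n)
        x[i0:i1] <- x[i0:i1] + w[seq_len(i1 - i0 + 1L)]
    }
  }
  x <- x + .bandlimitedNoise(n, fs, noiseRms)
  new("EMGSignal", signalId = signalId, patientId = patientId,
      diagnosis = diagnosis, muscle = muscle, fs = fs, samples = x,
      drive = drive)
}

.muscles <- c("deltoid", "biceps brachii", "first dorsal interosseous",
              "vastus lateralis", "tibialis anterior", "gastrocnemius")

#' Simulate a synthetic nEMG cohort
#'
#' Generates `nPerClass` patients for each of the three diagnosis classes.
#' Each patient contributes a number of signals drawn from
#' `signalsPerPatient`; each signal gets its own motor unit pool, a
#' voluntary drive drawn from `driveRange`, a duration drawn from
#' `durationRange`, and band-limited noise, all at the acquisition rate
#' `fs`. Per-item child seeds make the cohort extensible without
#' reshuffling earlier patients, and the whole cohort is reproducible from
#' `seed`.
#'
#' @param nPerClass Patients per diagnosis class (default 19, i.e. a
#'   57-patient cohort).
#' @param signalsPerPatient Integer range of signals per patient.
#' @param durationRange Signal duration range, seconds.
#' @param physiology Named per-class physiology list.
#' @param fs Acquisition sampling rate, Hz.
#' @param driveRange Range the per-signal contraction level is drawn from.
#' @param seed Master seed.
#' @return An [EMGCohort-class].
#' @export
#' @examples
#' \donttest{
#' coh <- simulateCohort(nPerClass = 1, signalsPerPatient = c(1, 1),
#'                       durationRange = c(0.5, 0.6), seed = 1)
#' nPatients(coh)
#' }
simulateCohort <- function(nPerClass = 19, signalsPerPatient = c(5, 7),
                           durationRange = c(1.2, 3.4),
                           physiology = defaultPhysiology(),
                           fs = 48000, driveRange = c(0.3, 1.0),
                           seed = 1) {
  if (nPerClass < 1) stop("nPerClass must be >= 1", call. = FALSE)
  .assertRange(signalsPerPatient, "signalsPerPatient")
  .assertRange(durationRange, "durationRange")
  .assertRange(driveRange, "driveRange")
  sigs <- list()
  for (ci in seq_along(diagnosisLevels())) {
    cls <- diagnosisLevels()[ci]
    phys <- physiology[[cls]]
    if (is.null(phys)) stop("physiology is missing class ", cls, call. = FALSE)
    for (p in seq_len(nPerClass)) {
      pid <- sprintf("%s%03d", cls, p)
      nSig <- withSeed(childSeed(seed, ci, p, 0), {
        if (signalsPerPatient[1] == signalsPerPatient[2])
          as.integer(signalsPerPatient[1])
        else sample(signalsPerPatient[1]:signalsPerPatient[2], 1L)
      })
      for (s in seq_len(nSig)) {
        sigs[[length(sigs) + 1L]] <- withSeed(childSeed(seed, ci, p, s), {
          pool <- sampleMotorUnitPool(phys, cls, fs)
          drive <- runif(1, driveRange[1], driveRange[2])
          dur <- runif(1, durationRange[1], durationRange[2])
          renderSignal(pool, drive, dur, fs, noiseRms = phys$noiseRms,
                       signalId = sprintf("%s_S%02d", pid, s),
                       patientId = pid, diagnosis = cls,
                       muscle = sample(.muscles, 1L))
        })
      }
    }
  }
  new("EMGCohort", signals = sigs,
      metadata = list(seed = seed, nPerClass = nPerClass, fs = fs))
}

#' Default rater confusion matrix
#'
#' Shared 3x3 row-stochastic confusion (true class in rows, assigned class
#' in columns, order M/N/NL) loosely shaped after reported physician
#' behaviour on this task: neuropathy is recognised best, myopathy is
#' under-called, and normal items are strongly biased towards a
#' neuropathy label.
#'
#' @return 3x3 row-stochastic matrix.
#' @export
defaultRaterConfusion <- function() {
  m <- matrix(c(0.50, 0.30, 0.20,
                0.08, 0.77, 0.15,
                0.25, 0.55, 0.20),
              nrow = 3, byrow = TRUE,
              dimnames = list(diagnosisLevels(), diagnosisLevels()))
  m
}

.rdirichletRow <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate a physician rater panel
#'
#' Each rater gets a private confusion matrix: the shared `confusionSpec`
#' rows perturbed by a mean-preserving Dirichlet jitter
#' (`alpha = row * jitterConcentration`). Signal and patient labels are
#' then sampled independently per (rater, item) from the rater's row for
#' the item's true class.
#'
#' @param cohort An [EMGCohort-class].
#' @param confusionSpec Shared 3x3 row-stochastic confusion matrix.
#' @param nRaters Number of raters (default 6).
#' @param jitterConcentration Dirichlet concentration of the per-rater
#'   jitter; `Inf` disables jitter.
#' @param seed Master seed.
#' @return A [RaterPanel-class].
#' @export
simulateRaterPanel <- function(cohort, confusionSpec = defaultRaterConfusion(),
                               nRaters = 6, jitterConcentration = 300,
                               seed = 1) {
  if (!is.matrix(confusionSpec) || any(dim(confusionSpec) != 3L) ||
      any(confusionSpec < 0) || any(abs(rowSums(confusionSpec) - 1) > 1e-8))
    stop("confusionSpec must be a 3x3 row-stochastic matrix", call. = FALSE)
  st <- signalTable(cohort)
  pt <- patientTable(cohort)
  items <- rbind(
    data.frame(item_type = "signal", item_id = st$signal_id,
               true_label = st$diagnosis, stringsAsFactors = FALSE),
    data.frame(item_type = "patient", item_id = pt$patient_id,
               true_label = pt$diagnosis, stringsAsFactors = FALSE))
  lev <- diagnosisLevels()
  confusions <- list()
  labs <- vector("list", nRaters)
  for (r in seq_len(nRaters)) {
    out <- withSeed(childSeed(seed, 9000, r), {
      cm <- confusionSpec
      if (is.finite(jitterConcentration)) {
        for (i in 1:3)
          cm[i, ] <- .rdirichletRow(confusionSpec[i, ] * jitterConcentration)
      }
      rows <- match(items$true_label, lev)
      lab <- vapply(rows, function(i) sample(lev, 1L, prob = cm[i, ]),
                    character(1))
      list(cm = cm, lab = lab)
    })
    confusions[[r]] <- out$cm
    labs[[r]] <- data.frame(rater_id = sprintf("R%d", r), items,
                            label = out$lab, stringsAsFactors = FALSE)
  }
  new("RaterPanel", nRaters = as.integer(nRaters), confusion = confusions,
      labels = do.call(rbind, labs))
}

#' Write rater panel labels as CSV
#'
#' @param panel A [RaterPanel-class].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
writeRaterPanel <- function(panel, path) {
  write.csv(raterLabels(panel), path, row.names = FALSE)
  invisible(path)
}
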
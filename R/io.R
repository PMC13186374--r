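# Minimal RIFF/WAVE float reader and writer. Format code 3 (IEEE float),
# mono, 32-bit: the manifest records the microvolt unit that WAV itself
# cannot carry.

.writeWave <- function(samples, fs, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(samples)
  dataBytes <- 4L * n
  writeChar("RIFF", con, 4, eos = NULL)
  writeBin(as.integer(4 + 26 + 12 + 8 + dataBytes), con, size = 4,
           endian = "little")
  writeChar("WAVE", con, 4, eos = NULL)
  writeChar("fmt ", con, 4, eos = NULL)
  writeBin(18L, con, size = 4, endian = "little")
  writeBin(3L, con, size = 2, endian = "little")        # IEEE float
  writeBin(1L, con, size = 2, endian = "little")        # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 4), con, size = 4, endian = "little")
  writeBin(4L, con, size = 2, endian = "little")
  writeBin(32L, con, size = 2, endian = "little")
  writeBin(0L, con, size = 2, endian = "little")        # cbSize
  writeChar("fact", con, 4, eos = NULL)
  writeBin(4L, con, size = 4, endian = "little")
  writeBin(as.integer(n), con, size = 4, endian = "little")
  writeChar("data", con, 4, eos = NULL)
  writeBin(as.integer(dataBytes), con, size = 4, endian = "little")
  writeBin(samples, con, size = 4, endian = "little")
  invisible(path)
}

.readWave <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4), "RIFF"))
    stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, integer(), size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE"))
    stop("not a WAVE file: ", path, call. = FALSE)
  fs <- NULL; fmt <- NULL; bits <- NULL; samplesOut <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || !nzchar(id)) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), size = 2, endian = "little")
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      fs <- readBin(con, integer(), size = 4, endian = "little")
      invisible(readBin(con, integer(), size = 4, endian = "little"))
      invisible(readBin(con, integer(), size = 2, endian = "little"))
      bits <- readBin(con, integer(), size = 2, endian = "little")
      rest <- sz - 16
      if (rest > 0) invisible(readBin(con, raw(), n = rest))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("malformed WAV: data before fmt", call. = FALSE)
      if (fmt != 3L || bits != 32L)
        stop("unsupported WAV encoding in ", path,
             " (expected 32-bit IEEE float)", call. = FALSE)
      samplesOut <- readBin(con, numeric(), n = sz %/% 4, size = 4,
                            endian = "little")
      if (sz %% 2 == 1) invisible(readBin(con, raw(), n = 1))
    } else {
      invisible(readBin(con, raw(), n = sz + sz %% 2))
    }
    if (!is.null(samplesOut) && !is.null(fs)) break
  }
  if (is.null(samplesOut)) stop("no data chunk in ", path, call. = FALSE)
  list(samples = samplesOut, fs = fs)
}

.manifestCols <- c("patient_id", "signal_id", "file_path", "diagnosis",
                   "muscle", "fs", "n_samples", "duration", "drive")

#' Write a cohort to a directory
#'
#' Layout: `directory/manifest.csv` plus one 32-bit float mono WAV per
#' signal under `directory/wav/`. Waveforms are quantised once to float32
#' at write time; read-back is exact at that precision. The manifest
#' records the patient linkage, diagnosis, muscle, sampling rate, sample
#' count, duration and simulated drive.
#'
#' @param cohort An [EMGCohort-class].
#' @param directory Output directory (created if needed).
#' @return The manifest `data.frame`, invisibly.
#' @export
writeCohort <- function(cohort, directory) {
  stopifnot(is(cohort, "EMGCohort"))
  dir.create(file.path(directory, "wav"), recursive = TRUE,
             showWarnings = FALSE)
  st <- signalTable(cohort)
  st$file_path <- file.path("wav", paste0(st$signal_id, ".wav"))
  for (i in seq_along(cohort@signals)) {
    s <- cohort@signals[[i]]
    .writeWave(s@samples, s@fs, file.path(directory, st$file_path[i]))
  }
  manifest <- st[, .manifestCols]
  write.csv(manifest, file.path(directory, "manifest.csv"),
            row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort from a directory
#'
#' Validates the manifest on load: unique signal ids, existing waveform
#' files whose sample counts match the manifest, and a single diagnosis
#' per patient. Violations raise an error naming the offending row.
#'
#' @param directory Directory written by [writeCohort()].
#' @return An [EMGCohort-class].
#' @export
readCohort <- function(directory) {
  mpath <- file.path(directory, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", directory, call. = FALSE)
  man <- read.csv(mpath, stringsAsFactors = FALSE)
  need <- setdiff(.manifestCols, "drive")
  miss <- setdiff(need, names(man))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"drive" %in% names(man)) man$drive <- NA_real_
  dup <- duplicated(man$signal_id)
  if (any(dup))
    stop("manifest row ", which(dup)[1], ": duplicate signal_id ",
         man$signal_id[which(dup)[1]], call. = FALSE)
  .checkDiagnosis(man$diagnosis)
  perPat <- tapply(man$diagnosis, man$patient_id,
                   function(d) length(unique(d)))
  if (any(perPat > 1)) {
    bad <- names(perPat)[perPat > 1][1]
    stop("manifest rows for patient ", bad,
         " carry conflicting diagnosis labels", call. = FALSE)
  }
  sigs <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    fp <- file.path(directory, man$file_path[i])
    if (!file.exists(fp))
      stop("manifest row ", i, ": file not found: ", man$file_path[i],
           call. = FALSE)
    wav <- .readWave(fp)
    if (length(wav$samples) != man$n_samples[i])
      stop("manifest row ", i, " (", man$signal_id[i],
           "): sample count mismatch (file ", length(wav$samples),
           ", manifest ", man$n_samples[i], ")", call. = FALSE)
    if (wav$fs != man$fs[i])
      stop("manifest row ", i, " (", man$signal_id[i],
           "): sampling rate mismatch", call. = FALSE)
    sigs[[i]] <- new("EMGSignal", signalId = man$signal_id[i],
                     patientId = man$patient_id[i],
                     diagnosis = man$diagnosis[i], muscle = man$muscle[i],
                     fs = wav$fs, samples = wav$samples,
                     drive = man$drive[i])
  }
  new("EMGCohort", signals = sigs, metadata = list(source = directory))
}

# Kaiser-windowed FIR low-pass for rational resampling, designed at the
# p-times upsampled rate; cutoff sits at 92% of the tighter Nyquist.
.resampleFilter <- function(p, q, ntaps = 1201, beta = 8) {
  fc <- 0.92 / max(p, q)
  signal::fir1(ntaps - 1, fc, type = "low",
               window = signal::kaiser(ntaps, beta))
}

#' Resample a signal with an anti-aliased polyphase FIR
#'
#' Rational-rate conversion (upsample by p, Kaiser-windowed linear-phase
#' FIR low-pass, downsample by q) with the group delay compensated.
#' Stop-band attenuation above the target Nyquist exceeds 60 dB;
#' only downsampling is supported.
#'
#' @param x An [EMGSignal-class] or numeric vector.
#' @param targetFs Target sampling rate, Hz.
#' @param fs Source rate (required when `x` is a plain vector).
#' @return Object of the same kind as `x` at `targetFs`; output length is
#'   `round(n * targetFs / fs)`.
#' @export
#' @examples
#' y <- resampleSignal(sin(2 * pi * 50 * (0:4799) / 48000), 10000, fs = 48000)
#' length(y)  # 1000
resampleSignal <- function(x, targetFs = 10000, fs = NULL) {
  if (is(x, "EMGSignal")) {
    out <- resampleSignal(x@samples, targetFs, fs = x@fs)
    return(new("EMGSignal", signalId = x@signalId, patientId = x@patientId,
               diagnosis = x@diagnosis, muscle = x@muscle,
               fs = targetFs, samples = out, drive = x@drive))
  }
  .assertScalarNum(targetFs, "targetFs", positive = TRUE)
  if (is.null(fs)) stop("fs is required for plain numeric input", call. = FALSE)
  if (targetFs > fs)
    stop("upsampling is not supported (targetFs > fs)", call. = FALSE)
  if (targetFs == fs) return(x)
  g <- .gcd(as.integer(round(fs)), as.integer(round(targetFs)))
  p <- as.integer(round(targetFs) / g)
  q <- as.integer(round(fs) / g)
  h <- .resampleFilter(p, q)
  y <- as.numeric(.firResample(as.numeric(x), h, p, q))
  nOut <- as.integer(round(length(x) * targetFs / fs))
  length(y) <- nOut   # pad/trim the floor-length output to the rounded one
  y[is.na(y)] <- 0
  y
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Split a signal into fixed non-overlapping windows
#'
#' Consecutive windows of `window` seconds from sample 1; the trailing
#' remainder shorter than one window is discarded. A signal shorter than
#' one window yields zero segments (callers decide to drop it, mirroring
#' the minimum-window exclusion rule).
#'
#' @param x An [EMGSignal-class] or numeric vector at the working rate.
#' @param window Window length in seconds (default 0.4).
#' @param fs Sampling rate (required for plain vectors).
#' @return Numeric matrix with one column per segment
#'   (`round(window * fs)` rows; zero columns if the signal is too short).
#' @export
#' @examples
#' dim(segmentSamples(numeric(26000), fs = 10000))  # 4000 x 6
segmentSamples <- function(x, window = 0.4, fs = NULL) {
  if (is(x, "EMGSignal")) {
    fs <- x@fs
    x <- x@samples
  }
  if (is.null(fs)) stop("fs is required for plain numeric input", call. = FALSE)
  .assertScalarNum(window, "window", positive = TRUE)
  wlen <- as.integer(round(window * fs))
  k <- length(x) %/% wlen
  matrix(x[seq_len(k * wlen)], nrow = wlen, ncol = k)
}

#' Resample and segment a cohort into a SummarizedExperiment
#'
#' The documented pipeline order: every signal is first resampled to the
#' working rate (default 10 kHz), then cut into non-overlapping 0.4-s
#' windows, fixing the segment length at 4000 samples. Segment waveforms
#' are multiplied by a global scale constant (default 1/1000: microvolts
#' to millivolts) for numeric conditioning; no per-segment amplitude
#' normalisation is applied, since absolute amplitude is diagnostic.
#' Signals shorter than one window contribute no segments.
#'
#' @param cohort An [EMGCohort-class].
#' @param targetFs Working rate, Hz.
#' @param window Window length, seconds.
#' @param scale Global amplitude scale applied to the segment matrix.
#' @return A [SummarizedExperiment::SummarizedExperiment-class] whose
#'   `segments` assay is a `round(window * targetFs)` x n matrix, with
#'   `colData` columns `signal_id`, `patient_id`, `diagnosis`, `muscle`,
#'   `segment` (0-based index within its signal).
#' @export
segmentCohort <- function(cohort, targetFs = 10000, window = 0.4,
                          scale = 1 / 1000) {
  stopifnot(is(cohort, "EMGCohort"))
  mats <- list(); meta <- list()
  for (s in cohort@signals) {
    y <- if (s@fs == targetFs) s else resampleSignal(s, targetFs)
    m <- segmentSamples(y, window = window, fs = targetFs)
    if (ncol(m) == 0L) next
    mats[[length(mats) + 1L]] <- m
    meta[[length(meta) + 1L]] <- data.frame(
      signal_id = s@signalId, patient_id = s@patientId,
      diagnosis = s@diagnosis, muscle = s@muscle,
      segment = seq_len(ncol(m)) - 1L, stringsAsFactors = FALSE)
  }
  if (!length(mats))
    stop("no signal in the cohort is at least one window long",
         call. = FALSE)
  assay <- do.call(cbind, mats) * scale
  cd <- do.call(rbind, meta)
  colnames(assay) <- sprintf("%s.%d", cd$signal_id, cd$segment)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(segments = assay),
    colData = S4Vectors::DataFrame(cd),
    metadata = list(fs = targetFs, window = window, scale = scale))
}
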
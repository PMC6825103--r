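#' Read a multichannel recording from disk
#'
#' Two on-disk layouts are supported: European Data Format (\code{"edf"}) and
#' a plain delimited matrix (\code{"delimited"}, rows = channels, columns =
#' samples, comma or tab separated) accompanied by a JSON sidecar
#' \code{<path>.json} with fields \code{subject_id}, \code{sex}, \code{fs}
#' and \code{channels}.
#'
#' @param path path to the data file.
#' @param format \code{"edf"} or \code{"delimited"}; default guesses from the
#'   file extension.
#' @return An [EEGRecording-class].
#' @seealso [writeRecording()]
#' @export
readRecording <- function(path, format = c("auto", "edf", "delimited")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("cannot read recording: file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "delimited"
  if (format == "edf") return(readEDF(path))
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing metadata sidecar for delimited recording: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (field in c("subject_id", "sex", "fs", "channels")) {
    if (is.null(meta[[field]]))
      stop("metadata sidecar is missing required field '", field, "'")
  }
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  dat <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  dimnames(dat) <- NULL
  EEGRecording(dat, fs = meta$fs, channelNames = meta$channels,
               subjectId = meta$subject_id, sex = meta$sex)
}

#' Write a recording as a delimited matrix plus JSON sidecar
#'
#' @param rec an [EEGRecording-class].
#' @param path output path for the data matrix; metadata goes to
#'   \code{<path>.json}.
#' @param sep field separator (\code{","} or \code{"\t"}).
#' @return \code{path}, invisibly.
#' @export
writeRecording <- function(rec, path, sep = ",") {
  stopifnot(is(rec, "EEGRecording"))
  utils::write.table(signalData(rec), path, sep = sep, row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(subject_id = subjectId(rec), sex = sexLabel(rec),
         fs = samplingRate(rec), channels = channelNames(rec)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---- Minimal EDF (16-bit) reader/writer ------------------------------------
# Continuous recordings only, one data-record per second. The subject id and
# sex label travel in the 80-byte patient field as "<id> <sex>".

padTo <- function(s, n) {
  s <- substr(as.character(s), 1L, n)
  paste0(s, strrep(" ", n - nchar(s)))
}

#' Write a recording as a 16-bit EDF file
#'
#' The recording is split into one-second data records; trailing samples that
#' do not fill a whole second are dropped with a warning. Samples are scaled
#' to the signed 16-bit digital range per channel, so values round-trip to
#' roughly \code{range/2^16} absolute accuracy.
#'
#' @inheritParams writeRecording
#' @return \code{path}, invisibly.
#' @export
writeEDF <- function(rec, path) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- samplingRate(rec)
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate")
  fs <- as.integer(round(fs))
  x <- signalData(rec)
  ns <- nrow(x)
  nrec <- floor(ncol(x) / fs)
  if (nrec < 1L) stop("recording shorter than one EDF data record (1 s)")
  if (ncol(x) > nrec * fs)
    warning(sprintf("EDF writer dropping %d trailing samples (partial second)",
                    ncol(x) - nrec * fs))
  x <- x[, seq_len(nrec * fs), drop = FALSE]

  pmin <- apply(x, 1, min); pmax <- apply(x, 1, max)
  flat <- pmax - pmin <= 0
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32767L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchar(s), eos = NULL)
  wr(padTo("0", 8))
  wr(padTo(paste(subjectId(rec), sexLabel(rec)), 80))
  wr(padTo("entrosex recording", 80))
  wr(padTo("01.01.00", 8)); wr(padTo("00.00.00", 8))
  wr(padTo(256L * (1L + ns), 8))
  wr(padTo("", 44))
  wr(padTo(nrec, 8))
  wr(padTo(1L, 8))            # record duration: 1 s
  wr(padTo(ns, 4))
  for (ch in channelNames(rec)) wr(padTo(ch, 16))
  for (i in seq_len(ns)) wr(padTo("", 80))       # transducer
  for (i in seq_len(ns)) wr(padTo("uV", 8))      # physical dimension
  for (i in seq_len(ns)) wr(padTo(format(pmin[i], digits = 7), 8))
  for (i in seq_len(ns)) wr(padTo(format(pmax[i], digits = 7), 8))
  for (i in seq_len(ns)) wr(padTo(dmin, 8))
  for (i in seq_len(ns)) wr(padTo(dmax, 8))
  for (i in seq_len(ns)) wr(padTo("", 80))       # prefiltering
  for (i in seq_len(ns)) wr(padTo(fs, 8))
  for (i in seq_len(ns)) wr(padTo("", 32))

  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(nrec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      dig <- as.integer(round((x[i, cols] - pmin[i]) * scale[i]) + dmin)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a 16-bit EDF file
#'
#' @param path path to the EDF file.
#' @return An [EEGRecording-class]. The subject id and sex label are parsed
#'   from the patient-identification header field (as written by
#'   [writeEDF()]); a missing or unparseable sex label is a validation error.
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  version <- rd(8)
  patient <- rd(80)
  rd(80); rd(8); rd(8)
  rd(8)                # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(nrec) || is.na(ns) || is.na(recdur) || recdur <= 0)
    stop("not a readable EDF file: ", path)
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  for (i in seq_len(ns)) rd(32)

  toks <- strsplit(patient, "\\s+")[[1]]
  sex <- tolower(toks[toks %in% c("male", "female", "Male", "Female", "M", "F")])
  sex <- if (length(sex)) c(m = "male", f = "female",
                            male = "male", female = "female")[[substr(sex[1], 1, 1)]] else NA
  if (is.na(sex))
    stop("EDF patient field does not carry a sex label (need 'male'/'female')")
  sid <- if (length(toks)) toks[1] else "unknown"

  sig <- matrix(0, ns, nrec * spr[1])
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2L, signed = TRUE,
                     endian = "little")
      sig[i, ((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        (dig - dmin[i]) * scale[i] + pmin[i]
    }
  }
  EEGRecording(sig, fs = spr[1] / recdur, channelNames = labels,
               subjectId = sid, sex = sex)
}

# ---- Filtering --------------------------------------------------------------

filtfiltRows <- function(filt, x) {
  out <- t(apply(x, 1, function(row) signal::filtfilt(filt, row)))
  dimnames(out) <- dimnames(x)
  out
}

#' Zero-phase notch filter (power-line removal)
#'
#' Second-order IIR notch (constrained biquad, standard audio-EQ closed form)
#' applied forward-backward with \code{signal::filtfilt}, so phase is zero
#' and epoch alignment is preserved.
#'
#' @param rec an [EEGRecording-class].
#' @param freq notch centre frequency in Hz (default 50, European mains).
#' @param q quality factor; bandwidth is \code{freq/q} (default 30).
#' @return The filtered [EEGRecording-class] (same shape and metadata).
#' @export
applyNotch <- function(rec, freq = 50, q = 30) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- samplingRate(rec)
  if (freq <= 0 || freq >= fs / 2)
    stop("notch frequency must lie in (0, fs/2); got ", freq,
         " Hz at fs = ", fs, " Hz")
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  filt <- signal::Arma(b = b / a[1], a = a / a[1])
  initialize(rec, signal = filtfiltRows(filt, signalData(rec)))
}

# RBJ audio-EQ biquad (bilinear transform of one analog prototype section,
# prewarped at fc) for a given section quality factor
biquadSection <- function(fc, fs, Q, type = c("high", "low")) {
  type <- match.arg(type)
  w0 <- 2 * pi * fc / fs
  alpha <- sin(w0) / (2 * Q)
  c0 <- cos(w0)
  b <- if (type == "high") c((1 + c0) / 2, -(1 + c0), (1 + c0) / 2)
       else c((1 - c0) / 2, 1 - c0, (1 - c0) / 2)
  a <- c(1 + alpha, -2 * c0, 1 - alpha)
  signal::Arma(b = b / a[1], a = a / a[1])
}

# Butterworth section quality factors for an even-order design
butterSectionQ <- function(order) {
  1 / (2 * cos((2 * seq_len(order / 2) - 1) * pi / (2 * order)))
}

#' Zero-phase Butterworth band-pass filter
#'
#' Realized as a cascade of an order-\code{order} Butterworth high-pass at
#' \code{low} and an order-\code{order} low-pass at \code{high}, each built
#' from second-order sections and applied forward-backward. Second-order
#' sections keep the filter numerically exact (linearity to ~1e-12) at the
#' very low normalized high-pass edge EEG uses (0.15 Hz at 1000 Hz), where a
#' transfer-function-form design degrades; the cascade also gives > 20 dB
#' stopband attenuation at 60 Hz.
#'
#' @param rec an [EEGRecording-class].
#' @param low high-pass edge in Hz (default 0.15).
#' @param high low-pass edge in Hz (default 45).
#' @param order order of each Butterworth section cascade (even, default 4).
#' @return The filtered [EEGRecording-class].
#' @export
applyBandpass <- function(rec, low = 0.15, high = 45, order = 4) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- samplingRate(rec)
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2; got [",
         low, ", ", high, "] at fs = ", fs, " Hz")
  if (order %% 2 != 0) stop("filter order must be even")
  x <- signalData(rec)
  for (Q in butterSectionQ(order))
    x <- filtfiltRows(biquadSection(low, fs, Q, "high"), x)
  for (Q in butterSectionQ(order))
    x <- filtfiltRows(biquadSection(high, fs, Q, "low"), x)
  initialize(rec, signal = x)
}

#' Retain the trailing analysis segment of a recording
#'
#' Keeps the last \code{durationS} seconds (the analysis window: subjects
#' need the first minutes of a resting-state session to settle).
#'
#' @param rec an [EEGRecording-class].
#' @param durationS seconds to retain from the end (default 300 = 5 min).
#' @return The trimmed [EEGRecording-class].
#' @export
retainFinalSegment <- function(rec, durationS = 300) {
  stopifnot(is(rec, "EEGRecording"))
  need <- round(durationS * samplingRate(rec))
  have <- ncol(signalData(rec))
  if (have < need)
    stop(sprintf("recording has %d samples but %d are required for %g s",
                 have, need, durationS))
  initialize(rec, signal = signalData(rec)[, (have - need + 1L):have,
                                           drop = FALSE])
}

#' Cut a recording into non-overlapping fixed-length epochs
#'
#' Consecutive half-open windows of \code{epochLenS} seconds; a trailing
#' partial window is discarded (so a 300 s recording at 1000 Hz gives exactly
#' 300 one-second epochs).
#'
#' @param rec an [EEGRecording-class].
#' @param epochLenS epoch length in seconds (default 1).
#' @return An [EpochSet-class]; every epoch inherits the recording's subject
#'   id and sex label.
#' @export
segmentEpochs <- function(rec, epochLenS = 1.0) {
  stopifnot(is(rec, "EEGRecording"))
  fs <- samplingRate(rec)
  nper <- round(epochLenS * fs)
  if (nper < 10)
    stop("epochs must contain at least 10 samples; got ", nper)
  x <- signalData(rec)
  nep <- floor(ncol(x) / nper)
  if (nep == 0L)
    warning("recording shorter than one epoch; returning 0 epochs")
  dropped <- ncol(x) - nep * nper
  if (dropped > 0L)
    message(sprintf("segmentEpochs: discarding %d trailing samples", dropped))
  arr <- array(0, dim = c(nep, nrow(x), nper))
  for (k in seq_len(nep)) {
    arr[k, , ] <- x[, ((k - 1L) * nper + 1L):(k * nper), drop = FALSE]
  }
  new("EpochSet", epochs = arr,
      subjectIds = rep(subjectId(rec), nep),
      labels = factor(rep(sexLabel(rec), nep), levels = SEX_LEVELS),
      epochLenS = epochLenS, fs = fs, channelNames = channelNames(rec))
}

#' Concatenate epoch sets
#'
#' @param ... [EpochSet-class] objects with matching channels, sampling rate
#'   and epoch length.
#' @return A single combined [EpochSet-class].
#' @export
bindEpochSets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is(sets[[1]], "EpochSet"))
    sets <- sets[[1]]
  stopifnot(length(sets) >= 1L, all(vapply(sets, is, logical(1), "EpochSet")))
  ref <- sets[[1]]
  for (s in sets[-1]) {
    if (!identical(s@channelNames, ref@channelNames) ||
        s@fs != ref@fs || s@epochLenS != ref@epochLenS)
      stop("epoch sets differ in channels, fs or epoch length")
  }
  arrs <- lapply(sets, function(s) s@epochs)
  total <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  d <- dim(arrs[[1]])
  out <- array(0, dim = c(total, d[2], d[3]))
  at <- 0L
  for (a in arrs) {
    n <- dim(a)[1]
    if (n > 0) out[(at + 1L):(at + n), , ] <- a
    at <- at + n
  }
  new("EpochSet", epochs = out,
      subjectIds = unlist(lapply(sets, function(s) s@subjectIds)),
      labels = factor(unlist(lapply(sets, function(s) as.character(s@labels))),
                      levels = SEX_LEVELS),
      epochLenS = ref@epochLenS, fs = ref@fs, channelNames = ref@channelNames)
}
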
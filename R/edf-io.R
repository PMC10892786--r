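## EDF (European Data Format) input/output.
##
## Minimal 16-bit EDF reader/writer for single-channel EEG plus an EDF+
## annotation (TAL) reader/writer for hypnograms. A plain TSV dialect
## "epoch_index<TAB>stage" is also accepted for hypnogram fixtures.

padField <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

readField <- function(con, width) trimws(rawToChar(readBin(con, "raw", width)))

## mapping between annotation text and raw stage labels
annotationText <- c(W = "Sleep stage W", N1 = "Sleep stage 1",
                    N2 = "Sleep stage 2", N3 = "Sleep stage 3",
                    N4 = "Sleep stage 4", SWS = "Sleep stage 3",
                    REM = "Sleep stage R", "?" = "Sleep stage ?",
                    MOVEMENT = "Movement time")

labelFromText <- function(txt) {
  lut <- c("Sleep stage W" = "W", "Sleep stage 1" = "N1", "Sleep stage 2" = "N2",
           "Sleep stage 3" = "N3", "Sleep stage 4" = "N4", "Sleep stage R" = "REM",
           "Sleep stage ?" = "?", "Movement time" = "MOVEMENT")
  out <- unname(lut[txt])
  out[is.na(out)] <- txt[is.na(out)]
  out
}

#' Read a single EEG channel from an EDF file
#'
#' Parses a 16-bit EDF file and returns the requested channel as an
#' [EEGRecording-class]. Subject metadata (age, sex, id) is recovered from
#' the local-patient-identification header field when it follows the
#' `id=<id> age=<years> sex=<label>` convention used by [writeEDF()];
#' otherwise defaults apply.
#'
#' @param path path to an EDF file.
#' @param channel channel label to extract; `NULL` selects the first signal.
#' @return An [EEGRecording-class].
#' @seealso [writeEDF()], [readHypnogram()]
#' @export
readRecording <- function(path, channel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  version <- readField(con, 8)
  if (version != "0") stop("unreadable EDF header in ", path, " (version field '", version, "')")
  patient <- readField(con, 80)
  readField(con, 80)                       # recording id
  readField(con, 8); readField(con, 8)     # start date/time
  headerBytes <- as.integer(readField(con, 8))
  readField(con, 44)
  nRecords <- as.integer(readField(con, 8))
  recDur <- as.numeric(readField(con, 8))
  ns <- as.integer(readField(con, 4))
  if (is.na(ns) || ns < 1L || is.na(headerBytes))
    stop("unreadable EDF header in ", path)
  labels <- vapply(seq_len(ns), function(i) readField(con, 16), character(1))
  vapply(seq_len(ns), function(i) readField(con, 80), character(1)) # transducer
  vapply(seq_len(ns), function(i) readField(con, 8), character(1))  # dimension
  physMin <- as.numeric(vapply(seq_len(ns), function(i) readField(con, 8), character(1)))
  physMax <- as.numeric(vapply(seq_len(ns), function(i) readField(con, 8), character(1)))
  digMin <- as.numeric(vapply(seq_len(ns), function(i) readField(con, 8), character(1)))
  digMax <- as.numeric(vapply(seq_len(ns), function(i) readField(con, 8), character(1)))
  vapply(seq_len(ns), function(i) readField(con, 80), character(1)) # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) readField(con, 8), character(1)))
  vapply(seq_len(ns), function(i) readField(con, 32), character(1)) # reserved

  if (is.null(channel)) {
    sig <- 1L
  } else {
    sig <- match(channel, labels)
    if (is.na(sig))
      stop("channel '", channel, "' not present; available channels: ",
           paste(labels, collapse = ", "))
  }
  gain <- (physMax[sig] - physMin[sig]) / (digMax[sig] - digMin[sig])
  seek(con, headerBytes)
  out <- vector("list", nRecords)
  for (r in seq_len(nRecords)) {
    for (s in seq_len(ns)) {
      vals <- readBin(con, "integer", n = spr[s], size = 2, signed = TRUE,
                      endian = "little")
      if (s == sig) out[[r]] <- (vals - digMin[sig]) * gain + physMin[sig]
    }
  }
  samples <- unlist(out, use.names = FALSE)
  age <- 30; sex <- "X"; id <- sub("\\.edf$", "", basename(path), ignore.case = TRUE)
  m <- regmatches(patient, regexec("age=([0-9.]+)", patient))[[1]]
  if (length(m) == 2) age <- as.numeric(m[2])
  m <- regmatches(patient, regexec("sex=(\\S+)", patient))[[1]]
  if (length(m) == 2) sex <- m[2]
  m <- regmatches(patient, regexec("id=(\\S+)", patient))[[1]]
  if (length(m) == 2) id <- m[2]
  EEGRecording(samples, rate = spr[sig] / recDur, channel = labels[sig],
               age = age, sex = sex, id = id)
}

#' Read a hypnogram annotation file
#'
#' Accepts either an EDF+ annotation file (time-stamped annotation lists as
#' written by [writeEDF()] or by polysomnography archives) or the plain TSV
#' dialect `epoch_index<TAB>stage` (0-based epoch index, raw stage labels).
#' Labels are normalised to the raw alphabet
#' W, N1, N2, N3, N4, REM, ?, MOVEMENT (SWS is also accepted so that
#' already-harmonised label files round-trip).
#'
#' @param path path to the annotation file.
#' @return A `RawHypnogram`: a data.frame with columns `onset` (s),
#'   `duration` (s) and `label`, ordered by onset.
#' @export
readHypnogram <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  head8 <- readBin(path, "raw", 8)
  if (identical(rawToChar(head8), "0       ")) {
    entries <- readEdfAnnotations(path)
  } else {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("epoch", "label"))
    entries <- data.frame(onset = tab$epoch * 30, duration = 30,
                          label = as.character(tab$label),
                          stringsAsFactors = FALSE)
  }
  entries$label <- labelFromText(entries$label)
  o <- order(entries$onset)
  entries <- entries[o, , drop = FALSE]
  rownames(entries) <- NULL
  bad <- which(entries$duration <= 0 | entries$duration %% 30 != 0)
  if (length(bad))
    stop("hypnogram entry ", bad[1], " (onset ", entries$onset[bad[1]],
         " s) has duration ", entries$duration[bad[1]],
         " s, not a positive multiple of 30 s")
  if (nrow(entries) > 1) {
    ends <- entries$onset + entries$duration
    ov <- which(entries$onset[-1] < ends[-nrow(entries)])
    if (length(ov))
      stop("overlapping hypnogram entries at rows ", ov[1], " and ", ov[1] + 1,
           " (onset ", entries$onset[ov[1] + 1], " s)")
  }
  class(entries) <- c("RawHypnogram", "data.frame")
  entries
}

readEdfAnnotations <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readField(con, 8 + 80 + 80 + 8 + 8)
  headerBytes <- as.integer(readField(con, 8))
  readField(con, 44)
  nRecords <- as.integer(readField(con, 8))
  readField(con, 8)
  ns <- as.integer(readField(con, 4))
  labels <- vapply(seq_len(ns), function(i) readField(con, 16), character(1))
  seek(con, 256 + ns * (16 + 80 + 8 + 8 + 8 + 8 + 8 + 80))
  spr <- as.integer(vapply(seq_len(ns), function(i) readField(con, 8), character(1)))
  annSig <- match("EDF Annotations", labels)
  if (is.na(annSig)) stop("no 'EDF Annotations' signal in ", path,
                          "; available channels: ", paste(labels, collapse = ", "))
  seek(con, headerBytes)
  blobs <- vector("list", nRecords)
  for (r in seq_len(nRecords)) {
    for (s in seq_len(ns)) {
      bytes <- readBin(con, "raw", n = spr[s] * 2)
      if (s == annSig) blobs[[r]] <- bytes
    }
  }
  blob <- unlist(blobs)
  ## TALs are separated by 0x00; fields by 0x14; duration marked by 0x15
  blob[blob == as.raw(0)] <- as.raw(10)
  pieces <- strsplit(rawToChar(blob), "\n", fixed = TRUE)[[1]]
  onset <- numeric(); duration <- numeric(); label <- character()
  for (p in pieces) {
    if (!nzchar(p)) next
    fields <- strsplit(p, "\x14", fixed = TRUE)[[1]]
    if (length(fields) < 2 || !any(nzchar(fields[-1]))) next  # bare timestamp TAL
    head <- strsplit(fields[1], "\x15", fixed = TRUE)[[1]]
    on <- suppressWarnings(as.numeric(head[1]))
    du <- if (length(head) > 1) suppressWarnings(as.numeric(head[2])) else NA_real_
    for (f in fields[-1]) {
      if (!nzchar(f)) next
      onset <- c(onset, on); duration <- c(duration, du); label <- c(label, f)
    }
  }
  if (!length(onset)) stop("no annotations found in ", path)
  if (anyNA(duration)) stop("annotation without a duration in ", path)
  data.frame(onset = onset, duration = duration, label = label,
             stringsAsFactors = FALSE)
}

#' Write an EDF recording/hypnogram fixture pair
#'
#' Writes the signal as a 16-bit EDF file (1-second data records) and the
#' stage labels as an EDF+ annotation file readable by [readHypnogram()].
#' Amplitudes round-trip within the 16-bit quantisation step implied by the
#' physical range of the data; stage labels round-trip exactly (through
#' [harmonise()], since canonical SWS is stored as the R&K "Sleep stage 3").
#'
#' @param recording an [EEGRecording-class]; its length must be a whole
#'   number of seconds.
#' @param hypnogram a [Hypnogram-class] aligned to the recording.
#' @param path output path of the signal file (e.g. `"S01-PSG.edf"`).
#' @param hypnogramPath output path of the annotation file; by default
#'   derived from `path` by replacing a `-PSG.edf` suffix with
#'   `-Hypnogram.edf` (or appending `-Hypnogram.edf`).
#' @return Invisibly, a character vector of the two paths written.
#' @export
writeEDF <- function(recording, hypnogram, path, hypnogramPath = NULL) {
  stopifnot(methods::is(recording, "EEGRecording"), methods::is(hypnogram, "Hypnogram"))
  x <- eegSamples(recording)
  if (length(x) == 0) stop("empty recording")
  rate <- samplingRate(recording)
  if (abs(rate - round(rate)) > 1e-9) stop("sampling rate must be an integer for EDF output")
  rate <- as.integer(round(rate))
  nRecords <- length(x) %/% rate
  if (nRecords < 1) stop("recording shorter than one 1-s data record")
  if (nRecords * rate != length(x)) {
    warning("recording truncated to a whole number of seconds for EDF output")
    x <- x[seq_len(nRecords * rate)]
  }
  if (is.null(hypnogramPath)) {
    hypnogramPath <- if (grepl("-PSG\\.edf$", path, ignore.case = TRUE))
      sub("-PSG\\.edf$", "-Hypnogram.edf", path, ignore.case = TRUE)
    else paste0(sub("\\.edf$", "", path, ignore.case = TRUE), "-Hypnogram.edf")
  }

  physMin <- min(x); physMax <- max(x)
  if (physMax <= physMin) physMax <- physMin + 1
  digMin <- -32768; digMax <- 32767
  gain <- (physMax - physMin) / (digMax - digMin)
  dig <- as.integer(round((x - physMin) / gain + digMin))

  con <- file(path, "wb")
  header <- paste0(
    padField("0", 8),
    padField(sprintf("id=%s age=%g sex=%s", recordingId(recording),
                     subjectAge(recording), recording@sex), 80),
    padField("Startdate 01-JAN-2000 somnoboost", 80),
    padField("01.01.00", 8), padField("00.00.00", 8),
    padField(256 * 2, 8), padField("", 44),
    padField(nRecords, 8), padField("1", 8), padField("1", 4),
    padField(recording@channel, 16), padField("synthetic", 80),
    padField("uV", 8),
    padField(sprintf("%.8g", physMin), 8), padField(sprintf("%.8g", physMax), 8),
    padField(digMin, 8), padField(digMax, 8),
    padField("", 80), padField(rate, 8), padField("", 32))
  writeChar(header, con, eos = NULL)
  writeBin(dig, con, size = 2, endian = "little")
  close(con)

  writeEdfAnnotations(hypnogram, hypnogramPath,
                      totalDuration = nEpochs(hypnogram) * hypnogram@epochLength)
  invisible(c(path, hypnogramPath))
}

writeEdfAnnotations <- function(hypnogram, path, totalDuration) {
  stages <- stageLabels(hypnogram)
  if (!length(stages)) stop("empty hypnogram")
  r <- rle(stages)
  onsets <- c(0, cumsum(r$lengths))[seq_along(r$lengths)] * hypnogram@epochLength
  durs <- r$lengths * hypnogram@epochLength
  tals <- c("+0\x14\x14",
            sprintf("+%g\x15%g\x14%s\x14", onsets, durs,
                    annotationText[r$values]))
  blob <- unlist(lapply(tals, function(t) c(charToRaw(t), as.raw(0L))))
  if (length(blob) %% 2 == 1) blob <- c(blob, as.raw(0))
  spr <- length(blob) / 2
  con <- file(path, "wb")
  header <- paste0(
    padField("0", 8), padField("", 80),
    padField("Startdate 01-JAN-2000 somnoboost", 80),
    padField("01.01.00", 8), padField("00.00.00", 8),
    padField(256 * 2, 8), padField("EDF+C", 44),
    padField(1, 8), padField(sprintf("%g", totalDuration), 8), padField("1", 4),
    padField("EDF Annotations", 16), padField("", 80), padField("", 8),
    padField(0, 8), padField(1, 8), padField(-32768, 8), padField(32767, 8),
    padField("", 80), padField(spr, 8), padField("", 32))
  writeChar(header, con, eos = NULL)
  writeBin(blob, con)
  close(con)
  invisible(path)
}

#' Write a hypnogram in the plain TSV dialect
#'
#' One line per epoch: `epoch_index<TAB>stage` (0-based).
#'
#' @param hypnogram a [Hypnogram-class].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
writeHypnogramTSV <- function(hypnogram, path) {
  stages <- stageLabels(hypnogram)
  utils::write.table(data.frame(epoch = seq_along(stages) - 1L, stage = stages),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

## expand a RawHypnogram into one raw label per 30-s epoch (gaps -> "?")
expandRawHypnogram <- function(raw) {
  lastEnd <- max(raw$onset + raw$duration)
  n <- as.integer(round(lastEnd / 30))
  labels <- rep("?", n)
  for (i in seq_len(nrow(raw))) {
    from <- as.integer(round(raw$onset[i] / 30)) + 1L
    to <- from + as.integer(round(raw$duration[i] / 30)) - 1L
    labels[from:to] <- raw$label[i]
  }
  labels
}

#' Convert a canonical Hypnogram to raw annotation entries
#'
#' Useful for re-running [harmonise()] on its own output (idempotence) and
#' for fixture generation.
#'
#' @param hypnogram a [Hypnogram-class].
#' @return A `RawHypnogram` data.frame.
#' @export
asRawHypnogram <- function(hypnogram) {
  stages <- stageLabels(hypnogram)
  r <- rle(stages)
  onsets <- c(0, cumsum(r$lengths))[seq_along(r$lengths)] * hypnogram@epochLength
  out <- data.frame(onset = onsets, duration = r$lengths * hypnogram@epochLength,
                    label = r$values, stringsAsFactors = FALSE)
  class(out) <- c("RawHypnogram", "data.frame")
  out
}

#' Harmonise a recording with its raw hypnogram
#'
#' Applies the stage conventions used throughout the package: R&K stages N3
#' and N4 are merged into SWS; epochs labelled `?` (ungraded) or `MOVEMENT`
#' are dropped together with their 30 s of signal; leading and trailing wake
#' runs are truncated to at most `wakeBuffer` minutes around the first and
#' last non-W epoch; the recording is cropped to the retained epochs.
#'
#' @param recording an [EEGRecording-class].
#' @param raw a `RawHypnogram` from [readHypnogram()] or [asRawHypnogram()].
#' @param wakeBuffer maximum wake retained at each end, in minutes.
#' @return A list with elements `recording` (cropped [EEGRecording-class])
#'   and `hypnogram` ([Hypnogram-class]); lengths are consistent
#'   (`nEpochs * 30 * rate == length(samples)`).
#' @export
harmonise <- function(recording, raw, wakeBuffer = 30) {
  stopifnot(methods::is(recording, "EEGRecording"), inherits(raw, "data.frame"))
  rate <- samplingRate(recording)
  spe <- rate * 30
  if (abs(spe - round(spe)) > 1e-9) stop("rate * 30 s must be an integer number of samples")
  spe <- as.integer(round(spe))
  labels <- expandRawHypnogram(raw)
  known <- rawStageAlphabet()
  badLab <- setdiff(unique(labels), known)
  if (length(badLab))
    stop("stage label(s) outside the known alphabet: ", paste(badLab, collapse = ", "))
  nSig <- length(eegSamples(recording)) %/% spe
  if (nSig < 1) stop("recording shorter than one epoch")
  if (nSig != length(labels)) {
    warning("recording covers ", nSig, " epochs but hypnogram has ",
            length(labels), "; truncating to the shorter")
    n <- min(nSig, length(labels))
    labels <- labels[seq_len(n)]
  } else n <- nSig

  labels[labels %in% c("N3", "N4")] <- "SWS"
  keep <- !(labels %in% c("?", "MOVEMENT"))
  idx <- which(keep)
  labels <- labels[keep]
  if (!length(labels)) stop("no scored epochs remain after dropping ungraded/movement epochs")
  nonW <- which(labels != "W")
  if (!length(nonW)) stop("hypnogram contains no non-W epochs; nothing to anchor wake trimming")
  buffer <- as.integer(round(wakeBuffer * 60 / 30))
  lo <- max(1L, min(nonW) - buffer)
  hi <- min(length(labels), max(nonW) + buffer)
  labels <- labels[lo:hi]
  idx <- idx[lo:hi]

  pick <- as.vector(outer(seq_len(spe), (idx - 1L) * spe, `+`))
  cropped <- EEGRecording(eegSamples(recording)[pick], rate = rate,
                          channel = recording@channel, age = subjectAge(recording),
                          sex = recording@sex, id = recordingId(recording))
  list(recording = cropped, hypnogram = Hypnogram(labels))
}
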
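test_that("EDF write/read round-trips signal, rate and metadata", {
  hyp <- simulateHypnogram(10, seed = 2)
  rec <- simulateRecording(hyp, seed = 3, age = 41, sex = "F", id = "T01")
  td <- withr::local_tempdir()
  psg <- file.path(td, "T01-PSG.edf")
  paths <- writeEDF(rec, hyp, psg)
  expect_true(all(file.exists(paths)))

  back <- readRecording(psg, channel = "EEG Pz-Oz")
  expect_equal(samplingRate(back), 100)
  expect_length(eegSamples(back), 10 * 3000)
  expect_equal(subjectAge(back), 41)
  expect_equal(recordingId(back), "T01")
  ## amplitudes within one 16-bit quantisation step of the data range
  step <- diff(range(eegSamples(rec))) / 65535
  expect_lt(max(abs(eegSamples(back) - eegSamples(rec))), step)
})

test_that("a simple fixture round-trips exactly 1000 samples at 100 Hz", {
  rec <- EEGRecording(sin(2 * pi * 5 * (0:999) / 100), rate = 100, id = "tiny")
  td <- withr::local_tempdir()
  writeEDF(rec, Hypnogram(rep("W", 1)), file.path(td, "tiny-PSG.edf"))
  back <- readRecording(file.path(td, "tiny-PSG.edf"))
  expect_length(eegSamples(back), 1000)
  expect_equal(samplingRate(back), 100)
})

test_that("requesting an absent channel names the available channels", {
  rec <- EEGRecording(rnorm(3000), channel = "EEG Pz-Oz", id = "c1")
  td <- withr::local_tempdir()
  writeEDF(rec, Hypnogram("W"), file.path(td, "c1-PSG.edf"))
  expect_error(readRecording(file.path(td, "c1-PSG.edf"), "EEG Fpz-Cz"),
               "EEG Pz-Oz")
  ## the correct label selects the channel
  expect_equal(readRecording(file.path(td, "c1-PSG.edf"), "EEG Pz-Oz")@channel,
               "EEG Pz-Oz")
  expect_error(readRecording(file.path(td, "nope.edf")), "not found")
})

test_that("empty recordings are rejected on write", {
  rec <- EEGRecording(0, rate = 100)
  expect_error(writeEDF(rec, Hypnogram("W"), tempfile(fileext = ".edf")),
               "shorter than")
})

test_that("hypnogram annotations expand, validate and round-trip", {
  hyp <- Hypnogram(c("W", "W", "N1", "N2", "SWS", "SWS", "REM", "N2", "N2", "W"))
  td <- withr::local_tempdir()
  p <- file.path(td, "h.edf")
  somnoboost:::writeEdfAnnotations(hyp, p, totalDuration = 300)
  raw <- readHypnogram(p)
  expect_s3_class(raw, "RawHypnogram")
  ## durations are run-length compressed; expansion recovers the epochs
  lab <- somnoboost:::expandRawHypnogram(raw)
  lab[lab == "N3"] <- "SWS"
  expect_identical(lab, stageLabels(hyp))
  expect_false(is.unsorted(raw$onset))

  ## the TSV dialect reads back identically
  tsv <- file.path(td, "h.tsv")
  writeHypnogramTSV(hyp, tsv)
  raw2 <- readHypnogram(tsv)
  expect_identical(somnoboost:::expandRawHypnogram(raw2), stageLabels(hyp))
})

test_that("invalid annotation durations and overlaps are rejected with location", {
  td <- withr::local_tempdir()
  ## a 45-s annotation is not a multiple of the 30-s epoch
  bad45 <- file.path(td, "d45.edf")
  somnoboost:::writeEdfAnnotations(Hypnogram("W", epochLength = 45), bad45,
                                   totalDuration = 45)
  expect_error(readHypnogram(bad45), "multiple of 30")

  ## overlapping entries are refused with their location
  ov <- file.path(td, "ov.edf")
  h <- Hypnogram(c("W", "N1"))
  raw <- asRawHypnogram(h)
  raw$onset[2] <- 15  # force overlap, keep 30-s durations
  tmp <- Hypnogram(c("W", "N1"))
  ## write by hand through the TAL writer path
  tals <- c("+0\x14\x14", sprintf("+%g\x15%g\x14%s\x14", raw$onset, raw$duration,
                                  c("Sleep stage W", "Sleep stage 1")))
  blob <- unlist(lapply(tals, function(t) c(charToRaw(t), as.raw(0L))))
  if (length(blob) %% 2 == 1) blob <- c(blob, as.raw(0))
  con <- file(ov, "wb")
  writeChar(paste0(
    formatC("0", width = -8), formatC("", width = -80),
    formatC("Startdate", width = -80), formatC("01.01.00", width = -8),
    formatC("00.00.00", width = -8), formatC("512", width = -8),
    formatC("EDF+C", width = -44), formatC("1", width = -8),
    formatC("60", width = -8), formatC("1", width = -4),
    formatC("EDF Annotations", width = -16), formatC("", width = -80),
    formatC("", width = -8), formatC("0", width = -8), formatC("1", width = -8),
    formatC("-32768", width = -8), formatC("32767", width = -8),
    formatC("", width = -80), formatC(length(blob) / 2, width = -8),
    formatC("", width = -32)), con, eos = NULL)
  writeBin(blob, con); close(con)
  expect_error(readHypnogram(ov), "overlap")

  expect_error(readHypnogram(tempfile()), "not found")
})

test_that("the raw label alphabet survives reading, including '?'", {
  td <- withr::local_tempdir()
  tsv <- file.path(td, "q.tsv")
  writeLines(c("0\tW", "1\t?", "2\tN3"), tsv)
  raw <- readHypnogram(tsv)
  expect_identical(raw$label, c("W", "?", "N3"))
  expect_identical(somnoboost:::expandRawHypnogram(raw), c("W", "?", "N3"))
})

test_that("harmonise maps N3/N4 to SWS, drops ungraded epochs and trims wake", {
  spe <- 3000
  mkraw <- function(labels) {
    out <- data.frame(onset = (seq_along(labels) - 1) * 30, duration = 30,
                      label = labels, stringsAsFactors = FALSE)
    class(out) <- c("RawHypnogram", "data.frame")
    out
  }
  labels <- c("W", "N3", "N4", "?", "REM", "MOVEMENT", "N2", "W")
  rec <- EEGRecording(seq_len(length(labels) * spe), rate = 100, id = "h1")
  h <- harmonise(rec, mkraw(labels), wakeBuffer = 30)
  expect_identical(stageLabels(h$hypnogram),
                   c("W", "SWS", "SWS", "REM", "N2", "W"))
  ## signal cropped consistently: epochs x 3000 samples
  expect_length(eegSamples(h$recording), nEpochs(h$hypnogram) * spe)
  ## dropped epochs removed their exact signal chunks
  expect_equal(eegSamples(h$recording)[spe + 1], spe + 1)   # N3 epoch kept
  expect_equal(eegSamples(h$recording)[3 * spe + 1], 4 * spe + 1) # ? skipped

  ## 120 leading W epochs with a 30-min buffer keep 60 of them
  labels2 <- c(rep("W", 120), "N2", "N2")
  rec2 <- EEGRecording(rnorm(122 * spe), rate = 100, id = "h2")
  h2 <- harmonise(rec2, mkraw(labels2), wakeBuffer = 30)
  expect_identical(stageLabels(h2$hypnogram), c(rep("W", 60), "N2", "N2"))

  ## all-wake input cannot anchor trimming
  rec3 <- EEGRecording(rnorm(4 * spe), rate = 100)
  expect_error(harmonise(rec3, mkraw(rep("W", 4))), "non-W")

  ## unknown labels are refused
  expect_error(harmonise(rec3, mkraw(c("W", "XX", "N2", "W"))), "alphabet")
})

test_that("harmonise is idempotent and length-mismatches truncate with warning", {
  hyp <- simulateHypnogram(30, seed = 9)
  rec <- simulateRecording(hyp, seed = 9, id = "idem")
  h1 <- harmonise(rec, asRawHypnogram(hyp))
  h2 <- harmonise(h1$recording, asRawHypnogram(h1$hypnogram))
  expect_identical(stageLabels(h2$hypnogram), stageLabels(h1$hypnogram))
  expect_equal(eegSamples(h2$recording), eegSamples(h1$recording))
  expect_true(all(stageLabels(h1$hypnogram) %in% sleepStages()))

  longRec <- EEGRecording(rnorm(40 * 3000), rate = 100)
  expect_warning(harmonise(longRec, asRawHypnogram(hyp)), "truncating")
})
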
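#' Canonical sleep-stage alphabet
#'
#' The five AASM-style classes used throughout the package, in fixed order.
#' Internally stages are encoded as integers `W = 0`, `N1 = 1`, `N2 = 2`,
#' `SWS = 3`, `REM = 4`; `SWS` merges the R&K stages N3 and N4.
#'
#' @return Character vector `c("W","N1","N2","SWS","REM")`.
#' @export
sleepStages <- function() c("W", "N1", "N2", "SWS", "REM")

## raw (pre-harmonisation) label alphabet as found in hypnogram files
rawStageAlphabet <- function() c("W", "N1", "N2", "N3", "N4", "SWS", "REM", "?", "MOVEMENT")

#' Map stage labels to integer codes and back
#'
#' @param stages character vector of canonical stage labels.
#' @param codes integer vector in 0..4.
#' @return `stageToCode`: integer codes (W=0 .. REM=4); `codeToStage`: labels.
#' @export
stageToCode <- function(stages) {
  idx <- match(as.character(stages), sleepStages())
  if (anyNA(idx)) {
    bad <- unique(as.character(stages)[is.na(idx)])
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  }
  idx - 1L
}

#' @rdname stageToCode
#' @export
codeToStage <- function(codes) {
  codes <- as.integer(codes)
  if (any(codes < 0L | codes > 4L)) stop("stage codes must lie in 0..4")
  sleepStages()[codes + 1L]
}

#' EEGRecording: one channel of EEG samples with subject metadata
#'
#' Container for a single-channel EEG signal in microvolts together with its
#' sampling rate and the subject metadata (age, sex, identifier) consumed by
#' the feature extractor.
#'
#' @slot samples numeric vector of amplitudes (uV).
#' @slot rate sampling rate in Hz (samples per second).
#' @slot channel channel label, e.g. `"EEG Pz-Oz"`.
#' @slot age subject age in years.
#' @slot sex subject sex label (`"F"`, `"M"` or `"X"`).
#' @slot id recording identifier.
#' @export
setClass("EEGRecording",
  representation(samples = "numeric", rate = "numeric", channel = "character",
                 age = "numeric", sex = "character", id = "character"),
  prototype(samples = numeric(), rate = 100, channel = "EEG",
            age = 30, sex = "X", id = "rec"))

setValidity("EEGRecording", function(object) {
  msg <- character()
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "rate must be a single positive number")
  if (length(object@samples) < 1L)
    msg <- c(msg, "samples must contain at least one value")
  if (length(object@age) != 1L || is.na(object@age) || object@age < 0)
    msg <- c(msg, "age must be a single non-negative number")
  if (anyNA(object@samples))
    msg <- c(msg, "samples must not contain NA")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecording
#'
#' @param samples numeric vector of amplitudes (uV).
#' @param rate sampling rate (Hz), default 100.
#' @param channel channel label.
#' @param age subject age (years).
#' @param sex subject sex label.
#' @param id recording identifier.
#' @return An [EEGRecording-class] object.
#' @examples
#' rec <- EEGRecording(sin(2 * pi * 10 * (0:2999) / 100), rate = 100)
#' samplingRate(rec)
#' @export
EEGRecording <- function(samples, rate = 100, channel = "EEG", age = 30,
                         sex = "X", id = "rec") {
  methods::new("EEGRecording", samples = as.numeric(samples), rate = as.numeric(rate),
               channel = as.character(channel), age = as.numeric(age),
               sex = as.character(sex), id = as.character(id))
}

#' Hypnogram: per-epoch sleep-stage labels
#'
#' An ordered sequence of canonical stage labels, one per 30-second epoch,
#' aligned to a recording.
#'
#' @slot stages factor with levels `sleepStages()`, one entry per epoch.
#' @slot epochLength epoch duration in seconds (fixed at 30).
#' @export
setClass("Hypnogram",
  representation(stages = "factor", epochLength = "numeric"),
  prototype(stages = factor(character(), levels = c("W","N1","N2","SWS","REM")),
            epochLength = 30))

setValidity("Hypnogram", function(object) {
  msg <- character()
  if (!identical(levels(object@stages), sleepStages()))
    msg <- c(msg, "stages must be a factor with levels W, N1, N2, SWS, REM")
  if (anyNA(object@stages))
    msg <- c(msg, "stages must not contain NA")
  if (length(object@epochLength) != 1L || object@epochLength <= 0)
    msg <- c(msg, "epochLength must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a Hypnogram
#'
#' @param stages character vector (or factor) of canonical stage labels.
#' @param epochLength epoch duration in seconds.
#' @return A [Hypnogram-class] object.
#' @examples
#' Hypnogram(c("W", "N1", "N2", "SWS", "REM", "N2"))
#' @export
Hypnogram <- function(stages, epochLength = 30) {
  methods::new("Hypnogram",
               stages = factor(as.character(stages), levels = sleepStages()),
               epochLength = as.numeric(epochLength))
}

#' CVReport: cross-validated experiment results
#'
#' Holds the per-fold metric table, per-fold confusion matrices, per-fold
#' logloss curves, the resolved hyperparameters and the seeds of one
#' cross-validated classification experiment.
#'
#' @slot folds data.frame with one row per fold (accuracy, f1, precision,
#'   recall, kappa).
#' @slot summary named numeric vector of fold means per metric.
#' @slot confusion list of 5x5 confusion matrices, rows = true stage.
#' @slot auc data.frame of one-vs-rest AUC per class per fold.
#' @slot curves list of per-fold train/test logloss curves (data.frames).
#' @slot params resolved hyperparameter list.
#' @slot mode experiment tag, `"default"` or `"pso"`.
#' @slot seed the master seed of the run.
#' @slot history PSO search history (data.frame; empty for default mode).
#' @export
setClass("CVReport",
  representation(folds = "data.frame", summary = "numeric", confusion = "list",
                 auc = "data.frame", curves = "list", params = "list",
                 mode = "character", seed = "numeric", history = "data.frame"))

setValidity("CVReport", function(object) {
  msg <- character()
  need <- c("accuracy", "f1", "precision", "recall", "kappa")
  if (!all(need %in% names(object@folds)))
    msg <- c(msg, "folds must contain accuracy, f1, precision, recall, kappa")
  if (nrow(object@folds) > 0L) {
    m <- vapply(object@folds[need], mean, numeric(1))
    if (!isTRUE(all.equal(unname(m), unname(object@summary[need]), tolerance = 1e-12)))
      msg <- c(msg, "summary must equal the arithmetic mean of the fold rows")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording '%s' | channel %s | %d samples @ %g Hz (%.1f min) | age %g, sex %s\n",
              object@id, object@channel, length(object@samples), object@rate,
              length(object@samples) / object@rate / 60, object@age, object@sex))
})

setMethod("show", "Hypnogram", function(object) {
  tab <- table(object@stages)
  cat(sprintf("Hypnogram | %d epochs of %g s\n", length(object@stages), object@epochLength))
  cat("  ", paste(sprintf("%s:%d", names(tab), as.integer(tab)), collapse = "  "), "\n")
})

setMethod("show", "CVReport", function(object) {
  cat(sprintf("CVReport (%s mode, %d folds, seed %g)\n", object@mode,
              nrow(object@folds), object@seed))
  cat("  mean:", paste(sprintf("%s=%.3f", names(object@summary), object@summary),
                       collapse = "  "), "\n")
})

#' Accessors for somnoboost containers
#'
#' @param x an [EEGRecording-class], [Hypnogram-class] or [CVReport-class].
#' @return `eegSamples`: numeric vector; `samplingRate`: Hz; `subjectAge`:
#'   years; `recordingId`: character; `stageLabels`: character vector of
#'   per-epoch stages; `nEpochs`: integer; `foldTable`: per-fold metric
#'   data.frame; `reportSummary`: named numeric vector of fold means.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("eegSamples", function(x) standardGeneric("eegSamples"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("subjectAge", function(x) standardGeneric("subjectAge"))
#' @rdname accessors
#' @export
setGeneric("recordingId", function(x) standardGeneric("recordingId"))
#' @rdname accessors
#' @export
setGeneric("stageLabels", function(x) standardGeneric("stageLabels"))
#' @rdname accessors
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))
#' @rdname accessors
#' @export
setGeneric("foldTable", function(x) standardGeneric("foldTable"))
#' @rdname accessors
#' @export
setGeneric("reportSummary", function(x) standardGeneric("reportSummary"))

#' @rdname accessors
#' @export
setMethod("eegSamples", "EEGRecording", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("samplingRate", "EEGRecording", function(x) x@rate)
#' @rdname accessors
#' @export
setMethod("subjectAge", "EEGRecording", function(x) x@age)
#' @rdname accessors
#' @export
setMethod("recordingId", "EEGRecording", function(x) x@id)
#' @rdname accessors
#' @export
setMethod("stageLabels", "Hypnogram", function(x) as.character(x@stages))
#' @rdname accessors
#' @export
setMethod("nEpochs", "Hypnogram", function(x) length(x@stages))
#' @rdname accessors
#' @export
setMethod("foldTable", "CVReport", function(x) x@folds)
#' @rdname accessors
#' @export
setMethod("reportSummary", "CVReport", function(x) x@summary)

## seeded evaluation without disturbing the caller's RNG state
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  eval.parent(substitute(expr))
}

## derive a child seed from a master seed and a stream tag (kept < 2^31)
childSeed <- function(seed, tag) {
  (as.numeric(seed) * 7919 + sum(utf8ToInt(tag)) * 104729) %% 2147483647
}
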
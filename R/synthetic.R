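## Synthetic EEG generator: seeded recordings and hypnograms with
## stage-dependent spectral structure (delta-dominant SWS, sigma spindles in
## N2, alpha/beta wake, theta N1, mixed REM), 1/f background noise, stage
## transients, subject age metadata, and Markov stage persistence.

#' Default stage-transition matrix
#'
#' A persistence-heavy (diagonal-dominant) 5x5 stochastic matrix loosely
#' shaped like overnight stage dynamics: wake runs, N1 as a transient
#' gateway stage, N2 as the hub, SWS and REM as persistent excursions.
#'
#' @return 5x5 matrix with rows/columns in [sleepStages()] order, rows sum 1.
#' @export
defaultTransitionMatrix <- function() {
  m <- matrix(c(
    0.85, 0.12, 0.01, 0.00, 0.02,   # W
    0.06, 0.62, 0.24, 0.00, 0.08,   # N1
    0.01, 0.05, 0.79, 0.10, 0.05,   # N2
    0.00, 0.01, 0.14, 0.83, 0.02,   # SWS
    0.02, 0.08, 0.05, 0.00, 0.85),  # REM
    nrow = 5, byrow = TRUE, dimnames = list(sleepStages(), sleepStages()))
  m
}

#' Stage-conditional spectral profiles
#'
#' Per stage: sinusoidal band amplitudes (uV), the 1/f background exponent
#' and scale, and the N2 transients (sigma spindle bursts and a K-complex
#' pulse). The `"easy"` preset separates stages strongly; `"hard"` shrinks
#' the amplitude contrasts and doubles the background noise.
#'
#' @param preset `"easy"` or `"hard"`.
#' @return Named list (one element per stage) of profile lists.
#' @export
defaultStageProfiles <- function(preset = c("easy", "hard")) {
  preset <- match.arg(preset)
  prof <- list(
    W   = list(bands = c(alpha = 20, beta1 = 10)),
    N1  = list(bands = c(theta = 15)),
    N2  = list(bands = c(theta = 8), spindleAmp = 15, spindleFreq = 13.5,
               spindleCount = 2, kcomplexAmp = 40, kcomplexFreq = 0.7),
    SWS = list(bands = c(delta = 40)),
    REM = list(bands = c(theta = 10, beta2 = 8)))
  scale <- if (preset == "easy") 1 else 0.5
  noise <- if (preset == "easy") 15 else 30
  for (s in names(prof)) {
    prof[[s]]$bands <- prof[[s]]$bands * scale
    if (!is.null(prof[[s]]$spindleAmp)) prof[[s]]$spindleAmp <- prof[[s]]$spindleAmp * scale
    if (!is.null(prof[[s]]$kcomplexAmp)) prof[[s]]$kcomplexAmp <- prof[[s]]$kcomplexAmp * scale
    prof[[s]]$noiseExponent <- 1
    prof[[s]]$noiseScale <- noise
  }
  prof
}

#' Simulate a hypnogram as a Markov chain
#'
#' @param nEpochs number of 30-s epochs.
#' @param transition 5x5 stochastic matrix in [sleepStages()] order.
#' @param init initial distribution over stages (default: start awake).
#' @param seed RNG seed.
#' @return A [Hypnogram-class].
#' @export
simulateHypnogram <- function(nEpochs, transition = defaultTransitionMatrix(),
                              init = c(1, 0, 0, 0, 0), seed = 1) {
  if (!is.matrix(transition) || !all(dim(transition) == 5) ||
      any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-9))
    stop("transition must be a 5x5 stochastic matrix (rows sum to 1)")
  stages <- integer(nEpochs)
  withSeed(seed, {
    stages[1] <- sample.int(5, 1, prob = init)
    for (i in seq_len(nEpochs - 1L))
      stages[i + 1L] <- sample.int(5, 1, prob = transition[stages[i], ])
  })
  Hypnogram(sleepStages()[stages])
}

## band-centre frequencies for the sinusoidal components
bandCentres <- function(bands = defaultBands()) {
  stats::setNames((bands$low + bands$high) / 2, bands$key)
}

## one epoch of 1/f^exponent noise with the requested RMS
pinkNoise <- function(n, exponent, rms) {
  half <- n %/% 2
  f <- seq_len(half) / n
  mag <- f^(-exponent / 2)
  phase <- stats::runif(half, 0, 2 * pi)
  spec <- complex(modulus = mag, argument = phase)
  full <- c(0, spec, Conj(rev(spec[seq_len(half - 1L)])))
  x <- Re(stats::fft(full, inverse = TRUE))
  x <- x[seq_len(n)]
  x * rms / sqrt(mean(x^2))
}

#' Simulate a recording for a given hypnogram
#'
#' Each epoch is a sum of band-limited oscillations (random-phase sinusoids
#' at the band centre with +/- 20% frequency jitter and +/- 20% amplitude
#' jitter, amplitudes per the stage profile), 1/f background noise, and the
#' stage transients (N2 spindle bursts and a K-complex pulse). Phase is not
#' continuous across epochs.
#'
#' @param hypnogram a [Hypnogram-class].
#' @param profiles stage profiles as from [defaultStageProfiles()].
#' @param rate sampling rate (Hz), default 100.
#' @param seed RNG seed.
#' @param age,sex,id subject metadata for the returned recording.
#' @param amplitudeScale global subject amplitude factor (emulates
#'   inter-subject amplitude differences; removed again by normalisation).
#' @return An [EEGRecording-class] of `nEpochs * 30 * rate` samples.
#' @export
simulateRecording <- function(hypnogram, profiles = defaultStageProfiles(),
                              rate = 100, seed = 1, age = 30, sex = "X",
                              id = "synthetic", amplitudeScale = 1) {
  stages <- stageLabels(hypnogram)
  missing <- setdiff(unique(stages), names(profiles))
  if (length(missing)) stop("no profile for stage(s): ", paste(missing, collapse = ", "))
  spe <- as.integer(rate * 30)
  t <- (seq_len(spe) - 1) / rate
  centres <- bandCentres()
  halfWidths <- with(defaultBands(), stats::setNames((high - low) / 2, key))
  out <- vector("list", length(stages))
  withSeed(seed, {
    for (i in seq_along(stages)) {
      p <- profiles[[stages[i]]]
      x <- numeric(spe)
      for (bk in names(p$bands)) {
        a <- p$bands[[bk]]
        if (a <= 0) next
        f0 <- centres[[bk]] + stats::runif(1, -0.2, 0.2) * halfWidths[[bk]]
        x <- x + a * stats::runif(1, 0.8, 1.2) *
          sin(2 * pi * f0 * t + stats::runif(1, 0, 2 * pi))
      }
      if (!is.null(p$spindleAmp) && p$spindleAmp > 0) {
        for (b in seq_len(p$spindleCount)) {
          len <- as.integer(rate)        # 1-s burst
          start <- sample.int(spe - len, 1)
          w <- 0.54 - 0.46 * cos(2 * pi * seq(0, len - 1) / (len - 1))
          burst <- p$spindleAmp * w *
            sin(2 * pi * p$spindleFreq * t[seq_len(len)] + stats::runif(1, 0, 2 * pi))
          x[start:(start + len - 1L)] <- x[start:(start + len - 1L)] + burst
        }
      }
      if (!is.null(p$kcomplexAmp) && p$kcomplexAmp > 0) {
        len <- as.integer(round(rate / p$kcomplexFreq))  # one biphasic cycle
        start <- sample.int(spe - len, 1)
        pulse <- p$kcomplexAmp * sin(2 * pi * p$kcomplexFreq * t[seq_len(len)])
        x[start:(start + len - 1L)] <- x[start:(start + len - 1L)] + pulse
      }
      if (!is.null(p$noiseScale) && p$noiseScale > 0)
        x <- x + pinkNoise(spe, p$noiseExponent, p$noiseScale)
      out[[i]] <- x
    }
  })
  EEGRecording(amplitudeScale * unlist(out, use.names = FALSE), rate = rate,
               channel = "EEG Pz-Oz", age = age, sex = sex, id = id)
}

#' Simulate a multi-subject dataset in memory
#'
#' Ages are drawn uniformly from 20-60 years; each subject gets a global
#' amplitude factor (log-uniform in 0.8-1.25) that the per-recording
#' normalisation must undo.
#'
#' @param nSubjects number of subjects.
#' @param epochsPerSubject epochs per subject.
#' @param preset profile preset, `"easy"` or `"hard"`.
#' @param seed master seed.
#' @param transition stage-transition matrix.
#' @return List of per-subject lists `(recording, hypnogram)`.
#' @export
synthSleepDataset <- function(nSubjects, epochsPerSubject, preset = "easy",
                              seed = 1, transition = defaultTransitionMatrix()) {
  profiles <- defaultStageProfiles(preset)
  lapply(seq_len(nSubjects), function(s) {
    hseed <- childSeed(seed, paste0("hyp", s))
    rseed <- childSeed(seed, paste0("rec", s))
    meta <- withSeed(childSeed(seed, paste0("meta", s)), {
      list(age = sample(20:60, 1), sex = sample(c("F", "M"), 1),
           scale = exp(stats::runif(1, log(0.8), log(1.25))))
    })
    hyp <- simulateHypnogram(epochsPerSubject, transition, seed = hseed)
    rec <- simulateRecording(hyp, profiles, seed = rseed, age = meta$age,
                             sex = meta$sex, id = sprintf("S%02d", s),
                             amplitudeScale = meta$scale)
    list(recording = rec, hypnogram = hyp)
  })
}

#' Write a synthetic EDF fixture set
#'
#' Generates `nSubjects` paired EDF signal + hypnogram files via
#' [writeEDF()] plus a JSON manifest recording the seeds and parameters
#' (byte-identical across runs with the same arguments).
#'
#' @param nSubjects number of subjects.
#' @param epochsPerSubject epochs per subject.
#' @param preset `"easy"` or `"hard"`.
#' @param seed master seed.
#' @param outDir output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
makeFixture <- function(nSubjects, epochsPerSubject, preset = "easy", seed = 1,
                        outDir = ".") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  ds <- synthSleepDataset(nSubjects, epochsPerSubject, preset, seed)
  files <- lapply(seq_along(ds), function(s) {
    psg <- file.path(outDir, sprintf("S%02d-PSG.edf", s))
    writeEDF(ds[[s]]$recording, ds[[s]]$hypnogram, psg)
  })
  manifest <- list(
    generator = "somnoboost synthetic EEG",
    seed = seed, preset = preset, nSubjects = nSubjects,
    epochsPerSubject = epochsPerSubject, rate = 100,
    subjects = lapply(seq_along(ds), function(s)
      list(id = sprintf("S%02d", s), age = subjectAge(ds[[s]]$recording),
           psg = basename(files[[s]][1]), hypnogram = basename(files[[s]][2]))))
  path <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Assemble the full feature matrix of a synthetic dataset
#'
#' Convenience wrapper: extracts features per subject, binds rows, and
#' optionally applies feature shifting.
#'
#' @param dataset list from [synthSleepDataset()].
#' @param shift apply [shiftFeatures()] (default TRUE).
#' @param ... passed to [extractFeatures()].
#' @return Feature matrix data.frame.
#' @export
datasetFeatures <- function(dataset, shift = TRUE, ...) {
  fm <- do.call(rbind, lapply(dataset, function(d)
    extractFeatures(d$recording, d$hypnogram, ...)))
  if (shift) fm <- shiftFeatures(fm) else fm
}
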
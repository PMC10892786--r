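## Feature-matrix assembly: the 52-column per-epoch feature vector, +/- 1
## epoch feature shifting to 154 columns, stratified fold plans, and
## training-fold oversampling.

#' Names of the 52 feature columns
#'
#' Fixed order: age, 24 whole-epoch features, then per-band energy, power
#' and peak-to-peak amplitude for the nine sub-bands.
#'
#' @param bands band table (defines the 9 band keys).
#' @return Character vector of length 52.
#' @export
sleepFeatureNames <- function(bands = defaultBands()) {
  c("age", "mean", "median", "amv", "variance", "skewness", "kurtosis",
    "rms", "ppa", "entropy", "perm_entropy", "spectral_entropy",
    "svd_entropy", "sample_entropy", "kfd", "hfd", "zcr", "dfa", "hurst",
    "mmd", "lzc", "hjorth_mobility", "hjorth_complexity", "psd", "pfd",
    paste0("energy_", bands$key), paste0("power_", bands$key),
    paste0("amp_", bands$key))
}

#' Default feature-extraction parameters
#'
#' Literature-default settings for the features whose tuning knobs are not
#' implied by the data: histogram entropy bins, permutation-entropy
#' order/delay, SVD embedding, sample-entropy template length and
#' tolerance, MMD window (1 s), Higuchi kMax, and Welch segmenting.
#'
#' @return Named list of parameters.
#' @export
featureParams <- function() {
  list(entropyBins = 10, permOrder = 3, permDelay = 1,
       svdDim = 10, svdDelay = 1, sampenM = 2, sampenR = 0.2,
       mmdWindowSec = 1, hfdKmax = 10, welchSegSec = 4, welchOverlap = 0.5)
}

#' Compute the 52 features of one epoch
#'
#' @param epoch numeric vector (one normalised 30-s epoch).
#' @param rate sampling rate (Hz).
#' @param age subject age (years); enters the vector as the `age` feature.
#' @param bands band table as from [defaultBands()].
#' @param params parameter list as from [featureParams()].
#' @return Named numeric vector of length 52 in [sleepFeatureNames()] order.
#' @export
epochFeatures <- function(epoch, rate = 100, age = 30, bands = defaultBands(),
                          params = featureParams()) {
  bs <- basicStats(epoch)
  hj <- hjorthParams(epoch)
  spec <- welchPSD(epoch, rate = rate, segLength = params$welchSegSec * rate,
                   overlap = params$welchOverlap)
  fd <- fractalDims(epoch, kMax = params$hfdKmax)
  lr <- longRange(epoch)
  subs <- subbandDecompose(epoch, rate = rate, bands = bands)
  out <- c(
    age = age,
    mean = unname(bs["mean"]), median = unname(bs["median"]),
    amv = unname(bs["amv"]), variance = unname(bs["variance"]),
    skewness = unname(bs["skewness"]), kurtosis = unname(bs["kurtosis"]),
    rms = unname(bs["rms"]), ppa = bandPPA(epoch),
    entropy = shannonEntropy(epoch, bins = params$entropyBins),
    perm_entropy = permutationEntropy(epoch, order = params$permOrder,
                                      delay = params$permDelay),
    spectral_entropy = spectralEntropy(epoch, rate = rate,
                                       segLength = params$welchSegSec * rate,
                                       overlap = params$welchOverlap),
    svd_entropy = svdEntropy(epoch, embedDim = params$svdDim,
                             embedDelay = params$svdDelay),
    sample_entropy = as.numeric(sampleEntropy(epoch, m = params$sampenM,
                                              rFactor = params$sampenR)),
    kfd = unname(fd["kfd"]), hfd = unname(fd["hfd"]),
    zcr = zeroCrossingRate(epoch),
    dfa = unname(lr["dfa"]), hurst = unname(lr["hurst"]),
    mmd = maxMinDistance(epoch, window = params$mmdWindowSec * rate),
    lzc = lempelZiv(epoch),
    hjorth_mobility = unname(hj["mobility"]),
    hjorth_complexity = unname(hj["complexity"]),
    psd = totalPSDFeature(spec),
    pfd = unname(fd["pfd"]))
  energies <- vapply(subs, bandEnergy, numeric(1))
  powers <- vapply(seq_len(nrow(bands)), function(i)
    bandPower(spec, bands$low[i], bands$high[i]), numeric(1))
  amps <- vapply(subs, bandPPA, numeric(1))
  out <- c(out, stats::setNames(energies, paste0("energy_", bands$key)),
           stats::setNames(powers, paste0("power_", bands$key)),
           stats::setNames(amps, paste0("amp_", bands$key)))
  out[sleepFeatureNames(bands)]
}

#' Extract the feature matrix of one recording
#'
#' Runs the preprocessing chain (band-pass, 30-s segmentation,
#' per-recording z-scoring) and assembles the 52 named features for every
#' epoch. Any non-finite feature value aborts with the feature name and
#' epoch index.
#'
#' @param recording an [EEGRecording-class].
#' @param hypnogram optional [Hypnogram-class] supplying per-epoch stage
#'   labels; must cover at least the segmented epochs.
#' @param bands band table.
#' @param params parameter list as from [featureParams()].
#' @param filter logical: apply the 0.5-49.5 Hz band-pass first (default).
#' @return A data.frame with columns `recording_id`, `epoch` (1-based),
#'   `stage` (label or NA) and the 52 feature columns.
#' @export
extractFeatures <- function(recording, hypnogram = NULL, bands = defaultBands(),
                            params = featureParams(), filter = TRUE) {
  rate <- samplingRate(recording)
  if (filter) recording <- bandpass(recording)
  epochs <- segmentEpochs(recording)
  epochs <- normaliseEpochs(epochs)
  n <- length(epochs)
  stages <- rep(NA_character_, n)
  if (!is.null(hypnogram)) {
    if (nEpochs(hypnogram) < n)
      stop("hypnogram (", nEpochs(hypnogram), " epochs) shorter than the recording (",
           n, " epochs)")
    stages <- stageLabels(hypnogram)[seq_len(n)]
  }
  age <- subjectAge(recording)
  rows <- matrix(NA_real_, n, 52,
                 dimnames = list(NULL, sleepFeatureNames(bands)))
  for (i in seq_len(n)) {
    v <- tryCatch(epochFeatures(epochs[[i]], rate = rate, age = age,
                                bands = bands, params = params),
                  error = function(e) stop("epoch ", i, " of recording '",
                                           recordingId(recording), "': ",
                                           conditionMessage(e), call. = FALSE))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("non-finite feature '", names(v)[bad[1]], "' in epoch ", i,
           " of recording '", recordingId(recording), "'")
    rows[i, ] <- v
  }
  out <- data.frame(recording_id = recordingId(recording), epoch = seq_len(n),
                    stage = stages, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(rows))
}

featureCols <- function(fm) setdiff(names(fm), c("recording_id", "epoch", "stage"))

#' Add lagged and led copies of the feature columns
#'
#' For every non-age feature column, appends a one-epoch-back (`.lag1`) and
#' a one-epoch-forward (`.lead1`) copy (and deeper context for `m > 1`),
#' giving each epoch its neighbours' features as temporal context:
#' `3 * 51 + 1 = 154` feature columns for the 52-column input at `m = 1`.
#' Shifting never crosses recording boundaries; at a recording's ends the
#' missing context is filled by replicating that recording's terminal row.
#'
#' @param fm feature matrix from [extractFeatures()] (rows in temporal order
#'   within each recording).
#' @param m context depth in epochs (default 1).
#' @return The feature matrix with shifted columns appended.
#' @export
shiftFeatures <- function(fm, m = 1) {
  feats <- setdiff(featureCols(fm), "age")
  groups <- split(seq_len(nrow(fm)), fm$recording_id)
  for (g in groups) {
    if (is.unsorted(fm$epoch[g], strictly = TRUE))
      stop("rows must be in temporal order within each recording")
  }
  shifted <- list()
  for (s in seq_len(m)) {
    for (f in feats) {
      lag <- lead <- fm[[f]]
      for (g in groups) {
        v <- fm[[f]][g]
        ng <- length(v)
        lag[g] <- v[pmax(seq_len(ng) - s, 1L)]
        lead[g] <- v[pmin(seq_len(ng) + s, ng)]
      }
      shifted[[paste0(f, ".lag", s)]] <- lag
      shifted[[paste0(f, ".lead", s)]] <- lead
    }
  }
  cbind(fm, as.data.frame(shifted))
}

#' Stratified fold assignment
#'
#' Deterministic given the seed: within every class the rows are shuffled
#' and dealt round-robin over the k folds, so per-fold class counts differ
#' from exact proportionality by at most one row per class.
#'
#' @param labels vector of class labels (one per row).
#' @param k number of folds (default 10).
#' @param seed RNG seed.
#' @return Integer vector of fold ids in `1..k` with attribute `seed`.
#' @export
stratifiedFolds <- function(labels, k = 10, seed = 1) {
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < k))
    stop("class '", names(tab)[which.min(tab)], "' has ", min(tab),
         " rows, fewer than k = ", k)
  folds <- integer(length(labels))
  withSeed(seed, {
    for (cl in names(tab)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  attr(folds, "seed") <- seed
  folds
}

#' Oversample training rows to class balance
#'
#' Random duplication with replacement of minority-class rows up to the
#' majority count; intended for training folds only — never apply it before
#' splitting. Already-balanced input is returned unchanged (as a multiset).
#'
#' @param labels vector of training-row class labels.
#' @param seed RNG seed.
#' @return Integer vector of row indices into the training set (original
#'   rows first, then sampled duplicates).
#' @export
balanceTraining <- function(labels, seed = 1) {
  labels <- as.character(labels)
  if (!length(labels)) stop("empty label vector")
  tab <- table(labels)
  if (any(tab == 0)) stop("empty class")
  target <- max(tab)
  extra <- integer(0)
  withSeed(seed, {
    for (cl in names(tab)) {
      need <- target - tab[[cl]]
      if (need > 0) {
        idx <- which(labels == cl)
        extra <- c(extra, idx[sample.int(length(idx), need, replace = TRUE)])
      }
    }
  })
  c(seq_along(labels), extra)
}
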
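## Preprocessing: FIR band-pass filtering, 30-s epoching, per-recording
## z-scoring, and decomposition of each epoch into nine analysis sub-bands.

#' Default analysis sub-bands
#'
#' The nine EEG sub-bands used for feature extraction: delta 0.5-4, theta
#' 4-8, alpha 9-11 (adult range), sigma 12-15, beta1 14-20, beta2 20-30,
#' gamma1 30-40, gamma2 40-49.5 and the K-complex band 0.5-1 Hz (which
#' deliberately overlaps delta).
#'
#' @return A data.frame with columns `name`, `key` (ASCII identifier used in
#'   feature-column names), `low` and `high` (Hz).
#' @export
defaultBands <- function() {
  data.frame(
    name = c("δ", "θ", "α", "σ", "β1", "β2",
             "γ1", "γ2", "K-complex"),
    key = c("delta", "theta", "alpha", "sigma", "beta1", "beta2",
            "gamma1", "gamma2", "kcomplex"),
    low = c(0.5, 4, 9, 12, 14, 20, 30, 40, 0.5),
    high = c(4, 8, 11, 15, 20, 30, 40, 49.5, 1),
    stringsAsFactors = FALSE)
}

#' Read a band table from a config file
#'
#' Plain whitespace/tab-separated lines `key low high`, `#` comments allowed.
#'
#' @param path file path.
#' @return A band data.frame as from [defaultBands()].
#' @export
readBandTable <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("key", "low", "high"),
                           stringsAsFactors = FALSE)
  tab$name <- tab$key
  validateBands(tab)
  tab[, c("name", "key", "low", "high")]
}

validateBands <- function(bands) {
  if (any(!is.finite(bands$low) | !is.finite(bands$high) |
          bands$low <= 0 | bands$low >= bands$high))
    stop("invalid band edges: need 0 < low < high for every band")
  invisible(bands)
}

## FIR design cache (keyed by low/high/rate) -- filters are reused across
## epochs, and their FFTs across equal-length inputs.
.firCache <- new.env(parent = emptyenv())

## transition bandwidth rule: narrow enough to respect the band's own width,
## never narrower than 0.5 Hz and never wider than 3 Hz
firTransition <- function(low, high) {
  min(max(0.5, low / 2), (high - low) / 2, 3)
}

firCoefficients <- function(low, high, rate, transition = NULL) {
  if (is.null(transition)) transition <- firTransition(low, high)
  key <- sprintf("%g|%g|%g|%g", low, high, rate, transition)
  hit <- .firCache[[key]]
  if (!is.null(hit)) return(hit)
  order <- ceiling(3.3 * rate / transition)   # hamming-window design rule
  if (order %% 2 == 1) order <- order + 1     # odd tap count => integer group delay
  w <- c(low, high) / (rate / 2)
  b <- signal::fir1(order, w, type = "pass")
  .firCache[[key]] <- b
  b
}

firSpectrum <- function(b, nfft) {
  bkey <- sprintf("B|%d|%.17g|%d|%.17g", nfft, b[1], length(b), sum(b))
  B <- .firCache[[bkey]]
  if (is.null(B)) {
    B <- stats::fft(c(b, rep(0, nfft - length(b))))
    .firCache[[bkey]] <- B
  }
  B
}

## linear-phase FIR applied by FFT convolution with exact group-delay
## compensation, so filtering is zero-phase; output length = input length.
## The signal is edge-padded by sample replication to suppress onset
## transients at the record boundaries.
applyFIR <- function(x, b) {
  n <- length(x); nb <- length(b)
  if (n < nb) stop("signal (", n, " samples) shorter than the filter (", nb, " taps)")
  gd <- (nb - 1L) %/% 2L
  pad <- nb - 1L
  xp <- c(rep(x[1], pad), x, rep(x[n], pad))
  np <- length(xp)
  nfft <- stats::nextn(np + nb - 1L, 2)
  B <- firSpectrum(b, nfft)
  X <- stats::fft(c(xp, rep(0, nfft - np)))
  y <- Re(stats::fft(X * B, inverse = TRUE)) / nfft
  y[(pad + gd + 1L):(pad + gd + n)]
}

#' Band-pass filter a recording
#'
#' Linear-phase FIR band-pass (hamming-window design) applied with
#' group-delay compensation so the output is zero-phase and has the same
#' length as the input. Defaults implement the 0.5-49.5 Hz analysis band.
#'
#' @param recording an [EEGRecording-class].
#' @param low,high passband edges in Hz.
#' @param transition transition bandwidth (Hz); default 0.5.
#' @return A filtered [EEGRecording-class].
#' @export
bandpass <- function(recording, low = 0.5, high = 49.5, transition = 0.5) {
  rate <- samplingRate(recording)
  if (high >= rate / 2) stop("upper passband edge (", high,
                             " Hz) must be below the Nyquist frequency (", rate / 2, " Hz)")
  if (low <= 0 || low >= high) stop("need 0 < low < high")
  b <- firCoefficients(low, high, rate, transition)
  EEGRecording(applyFIR(eegSamples(recording), b), rate = rate,
               channel = recording@channel, age = subjectAge(recording),
               sex = recording@sex, id = recordingId(recording))
}

#' Segment a recording into non-overlapping 30-s epochs
#'
#' @param recording an [EEGRecording-class]; `rate * 30` must be an integer.
#' @return A list of numeric vectors, each of `rate * 30` samples, with
#'   attributes `rate`, `recording_id` and `age` carried on the list.
#'   A trailing remainder shorter than 30 s is dropped.
#' @export
segmentEpochs <- function(recording) {
  rate <- samplingRate(recording)
  spe <- rate * 30
  if (abs(spe - round(spe)) > 1e-9) stop("rate * 30 s must be an integer number of samples")
  spe <- as.integer(round(spe))
  x <- eegSamples(recording)
  n <- length(x) %/% spe
  if (n < 1) stop("recording (", length(x), " samples) shorter than one 30-s epoch (",
                  spe, " samples)")
  epochs <- lapply(seq_len(n), function(i) x[((i - 1L) * spe + 1L):(i * spe)])
  attr(epochs, "rate") <- rate
  attr(epochs, "recording_id") <- recordingId(recording)
  attr(epochs, "age") <- subjectAge(recording)
  epochs
}

#' Normalise epochs by their recording's global mean and SD
#'
#' Z-scores every epoch using the mean and standard deviation pooled over
#' the whole recording (all supplied epochs), equalising amplitude across
#' subjects while preserving within-recording dynamics.
#'
#' @param epochs an epoch list from [segmentEpochs()].
#' @return The epoch list with samples z-scored; attributes preserved.
#' @export
normaliseEpochs <- function(epochs) {
  if (!length(epochs)) stop("no epochs to normalise")
  all <- unlist(epochs, use.names = FALSE)
  mu <- mean(all)
  sdv <- sqrt(mean((all - mu)^2))
  if (sdv == 0) stop("constant recording: zero standard deviation, cannot normalise")
  out <- lapply(epochs, function(e) (e - mu) / sdv)
  attributes(out) <- attributes(epochs)
  out
}

#' Decompose an epoch into band-limited sub-band signals
#'
#' Applies one zero-phase FIR band-pass per band definition and returns the
#' filtered copies, each the same length as the source epoch.
#'
#' @param epoch numeric vector (one epoch of samples).
#' @param rate sampling rate in Hz.
#' @param bands band table as from [defaultBands()].
#' @return A named list (by band `key`) of filtered numeric vectors.
#' @export
subbandDecompose <- function(epoch, rate = 100, bands = defaultBands()) {
  validateBands(bands)
  if (any(bands$high >= rate / 2 + 1e-9))
    stop("band edges must lie below the Nyquist frequency")
  n <- length(epoch)
  out <- vector("list", nrow(bands))
  names(out) <- bands$key
  ## share the padded epoch's forward FFT across all bands
  coefs <- lapply(seq_len(nrow(bands)), function(i)
    firCoefficients(bands$low[i], bands$high[i], rate))
  pad <- max(lengths(coefs)) - 1L
  xp <- c(rep(epoch[1], pad), epoch, rep(epoch[n], pad))
  np <- length(xp)
  nfft <- stats::nextn(np + pad, 2)
  X <- stats::fft(c(xp, rep(0, nfft - np)))
  for (i in seq_len(nrow(bands))) {
    b <- coefs[[i]]
    if (n < length(b)) stop("epoch shorter than the designed filter for band ", bands$key[i])
    gd <- (length(b) - 1L) %/% 2L
    y <- Re(stats::fft(X * firSpectrum(b, nfft), inverse = TRUE)) / nfft
    out[[i]] <- y[(pad + gd + 1L):(pad + gd + n)]
  }
  out
}
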
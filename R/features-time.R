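## Time-domain features: population moments, median, absolute maximum value,
## RMS, zero-crossing rate, Hjorth parameters, per-band energy and
## peak-to-peak amplitude.

#' Basic statistical features of a signal
#'
#' Population conventions throughout: variance with 1/M, skewness
#' (1/M) sum (x - mean)^3 / var^{3/2}, non-excess kurtosis
#' (1/M) sum (x - mean)^4 / var^2 (a Gaussian scores about 3).
#' On a zero-variance signal skewness and kurtosis are reported as 0 and
#' the result carries a `degenerate = TRUE` attribute.
#'
#' @param x numeric vector, length >= 2.
#' @return Named numeric vector: `mean`, `median`, `variance`, `skewness`,
#'   `kurtosis`, `amv` (max absolute value), `rms`.
#' @export
basicStats <- function(x) {
  m <- length(x)
  if (m < 2) stop("need at least 2 samples")
  mu <- mean(x)
  d <- x - mu
  v <- mean(d^2)
  degenerate <- v == 0
  out <- c(mean = mu,
           median = stats::median(x),
           variance = v,
           skewness = if (degenerate) 0 else mean(d^3) / v^1.5,
           kurtosis = if (degenerate) 0 else mean(d^4) / v^2,
           amv = max(abs(x)),
           rms = sqrt(mean(x^2)))
  if (degenerate) attr(out, "degenerate") <- TRUE
  out
}

#' Zero-crossing rate
#'
#' Fraction of consecutive sample pairs whose product is negative, i.e.
#' sign changes between strictly positive and strictly negative values;
#' exact zeros do not count as crossings.
#'
#' @param x numeric vector, length >= 2.
#' @return Rate in `[0, 1]`: crossings / (M - 1).
#' @export
zeroCrossingRate <- function(x) {
  m <- length(x)
  if (m < 2) stop("need at least 2 samples")
  sum(x[-1] * x[-m] < 0) / (m - 1)
}

#' Hjorth mobility and complexity
#'
#' Mobility is `sqrt(var(dx) / var(x))` and complexity
#' `mobility(dx) / mobility(x)`, with `dx` the first difference and
#' population variances; mobility tracks the spectrum's mean frequency and
#' complexity its bandwidth. A signal whose first difference is constant
#' (e.g. a ramp) yields mobility 0 and complexity flagged degenerate (0).
#'
#' @param x numeric vector, length >= 3, non-constant.
#' @return Named numeric vector `mobility`, `complexity`.
#' @export
hjorthParams <- function(x) {
  if (length(x) < 3) stop("need at least 3 samples")
  popVar <- function(v) mean((v - mean(v))^2)
  v0 <- popVar(x)
  if (v0 == 0) stop("zero variance signal: Hjorth parameters undefined")
  d1 <- diff(x)
  v1 <- popVar(d1)
  mob <- sqrt(v1 / v0)
  if (v1 == 0) {
    out <- c(mobility = 0, complexity = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  d2 <- diff(d1)
  v2 <- popVar(d2)
  c(mobility = mob, complexity = sqrt(v2 / v1) / mob)
}

#' Signal energy
#'
#' Sum of squared amplitudes over the epoch (uV^2 x samples); computed per
#' sub-band signal in the feature set.
#'
#' @param x numeric vector.
#' @return `sum(abs(x)^2)`.
#' @export
bandEnergy <- function(x) {
  if (!length(x)) stop("empty signal")
  sum(x^2)
}

#' Peak-to-peak amplitude
#'
#' @param x numeric vector.
#' @return `max(x) - min(x)` (uV).
#' @export
bandPPA <- function(x) {
  if (!length(x)) stop("empty signal")
  max(x) - min(x)
}
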
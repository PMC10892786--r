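## Frequency-domain features: Welch power spectral density, band powers by
## trapezoidal integration, and the total-PSD scalar feature.

#' Welch power spectral density estimate
#'
#' Averaged modified periodogram: the signal is split into overlapping
#' hamming-windowed segments (default 4 s, 50% overlap), each segment is
#' mean-detrended, and the one-sided periodograms are averaged. The density
#' is scaled so that its integral over frequency reproduces the signal
#' variance (Parseval, up to windowing bias).
#'
#' @param x numeric vector (one epoch).
#' @param rate sampling rate in Hz.
#' @param segLength segment length in samples (default `4 * rate`).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return A list of class `WelchPSD`: `frequency` (Hz, 0..Nyquist),
#'   `density` (power per Hz), `segLength`, `overlap`, `window`.
#' @export
welchPSD <- function(x, rate = 100, segLength = 4 * rate, overlap = 0.5) {
  n <- length(x)
  segLength <- as.integer(segLength)
  if (segLength < 8) stop("segment length too short")
  if (n < segLength) stop("epoch (", n, " samples) shorter than the segment length (",
                          segLength, ")")
  step <- max(1L, as.integer(round(segLength * (1 - overlap))))
  starts <- seq(1L, n - segLength + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, segLength - 1) / (segLength - 1))
  scale <- rate * sum(w^2)
  nf <- segLength %/% 2 + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + segLength - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))[seq_len(nf)]^2 / scale
    acc <- acc + p
  }
  dens <- acc / length(starts)
  dens[c(-1, -nf)] <- dens[c(-1, -nf)] * 2   # one-sided: double interior bins
  structure(list(frequency = seq(0, rate / 2, length.out = nf),
                 density = dens, segLength = segLength, overlap = overlap,
                 window = "hamming"),
            class = "WelchPSD")
}

#' @export
print.WelchPSD <- function(x, ...) {
  cat(sprintf("Welch PSD estimate: %d bins, 0-%g Hz (df = %g Hz), %d-sample %s segments, %.0f%% overlap\n",
              length(x$frequency), max(x$frequency),
              x$frequency[2] - x$frequency[1], x$segLength, x$window,
              100 * x$overlap))
  invisible(x)
}

#' Integrated band power from a PSD estimate
#'
#' Trapezoidal integral of the density over `[low, high]`, with linear
#' interpolation of the density at the exact band edges so that adjacent
#' bands tile the spectrum additively.
#'
#' @param spec a `WelchPSD` from [welchPSD()].
#' @param low,high band edges in Hz (within the frequency grid).
#' @return Band power (uV^2).
#' @export
bandPower <- function(spec, low, high) {
  f <- spec$frequency; d <- spec$density
  if (low < f[1] - 1e-9 || high > f[length(f)] + 1e-9 || low >= high)
    stop("band [", low, ", ", high, "] outside the frequency grid")
  inside <- which(f > low & f < high)
  fg <- c(low, f[inside], high)
  dg <- c(stats::approx(f, d, low)$y, d[inside], stats::approx(f, d, high)$y)
  sum(diff(fg) * (utils::head(dg, -1) + utils::tail(dg, -1)) / 2)
}

#' Total power spectral density feature
#'
#' The scalar PSD feature stored in the feature vector: total integrated
#' power over the analysis band (default 0.5-49.5 Hz).
#'
#' @param spec a `WelchPSD`.
#' @param low,high integration limits in Hz.
#' @return Total power (uV^2).
#' @export
totalPSDFeature <- function(spec, low = 0.5, high = 49.5) {
  bandPower(spec, low, high)
}
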
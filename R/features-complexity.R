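## Entropy, complexity, fractal and long-range-dependence features.
## Natural logarithms throughout (values in nats).

#' Histogram (Shannon) entropy of signal amplitudes
#'
#' `-sum(P_i * ln P_i)` with `P_i` estimated by an equal-width amplitude
#' histogram over `[min, max]`; empty bins contribute 0. A constant signal
#' occupies a single bin and scores 0. Because the bin grid follows the
#' observed range, the value is invariant under affine rescaling of the
#' amplitudes and responds only to the *shape* of the amplitude
#' distribution.
#'
#' @param x numeric vector.
#' @param bins number of histogram bins (default 10).
#' @return Entropy in nats.
#' @export
shannonEntropy <- function(x, bins = 10) {
  if (!length(x)) stop("empty signal")
  rng <- range(x)
  if (rng[1] == rng[2]) return(0)
  idx <- pmin(bins, pmax(1L, as.integer(floor((x - rng[1]) / (rng[2] - rng[1]) * bins)) + 1L))
  p <- tabulate(idx, nbins = bins) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

## ordinal pattern codes for permutation entropy: rank of each element within
## its window, ties resolved by temporal order (earlier sample ranks lower)
ordinalPatternCodes <- function(x, order, delay) {
  n <- length(x) - (order - 1L) * delay
  ranks <- matrix(0L, n, order)
  cols <- lapply(seq_len(order), function(j) x[seq_len(n) + (j - 1L) * delay])
  for (j in seq_len(order)) {
    r <- rep(1L, n)
    for (k in seq_len(order)) {
      if (k == j) next
      if (k < j) r <- r + (cols[[k]] <= cols[[j]])
      else r <- r + (cols[[k]] < cols[[j]])
    }
    ranks[, j] <- r
  }
  as.vector(ranks %*% order^(seq_len(order) - 1L))
}

#' Permutation entropy
#'
#' Shannon entropy (nats) of the distribution of ordinal patterns of
#' embedded windows; ties are broken by temporal order of occurrence.
#'
#' @param x numeric vector of length at least `order * delay + 1`.
#' @param order embedding order (window length), default 3.
#' @param delay embedding delay in samples, default 1.
#' @return Entropy in nats, 0 for a strictly monotone signal, at most
#'   `log(factorial(order))`.
#' @export
permutationEntropy <- function(x, order = 3, delay = 1) {
  if (length(x) < order * delay + 1) stop("signal too short for the requested embedding")
  codes <- ordinalPatternCodes(x, as.integer(order), as.integer(delay))
  p <- table(codes) / length(codes)
  -sum(p * log(p))
}

#' Spectral entropy
#'
#' Shannon entropy (nats) of the Welch PSD normalised to a probability
#' distribution over frequency bins; invariant under amplitude scaling.
#'
#' @param x numeric vector (one epoch).
#' @param rate sampling rate in Hz.
#' @param ... passed to [welchPSD()].
#' @return Entropy in nats.
#' @export
spectralEntropy <- function(x, rate = 100, ...) {
  spec <- welchPSD(x, rate = rate, ...)
  tot <- sum(spec$density)
  if (tot == 0) stop("zero total power: spectral entropy undefined")
  p <- spec$density / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Singular value decomposition entropy
#'
#' Shannon entropy (nats) of the normalised singular values of the
#' delay-embedding trajectory matrix; low for low-rank trajectories such as
#' sinusoids, higher for noise.
#'
#' @param x numeric vector, length >= `embedDim`.
#' @param embedDim embedding dimension (default 10).
#' @param embedDelay embedding delay (default 1).
#' @return Entropy in nats.
#' @export
svdEntropy <- function(x, embedDim = 10, embedDelay = 1) {
  d <- as.integer(embedDim); tau <- as.integer(embedDelay)
  n <- length(x) - (d - 1L) * tau
  if (n < 1) stop("signal too short for the requested embedding")
  Y <- vapply(seq_len(d), function(j) x[seq_len(n) + (j - 1L) * tau], numeric(n))
  sv <- svd(Y, nu = 0, nv = 0)$d
  if (sum(sv) == 0) stop("degenerate (all-zero) trajectory matrix")
  p <- sv / sum(sv)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Sample entropy
#'
#' `-ln(A/B)` where `B` counts pairs of length-`m` templates within
#' Chebyshev distance `rFactor * sd(x)` (self-matches excluded) and `A`
#' counts the same pairs still matching at length `m + 1`. When `A` or `B`
#' is zero the value is capped at `log(nt * (nt - 1) / 2)` (the most
#' informative resolvable value for `nt` templates) and flagged with a
#' `capped` attribute.
#'
#' @param x numeric vector, length >= `m + 2`.
#' @param m template length (default 2).
#' @param rFactor tolerance as a fraction of the population SD (default 0.2).
#' @return Non-negative scalar.
#' @export
sampleEntropy <- function(x, m = 2, rFactor = 0.2) {
  n <- length(x)
  if (n < m + 2) stop("signal too short for sample entropy")
  r <- rFactor * sqrt(mean((x - mean(x))^2))
  if (r <= 0) stop("zero tolerance (constant signal): sample entropy undefined")
  ab <- .sampenCounts(as.numeric(x), as.integer(m), r)
  A <- ab[1]; B <- ab[2]
  nt <- n - m
  cap <- log(nt * (nt - 1) / 2)
  if (B == 0 || A == 0) {
    out <- cap
    attr(out, "capped") <- TRUE
    return(out)
  }
  -log(A / B)
}

#' Lempel-Ziv complexity
#'
#' Binarises the signal at its median (`x >= median -> 1`) and parses the
#' binary string with the LZ76 exhaustive-history scheme; the complexity is
#' the number of parsed words. Invariant under amplitude scaling.
#'
#' @param x numeric vector.
#' @return Integer complexity (>= 1; a constant string parses to 2 words
#'   for length > 1).
#' @export
lempelZiv <- function(x) {
  if (!length(x)) stop("empty signal")
  s <- as.integer(x >= stats::median(x))
  .lz76Complexity(s)
}

#' Maximum-minimum distance
#'
#' Partitions the signal into consecutive non-overlapping windows; in each
#' window computes `sqrt(dx^2 + dy^2)` with `dx` the index separation of
#' the window maximum and minimum and `dy` their amplitude difference, and
#' returns the sum over windows. Ties in the extrema locations resolve to
#' the first occurrence.
#'
#' @param x numeric vector, length >= `window`.
#' @param window window length in samples (default 100, i.e. 1 s at 100 Hz).
#' @return Non-negative scalar.
#' @export
maxMinDistance <- function(x, window = 100) {
  n <- length(x)
  if (window > n) stop("window (", window, ") longer than the signal (", n, ")")
  nw <- n %/% window
  total <- 0
  for (w in seq_len(nw)) {
    seg <- x[((w - 1L) * window + 1L):(w * window)]
    iMax <- which.max(seg); iMin <- which.min(seg)
    total <- total + sqrt((iMax - iMin)^2 + (seg[iMax] - seg[iMin])^2)
  }
  total
}

#' Fractal dimensions: Petrosian, Katz and Higuchi
#'
#' Petrosian: `log(M) / (log(M) + log(M / (M + 0.4 K)))` with `K` the number
#' of sign changes of the first difference (standard ratio form; a monotone
#' signal has K = 0 and PFD = 1). Katz: `log(M) / (log(M) + log(d / L))`
#' with `L` the total path length through the index-value plane and `d` the
#' maximum distance from the first point; a constant-slope ramp gives
#' exactly 1, and a degenerate signal (`d = 0` or `L = 0`) is reported as 1
#' with a `degenerate` attribute. Higuchi: slope of `log(L(k))` versus
#' `log(1/k)` for curve lengths at scales `k = 1..kMax`.
#'
#' @param x numeric vector, length >= 4.
#' @param kMax maximum Higuchi scale (default 10).
#' @return Named numeric vector `pfd`, `kfd`, `hfd`.
#' @export
fractalDims <- function(x, kMax = 10) {
  m <- length(x)
  if (m < 4) stop("need at least 4 samples")
  d1 <- diff(x)
  K <- sum(d1[-1] * d1[-length(d1)] < 0)
  pfd <- log(m) / (log(m) + log(m / (m + 0.4 * K)))

  steps <- sqrt(1 + d1^2)
  L <- sum(steps)
  d <- max(sqrt((seq_len(m) - 1)^2 + (x - x[1])^2))
  degenerate <- FALSE
  if (d == 0 || L == 0) { kfd <- 1; degenerate <- TRUE }
  else kfd <- log(m) / (log(m) + log(d / L))

  hfd <- higuchiFD(x, kMax)
  out <- c(pfd = pfd, kfd = kfd, hfd = hfd)
  if (degenerate) attr(out, "degenerate") <- TRUE
  out
}

higuchiFD <- function(x, kMax = 10) {
  n <- length(x)
  Lk <- numeric(kMax)
  for (k in seq_len(kMax)) {
    Lm <- numeric(k)
    for (m0 in seq_len(k)) {
      idx <- seq(m0, n, by = k)
      nm <- length(idx) - 1L
      if (nm < 1) { Lm[m0] <- NA; next }
      Lm[m0] <- sum(abs(diff(x[idx]))) * (n - 1) / (nm * k) / k
    }
    Lk[k] <- mean(Lm, na.rm = TRUE)
  }
  ok <- Lk > 0
  if (sum(ok) < 2) return(1)   # flat signal: no curve length at any scale
  stats::coef(stats::lm(log(Lk[ok]) ~ log(1 / seq_len(kMax)[ok])))[[2]]
}

#' Long-range dependence: DFA exponent and Hurst exponent
#'
#' DFA: the signal is integrated (cumulative sum of deviations from the
#' mean), split into non-overlapping windows of log-spaced sizes between 4
#' and `n/4`, linearly detrended per window, and the fluctuation
#' `F(s) = sqrt(mean residual^2)` is regressed on window size in log-log
#' coordinates; the slope is the DFA exponent (about 0.5 for white noise,
#' about 1.5 for its cumulative sum). Hurst: classical rescaled-range
#' analysis, slope of `log(mean R/S)` versus `log(window size)` over
#' log-spaced windows between 16 and `n/4`.
#'
#' @param x numeric vector, length >= 100.
#' @return Named numeric vector `dfa`, `hurst`.
#' @export
longRange <- function(x) {
  n <- length(x)
  if (n < 100) stop("need at least 100 samples")
  if (stats::sd(x) == 0) stop("zero variance signal")
  c(dfa = dfaExponent(x), hurst = hurstRS(x))
}

dfaExponent <- function(x, nScales = 12) {
  n <- length(x)
  scales <- unique(round(exp(seq(log(4), log(n %/% 4), length.out = nScales))))
  prof <- cumsum(x - mean(x))
  Fs <- vapply(scales, function(s) {
    nw <- n %/% s
    M <- matrix(prof[seq_len(nw * s)], nrow = s)
    res <- stats::lm.fit(cbind(1, seq_len(s)), M)$residuals
    sqrt(mean(res^2))
  }, numeric(1))
  ok <- Fs > 0
  stats::coef(stats::lm(log(Fs[ok]) ~ log(scales[ok])))[[2]]
}

hurstRS <- function(x, nScales = 10) {
  n <- length(x)
  scales <- unique(round(exp(seq(log(16), log(n %/% 4), length.out = nScales))))
  rs <- vapply(scales, function(s) {
    nw <- n %/% s
    vals <- vapply(seq_len(nw), function(w) {
      seg <- x[((w - 1L) * s + 1L):(w * s)]
      z <- cumsum(seg - mean(seg))
      S <- sqrt(mean((seg - mean(seg))^2))
      if (S == 0) return(NA_real_)
      (max(z) - min(z)) / S
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  ok <- is.finite(rs) & rs > 0
  stats::coef(stats::lm(log(rs[ok]) ~ log(scales[ok])))[[2]]
}
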
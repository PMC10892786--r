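## Independent brute-force oracles used to verify the feature
## implementations. These deliberately use naive direct summation /
## enumeration, not the package's code paths.

oracleMoments <- function(x) {
  M <- length(x)
  mu <- sum(x) / M
  v <- sum((x - mu)^2) / M
  list(mean = mu, variance = v,
       skewness = if (v == 0) 0 else (sum((x - mu)^3) / M) / v^(3 / 2),
       kurtosis = if (v == 0) 0 else (sum((x - mu)^4) / M) / v^2,
       amv = max(abs(x)), rms = sqrt(sum(x^2) / M))
}

oracleZCR <- function(x) {
  cnt <- 0
  for (i in 2:length(x)) if (x[i] * x[i - 1] < 0) cnt <- cnt + 1
  cnt / (length(x) - 1)
}

oracleHjorth <- function(x) {
  pv <- function(v) sum((v - sum(v) / length(v))^2) / length(v)
  d1 <- x[-1] - x[-length(x)]
  mob <- sqrt(pv(d1) / pv(x))
  d2 <- d1[-1] - d1[-length(d1)]
  list(mobility = mob, complexity = sqrt(pv(d2) / pv(d1)) / mob)
}

## direct (single-window rectangular) periodogram, one-sided density
oraclePeriodogram <- function(x, rate) {
  n <- length(x)
  x <- x - sum(x) / n
  X <- fft(x)
  nf <- n %/% 2 + 1
  dens <- Mod(X[seq_len(nf)])^2 / (rate * n)
  dens[c(-1, -nf)] <- 2 * dens[c(-1, -nf)]
  list(frequency = seq(0, rate / 2, length.out = nf), density = dens)
}

oracleBandPower <- function(freq, dens, lo, hi) {
  keep <- freq >= lo & freq <= hi
  f <- freq[keep]; d <- dens[keep]
  sum(diff(f) * (head(d, -1) + tail(d, -1)) / 2)
}

## permutation entropy by explicit pattern enumeration (ties: first index)
oraclePermEntropy <- function(x, order = 3, delay = 1) {
  n <- length(x) - (order - 1) * delay
  pats <- character(n)
  for (i in seq_len(n)) {
    w <- x[i + (seq_len(order) - 1) * delay]
    pats[i] <- paste(order(w), collapse = "-")   # stable sort: ties by time
  }
  p <- table(pats) / n
  -sum(p * log(p))
}

## naive O(n^2) sample-entropy template counting
oracleSampEn <- function(x, m = 2, rFactor = 0.2) {
  n <- length(x)
  r <- rFactor * sqrt(mean((x - mean(x))^2))
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  list(A = A, B = B, value = if (A > 0 && B > 0) -log(A / B) else NA)
}

## LZ76 word count by the definitional reproducibility test (substring
## search in the full history), independent of the Kaspar-Schuster parser
oracleLZ76 <- function(bits) {
  str <- paste(bits, collapse = "")
  n <- nchar(str)
  c <- 0L; i <- 0L
  while (i < n) {
    k <- 1L
    repeat {
      if (i + k >= n) break
      w <- substr(str, i + 1, i + k)
      hist <- substr(str, 1, i + k - 1)
      if (!grepl(w, hist, fixed = TRUE)) break
      k <- k + 1L
    }
    c <- c + 1L
    i <- i + k
  }
  c
}

oracleMMD <- function(x, window) {
  nw <- length(x) %/% window
  tot <- 0
  for (w in seq_len(nw)) {
    seg <- x[((w - 1) * window + 1):(w * window)]
    tot <- tot + sqrt((which.max(seg) - which.min(seg))^2 + (max(seg) - min(seg))^2)
  }
  tot
}

oracleKappa <- function(truth, pred) {
  lev <- sort(unique(c(truth, pred)))
  tab <- table(factor(truth, lev), factor(pred, lev))
  po <- sum(diag(tab)) / length(truth)
  pe <- sum(rowSums(tab) * colSums(tab)) / length(truth)^2
  (po - pe) / (1 - pe)
}

## small feature matrix shared by dataset/classifier tests: well-separated
## Gaussian blobs per stage so the classifier's sanity properties hold
toyFeatureMatrix <- function(nPerClass = 30, nRec = 2, seed = 42) {
  set.seed(seed)
  stages <- sleepStages()
  rows <- list()
  for (r in seq_len(nRec)) {
    lab <- sample(rep(stages, length.out = nPerClass * 5))
    f1 <- match(lab, stages) * 3 + rnorm(length(lab), sd = 0.3)
    f2 <- (match(lab, stages) %% 3) * 2 + rnorm(length(lab), sd = 0.3)
    rows[[r]] <- data.frame(recording_id = sprintf("R%02d", r),
                            epoch = seq_along(lab), stage = lab,
                            age = 30 + r, f1 = f1, f2 = f2,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

oracleShannon <- function(x, bins = 10) {
  if (min(x) == max(x)) return(0)
  br <- seq(min(x), max(x), length.out = bins + 1)
  cnt <- table(cut(x, breaks = br, right = FALSE, include.lowest = TRUE))
  p <- as.numeric(cnt) / length(x); p <- p[p > 0]
  -sum(p * log(p))
}

oraclePFD <- function(x) {
  M <- length(x)
  d <- diff(x)
  K <- 0
  for (i in 2:length(d)) if (d[i] * d[i - 1] < 0) K <- K + 1
  log(M) / (log(M) + log(M / (M + 0.4 * K)))
}

oracleKFD <- function(x) {
  M <- length(x)
  L <- 0
  for (i in 2:M) L <- L + sqrt(1 + (x[i] - x[i - 1])^2)
  d <- 0
  for (i in 1:M) d <- max(d, sqrt((i - 1)^2 + (x[i] - x[1])^2))
  if (d == 0 || L == 0) return(1)
  log(M) / (log(M) + log(d / L))
}

## straight-loop Higuchi curve-length implementation
oracleHiguchi <- function(x, kmax = 10) {
  n <- length(x)
  lk <- numeric(kmax)
  for (k in 1:kmax) {
    lm <- c()
    for (m in 1:k) {
      idx <- seq(m, n, by = k)
      if (length(idx) < 2) next
      s <- 0
      for (i in 2:length(idx)) s <- s + abs(x[idx[i]] - x[idx[i - 1]])
      lm <- c(lm, s * (n - 1) / ((length(idx) - 1) * k) / k)
    }
    lk[k] <- mean(lm)
  }
  ok <- lk > 0
  as.numeric(coef(lm(log(lk[ok]) ~ log(1 / (1:kmax)[ok])))[2])
}

## SVD entropy through the Gram-matrix eigenvalues
oracleSVDent <- function(x, d = 10, tau = 1) {
  n <- length(x) - (d - 1) * tau
  Y <- sapply(1:d, function(j) x[1:n + (j - 1) * tau])
  sv <- sqrt(pmax(eigen(crossprod(Y), symmetric = TRUE, only.values = TRUE)$values, 0))
  p <- sv / sum(sv); p <- p[p > 1e-15]
  -sum(p * log(p))
}
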
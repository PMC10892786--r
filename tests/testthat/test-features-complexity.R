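test_that("histogram entropy hits its analytic anchor points", {
  expect_equal(shannonEntropy(rep(3, 100)), 0)
  ## samples filling 10 bins uniformly
  x <- rep(seq(0.05, 0.95, by = 0.1), each = 10)
  expect_equal(shannonEntropy(x), log(10), tolerance = 1e-9)
  ## two equally occupied bins
  expect_equal(shannonEntropy(rep(c(0, 1), 50), bins = 2), log(2), tolerance = 1e-9)
  ## the bin grid follows the data range: affine rescaling leaves it unchanged
  set.seed(3); x <- rnorm(500)
  expect_equal(shannonEntropy(5 * x + 2), shannonEntropy(x), tolerance = 1e-12)
})

test_that("permutation entropy matches the ordinal-pattern oracle", {
  expect_equal(permutationEntropy(1:50), 0)
  x <- c(4, 7, 9, 10, 6, 11, 3)
  expect_equal(permutationEntropy(x, 3), oraclePermEntropy(x, 3), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:50) {
    y <- rnorm(sample(15:60, 1))
    expect_equal(permutationEntropy(y, 3), oraclePermEntropy(y, 3), tolerance = 1e-10)
    expect_equal(permutationEntropy(y, 4, 2), oraclePermEntropy(y, 4, 2), tolerance = 1e-10)
    ## scale invariance
    expect_equal(permutationEntropy(5 * y, 3), permutationEntropy(y, 3), tolerance = 1e-12)
  }
  ## long i.i.d. noise approaches ln(order!)
  set.seed(12)
  z <- rnorm(100000)
  expect_lt(abs(permutationEntropy(z, 3) / log(6) - 1), 0.05)
  expect_error(permutationEntropy(1:3, order = 3), "too short")
})

test_that("spectral entropy separates tones from noise and ignores scale", {
  t <- (0:2999) / 100
  tone <- sin(2 * pi * 10 * t)
  set.seed(13)
  noise <- rnorm(3000)
  se.tone <- spectralEntropy(tone, 100)
  se.noise <- spectralEntropy(noise, 100)
  expect_lt(se.tone, 0.5 * se.noise)
  ## white noise is near the uniform maximum over the PSD bins
  nbins <- length(welchPSD(noise, 100)$frequency)
  expect_lt(abs(se.noise / log(nbins) - 1), 0.10)
  expect_equal(spectralEntropy(3 * tone, 100), se.tone, tolerance = 1e-9)
  expect_error(spectralEntropy(numeric(3000), 100), "zero total power")
})

test_that("SVD entropy ranks noise above sinusoids and ignores amplitude", {
  t <- (0:999) / 100
  tone <- sin(2 * pi * 7 * t)
  set.seed(14)
  noise <- rnorm(1000, sd = sd(tone))
  expect_lt(svdEntropy(tone), svdEntropy(noise))
  expect_equal(svdEntropy(9 * tone), svdEntropy(tone), tolerance = 1e-9)
  expect_error(svdEntropy(numeric(50)), "degenerate")
})

test_that("sample entropy equals the naive template-counting oracle", {
  periodic <- rep(c(1, 2), 50)
  expect_lt(abs(sampleEntropy(periodic)), 1e-12)
  set.seed(15)
  for (i in 1:10) {
    x <- rnorm(sample(60:200, 1))
    o <- oracleSampEn(x)
    expect_equal(as.numeric(sampleEntropy(x)), o$value, tolerance = 1e-12)
  }
  expect_error(sampleEntropy(rep(1, 50)), "zero tolerance")
  ## zero matches cap the value at the most informative resolvable level
  mono <- (1:30) * 1000
  if (is.na(oracleSampEn(mono)$value))
    expect_true(isTRUE(attr(sampleEntropy(mono), "capped")))
})

test_that("Lempel-Ziv complexity reproduces LZ76 parsing", {
  ## the classic worked string parses into 6 words
  bits <- as.integer(strsplit("0001101001000101", "")[[1]])
  expect_equal(somnoboost:::.lz76Complexity(bits), 6L)
  expect_equal(oracleLZ76(bits), 6L)
  ## a constant signal binarises to all-ones: 2 words
  expect_equal(lempelZiv(rep(5, 40)), 2L)
  set.seed(16)
  for (i in 1:50) {
    b <- sample(0:1, sample(10:60, 1), replace = TRUE)
    expect_equal(somnoboost:::.lz76Complexity(as.integer(b)), oracleLZ76(b))
  }
  ## appending a random suffix never lowers the complexity
  base <- sample(0:1, 40, replace = TRUE)
  ext <- c(base, sample(0:1, 20, replace = TRUE))
  expect_gte(somnoboost:::.lz76Complexity(as.integer(ext)),
             somnoboost:::.lz76Complexity(as.integer(base)))
  ## median binarisation makes the feature scale invariant
  x <- rnorm(500)
  expect_equal(lempelZiv(10 * x), lempelZiv(x))
})

test_that("max-min distance follows its per-window definition", {
  expect_equal(maxMinDistance(c(0, 3, 1, -2), window = 4), sqrt(29), tolerance = 1e-12)
  expect_equal(maxMinDistance(rep(2, 200), window = 100), 0)
  w <- c(0, 3, 1, -2)
  expect_equal(maxMinDistance(c(w, w), window = 4), 2 * sqrt(29), tolerance = 1e-12)
  set.seed(17)
  for (i in 1:50) {
    x <- rnorm(sample(c(100, 150, 200), 1))
    expect_equal(maxMinDistance(x, 50), oracleMMD(x, 50), tolerance = 1e-10)
  }
  expect_error(maxMinDistance(rnorm(10), 100), "longer than")
})

test_that("fractal dimensions hit their closed-form anchors", {
  ## monotone signal: no slope sign changes, PFD exactly 1
  expect_equal(unname(fractalDims(cumsum(runif(100)))["pfd"]), 1)
  ## constant-slope ramp: d = L, KFD exactly 1
  ramp <- seq(0, 10, length.out = 200)
  fd <- fractalDims(ramp)
  expect_equal(unname(fd["kfd"]), 1)
  expect_lt(abs(unname(fd["hfd"]) - 1), 0.1)
  ## white noise is nearly plane filling
  set.seed(18)
  fdn <- fractalDims(rnorm(1000))
  expect_gt(unname(fdn["hfd"]), 1.8)
  expect_lt(unname(fdn["hfd"]), 2.05)
  expect_gte(unname(fdn["kfd"]), 1)
  ## scale invariance of PFD (sign-change count is scale free)
  x <- rnorm(300)
  expect_equal(unname(fractalDims(3 * x)["pfd"]), unname(fractalDims(x)["pfd"]))
  ## degenerate constant input flags KFD
  fdc <- fractalDims(rep(1, 50))
  expect_equal(unname(fdc["kfd"]), 1)
})

test_that("DFA and Hurst recover known long-range exponents", {
  set.seed(19)
  white <- rnorm(3000)
  lr <- longRange(white)
  expect_lt(abs(lr[["dfa"]] - 0.5), 0.1)
  expect_lt(abs(lr[["hurst"]] - 0.5), 0.1)
  ## integrated noise: dfa about 1.5
  walk <- cumsum(rnorm(3000))
  expect_lt(abs(longRange(walk)[["dfa"]] - 1.5), 0.15)
  expect_error(longRange(rnorm(50)), "at least 100")
  expect_error(longRange(rep(1, 500)), "zero variance")
})

test_that("all complexity features stay finite on generator output", {
  ds <- synthSleepDataset(1, 6, "easy", seed = 23)
  eps <- normaliseEpochs(segmentEpochs(bandpass(ds[[1]]$recording)))
  for (e in eps) {
    v <- c(shannonEntropy(e), permutationEntropy(e), spectralEntropy(e, 100),
           svdEntropy(e), as.numeric(sampleEntropy(e)), lempelZiv(e),
           maxMinDistance(e), fractalDims(e), longRange(e))
    expect_true(all(is.finite(v)))
  }
})
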
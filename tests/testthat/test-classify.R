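test_that("multiclass logloss matches its analytic anchors", {
  y <- c(0L, 1L, 2L, 3L, 4L)
  onehot <- diag(5)[y + 1L, ]
  expect_lt(multiclassLogloss(y, onehot), 1e-10)
  unif <- matrix(0.2, 5, 5)
  expect_equal(multiclassLogloss(y, unif), log(5), tolerance = 1e-12)
  p <- matrix(c(0.5, 0.2, 0.1, 0.1, 0.1), 1)
  expect_equal(multiclassLogloss(0L, p), log(2), tolerance = 1e-12)
  expect_error(multiclassLogloss(c(0L, 1L), p), "mismatch")
  expect_error(multiclassLogloss(0L, matrix(c(0.5, 0.2, 0.1, 0.1, 0.2), 1)),
               "sum to 1")
})

test_that("Cohen's kappa matches hand-computed contingencies", {
  expect_equal(as.numeric(cohenKappa(c("A", "B", "C", "A"), c("A", "B", "C", "A"))), 1)
  ## chance-level symmetric case
  expect_equal(as.numeric(cohenKappa(c("A", "A", "B", "B"), c("A", "B", "A", "B"))), 0)
  ## hand-evaluated 2x2 marginals: Po 0.75, Pe 0.5
  expect_equal(as.numeric(cohenKappa(c("A", "A", "A", "B"), c("A", "A", "B", "B"))), 0.5)
  set.seed(41)
  for (i in 1:25) {
    truth <- sample(letters[1:4], 30, replace = TRUE)
    pred <- sample(letters[1:4], 30, replace = TRUE)
    expect_equal(as.numeric(cohenKappa(truth, pred)), oracleKappa(truth, pred),
                 tolerance = 1e-12)
  }
  ## both constant and equal: defined as 1 with a flag
  k <- cohenKappa(rep("A", 5), rep("A", 5))
  expect_equal(as.numeric(k), 1)
  expect_true(isTRUE(attr(k, "degenerate")))
})

test_that("fold metrics are coherent on perfect, constant and hand-made cases", {
  y <- rep(0:4, each = 4)
  perfect <- foldMetrics(y, y)
  expect_equal(unname(perfect$metrics), rep(1, 5))
  expect_true(all(perfect$confusion[row(perfect$confusion) != col(perfect$confusion)] == 0))

  constant <- foldMetrics(y, rep(0L, 20))
  expect_equal(unname(constant$metrics["accuracy"]), 0.2)
  expect_equal(unname(constant$metrics["kappa"]), 0)

  ## hand-computed 20-row case: W/N1 swapped for 2 rows each
  pred <- y
  pred[1:2] <- 1L; pred[5:6] <- 0L
  m <- foldMetrics(y, pred)
  expect_equal(unname(m$metrics["accuracy"]), 16 / 20)
  expect_equal(unname(m$metrics["precision"]), 0.8, tolerance = 1e-12)
  expect_equal(unname(m$metrics["recall"]), 0.8, tolerance = 1e-12)
  expect_equal(unname(m$metrics["f1"]), 0.8, tolerance = 1e-12)
  expect_equal(unname(m$metrics["kappa"]), (0.8 - 0.2) / 0.8, tolerance = 1e-12)
  expect_equal(m$confusion["W", "N1"], 2)

  ## balanced symmetric predictions: weighted metrics coincide with accuracy
  expect_equal(unname(m$metrics["accuracy"]), unname(m$metrics["f1"]))
})

test_that("kappa is 1 exactly when the confusion matrix is diagonal", {
  y <- rep(0:4, each = 3)
  m <- foldMetrics(y, y)
  expect_equal(unname(m$metrics["kappa"]), 1)
  pred <- y; pred[1] <- 2L
  m2 <- foldMetrics(y, pred)
  expect_lt(unname(m2$metrics["kappa"]), 1)
})

test_that("cvMean reproduces the reference table means at printed precision", {
  ref <- read.csv(system.file("extdata", "sleepEDFx_fold_metrics.csv",
                              package = "somnoboost"))
  d <- ref[ref$experiment == "default", ]
  p <- ref[ref$experiment == "pso", ]
  expect_equal(attr(cvMean(d$accuracy), "rounded"), 0.845)
  expect_equal(attr(cvMean(p$accuracy), "rounded"), 0.954)
  expect_equal(attr(cvMean(p$kappa), "rounded"), 0.943)
  expect_equal(as.numeric(cvMean(rep(0.7, 10))), 0.7)
  expect_error(cvMean(numeric(0)), "no fold values")
})

test_that("the boosted classifier separates a separable toy problem deterministically", {
  fm <- toyFeatureMatrix(nPerClass = 20, nRec = 2, seed = 43)
  x <- as.matrix(fm[, c("age", "f1", "f2")])
  y <- stageToCode(fm$stage)
  model <- trainSleepModel(x, y, seed = 7)
  expect_gte(mean(predictStage(model, x) == y), 0.99)
  model2 <- trainSleepModel(x, y, seed = 7)
  expect_identical(predictStageProb(model, x), predictStageProb(model2, x))
  prob <- predictStageProb(model, x)
  expect_equal(dim(prob), c(nrow(x), 5))
  expect_equal(rowSums(prob), rep(1, nrow(x)), tolerance = 1e-6)

  ## invalid hyperparameters fail before training
  expect_error(trainSleepModel(x, y, params = list(learning_rate = -1)),
               "learning_rate")
  expect_error(trainSleepModel(x, y, params = list(booster = "boom")), "booster")
  expect_error(trainSleepModel(x, cbind(y + 9)), "0..4")
})

test_that("a small cross-validated experiment is internally consistent", {
  fm <- toyFeatureMatrix(nPerClass = 12, nRec = 2, seed = 44)
  rep <- runExperiment(fm, "default", k = 4, seed = 5)
  ft <- foldTable(rep)
  expect_equal(nrow(ft), 4)
  for (mtr in c("accuracy", "f1", "precision", "recall", "kappa"))
    expect_equal(unname(reportSummary(rep)[mtr]), as.numeric(cvMean(ft[[mtr]])))
  ## per-fold bookkeeping: accuracy equals trace/sum of its confusion matrix
  for (f in 1:4)
    expect_equal(ft$accuracy[f],
                 sum(diag(rep@confusion[[f]])) / sum(rep@confusion[[f]]))
  expect_true(all(ft$kappa >= -1 & ft$kappa <= 1))
  ## logloss curves were captured per fold
  expect_true(all(vapply(rep@curves, nrow, integer(1)) > 0))
  ## determinism of the whole experiment
  rep2 <- runExperiment(fm, "default", k = 4, seed = 5)
  expect_identical(foldTable(rep2), ft)
})

test_that("balancing never touches test rows (leakage guard)", {
  fm <- toyFeatureMatrix(nPerClass = 12, nRec = 2, seed = 45)
  y <- stageToCode(fm$stage)
  folds <- stratifiedFolds(y, k = 4, seed = 8)
  f <- 1L
  tr <- which(folds != f); te <- which(folds == f)
  idx <- balanceTraining(y[tr], seed = 3)
  ## every selected row is a training row
  expect_true(all(tr[idx] %in% tr))
  expect_true(length(intersect(tr[idx], te)) == 0)
  ## corrupting the test labels changes nothing about the balanced sample
  y2 <- y; y2[te] <- rev(y2[te])
  expect_identical(balanceTraining(y2[tr], seed = 3), idx)
})

test_that("temporal context resolves stages that are spectrally ambiguous", {
  ## give N1 the exact spectral profile of REM: instantaneous features can
  ## no longer separate the two, but their Markov dynamics differ (REM is
  ## persistent, N1 transient), so the lag/lead context must recover a
  ## substantial share of the lost accuracy
  prof <- defaultStageProfiles("easy")
  prof$N1 <- prof$REM
  tm <- defaultTransitionMatrix()
  mk <- function(s) {
    hyp <- simulateHypnogram(250, tm, seed = somnoboost:::childSeed(s, "h"))
    rec <- simulateRecording(hyp, prof, seed = somnoboost:::childSeed(s, "r"),
                             id = sprintf("S%d", s))
    extractFeatures(rec, hyp)
  }
  fm <- do.call(rbind, lapply(1:2, mk))
  sf <- shiftFeatures(fm)
  accShift <- reportSummary(runExperiment(sf, "default", k = 5, seed = 3))["accuracy"]
  accPlain <- reportSummary(runExperiment(fm, "default", k = 5, seed = 3))["accuracy"]
  expect_gte(unname(accShift - accPlain), 0.03)
})

test_that("CV reports serialise to JSON and CSV", {
  fm <- toyFeatureMatrix(nPerClass = 10, nRec = 1, seed = 46)
  rep <- runExperiment(fm, "default", k = 3, seed = 6)
  td <- withr::local_tempdir()
  path <- writeCVReport(rep, file.path(td, "r"))
  expect_true(file.exists(path))
  expect_true(file.exists(file.path(td, "r-folds.csv")))
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$summary$accuracy, unname(reportSummary(rep)["accuracy"]),
               tolerance = 1e-12)
})
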
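## Gradient-boosted multiclass classifier (delegated to xgboost) plus the
## evaluation metrics: multiclass logloss, Cohen's kappa, weighted per-class
## metrics, confusion matrices, one-vs-rest AUC, and the cross-validated
## experiment driver (default vs swarm-tuned hyperparameters).

#' Default classifier hyperparameters
#'
#' The stock configuration of the gradient-boosted tree classifier:
#' 5-class softmax objective, multiclass logloss evaluation, learning rate
#' 0.1, depth 3, 100 trees, no regularisation beyond `reg_lambda = 1`, and
#' dart extras at their defaults (uniform sampling, tree normalisation,
#' zero drop rates — with which dart coincides with gbtree).
#'
#' @param booster `"gbtree"` or `"dart"`.
#' @return Named list of hyperparameters.
#' @export
defaultHyperparams <- function(booster = c("gbtree", "dart")) {
  booster <- match.arg(booster)
  list(booster = booster, learning_rate = 0.1, max_depth = 3,
       n_estimators = 100, min_child_weight = 1, gamma = 0,
       subsample = 1, colsample_bytree = 1, colsample_bylevel = 1,
       colsample_bynode = 1, max_delta_step = 0, scale_pos_weight = 1,
       base_score = 0.5, reg_alpha = 0, reg_lambda = 1,
       sample_type = "uniform", normalize_type = "tree",
       rate_drop = 0, one_drop = 0, skip_drop = 0)
}

validateHyperparams <- function(params) {
  chk <- function(cond, what) if (!isTRUE(cond)) stop("invalid hyperparameter: ", what)
  chk(params$booster %in% c("gbtree", "dart"), "booster must be gbtree or dart")
  chk(params$learning_rate > 0 && params$learning_rate <= 1, "learning_rate in (0, 1]")
  chk(params$max_depth >= 1, "max_depth >= 1")
  chk(params$n_estimators >= 1, "n_estimators >= 1")
  chk(is.null(params$subsample) || (params$subsample > 0 && params$subsample <= 1),
      "subsample in (0, 1]")
  chk(is.null(params$gamma) || params$gamma >= 0, "gamma >= 0")
  chk(is.null(params$rate_drop) || (params$rate_drop >= 0 && params$rate_drop <= 1),
      "rate_drop in [0, 1]")
  invisible(params)
}

resolveParams <- function(params) {
  if (!is.null(params$booster) && !params$booster %in% c("gbtree", "dart"))
    stop("invalid hyperparameter: booster must be gbtree or dart")
  full <- defaultHyperparams(params$booster %||% "gbtree")
  full[names(params)] <- params
  validateHyperparams(full)
  full
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train the multiclass sleep-stage classifier
#'
#' Trains a gradient-boosted tree ensemble on the feature matrix with a
#' 5-class softmax objective. Predictions are made in probability mode
#' (softprob) so that ROC analysis is possible; the hard class is the
#' argmax. For the dart booster, prediction uses the full trained ensemble
#' (no dropout at predict time).
#'
#' @param x numeric matrix (epochs x features), no missing values.
#' @param y integer stage codes in 0..4 (see [stageToCode()]).
#' @param params hyperparameter list; missing entries filled from
#'   [defaultHyperparams()].
#' @param seed RNG seed passed to the boosting engine.
#' @param evalSets optional named list of `list(x =, y =)` evaluation sets;
#'   per-round multiclass logloss on each is recorded in the returned
#'   model's `curves` element.
#' @param nthread threads for the engine (default 1, deterministic).
#' @return A `sleepModel` list: `booster` (xgb handle), `params`, `curves`.
#' @export
trainSleepModel <- function(x, y, params = defaultHyperparams(), seed = 1,
                            evalSets = NULL, nthread = 1) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (anyNA(x) || any(!is.finite(x))) stop("feature matrix contains missing/non-finite values")
  if (any(y < 0L | y > 4L)) stop("labels must be integer stage codes in 0..4")
  params <- resolveParams(params)
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  xp <- list(booster = params$booster, eta = params$learning_rate,
             max_depth = params$max_depth,
             min_child_weight = params$min_child_weight, gamma = params$gamma,
             subsample = params$subsample,
             colsample_bytree = params$colsample_bytree,
             colsample_bylevel = params$colsample_bylevel,
             colsample_bynode = params$colsample_bynode,
             max_delta_step = params$max_delta_step,
             ## scale_pos_weight is binary-only; not forwarded for 5-class softmax
             base_score = params$base_score,
             alpha = params$reg_alpha, lambda = params$reg_lambda,
             objective = "multi:softprob", num_class = 5,
             eval_metric = "mlogloss", seed = as.integer(seed) %% 2147483647,
             nthread = nthread)
  if (params$booster == "dart")
    xp <- c(xp, list(sample_type = params$sample_type,
                     normalize_type = params$normalize_type,
                     rate_drop = params$rate_drop, one_drop = params$one_drop,
                     skip_drop = params$skip_drop))
  evals <- list(train = dtrain)
  if (!is.null(evalSets))
    for (nm in names(evalSets))
      evals[[nm]] <- xgboost::xgb.DMatrix(as.matrix(evalSets[[nm]]$x),
                                          label = as.integer(evalSets[[nm]]$y))
  booster <- xgboost::xgb.train(params = xp, data = dtrain,
                                nrounds = params$n_estimators,
                                evals = evals, verbose = 0)
  curves <- attributes(booster)$evaluation_log
  structure(list(booster = booster, params = params,
                 curves = if (is.null(curves)) data.frame() else as.data.frame(curves)),
            class = "sleepModel")
}

#' Predict stage probabilities or classes
#'
#' @param model a `sleepModel` from [trainSleepModel()].
#' @param x feature matrix.
#' @return `predictStageProb`: epochs x 5 probability matrix (columns in
#'   [sleepStages()] order); `predictStage`: integer stage codes 0..4.
#' @export
predictStageProb <- function(model, x) {
  p <- stats::predict(model$booster, as.matrix(x))
  p <- matrix(p, ncol = 5, dimnames = list(NULL, sleepStages()))
  p
}

#' @rdname predictStageProb
#' @export
predictStage <- function(model, x) {
  max.col(predictStageProb(model, x), ties.method = "first") - 1L
}

#' Multiclass logarithmic loss
#'
#' `-(1/M) sum_j sum_k y_jk ln p_jk` with one-hot true labels and predicted
#' probabilities clipped to `[1e-15, 1 - 1e-15]`.
#'
#' @param y integer stage codes 0..4 (length M).
#' @param prob M x 5 probability matrix; rows must sum to 1 within 1e-6.
#' @return Non-negative scalar.
#' @export
multiclassLogloss <- function(y, prob) {
  prob <- as.matrix(prob)
  y <- as.integer(y)
  if (length(y) != nrow(prob)) stop("label/probability shape mismatch")
  if (any(abs(rowSums(prob) - 1) > 1e-6)) stop("probability rows must sum to 1")
  p <- pmin(pmax(prob[cbind(seq_along(y), y + 1L)], 1e-15), 1 - 1e-15)
  -mean(log(p))
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(Po - Pe) / (1 - Pe)` with `Po` the observed
#' agreement rate and `Pe` the expected agreement from the row/column
#' marginals. If both vectors are the same constant (`Pe = 1`), kappa is
#' defined as 1 with a `degenerate` attribute.
#'
#' @param truth,predicted label vectors of equal length.
#' @return Kappa in `[-1, 1]`.
#' @export
cohenKappa <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) stop("length mismatch")
  lev <- sort(unique(c(truth, predicted)))
  m <- length(truth)
  tab <- table(factor(truth, lev), factor(predicted, lev))
  po <- sum(diag(tab)) / m
  pe <- sum(rowSums(tab) * colSums(tab)) / m^2
  if (pe >= 1) {
    out <- 1
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (po - pe) / (1 - pe)
}

#' Metrics of one evaluation fold
#'
#' Accuracy, support-weighted F1/precision/recall, Cohen's kappa, the 5x5
#' confusion matrix (rows = true stage, fixed W/N1/N2/SWS/REM order) and
#' one-vs-rest AUC per class. Classes absent from both truth and
#' prediction are excluded from the weighted averages with a warning;
#' classes absent from the truth get `NA` AUC.
#'
#' @param truth,predicted integer stage codes 0..4.
#' @param prob optional probability matrix for AUC.
#' @return List: `metrics` (named numeric: accuracy, f1, precision,
#'   recall, kappa), `confusion`, `auc` (named numeric length 5),
#'   `perClass` (data.frame).
#' @export
foldMetrics <- function(truth, predicted, prob = NULL) {
  stages <- sleepStages()
  tl <- factor(codeToStage(truth), stages)
  pl <- factor(codeToStage(predicted), stages)
  conf <- table(true = tl, predicted = pl)
  acc <- sum(diag(conf)) / sum(conf)
  support <- rowSums(conf)
  prec <- diag(conf) / colSums(conf)
  rec <- diag(conf) / support
  prec[is.nan(prec)] <- 0
  rec[is.nan(rec)] <- 0
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  present <- support > 0 | colSums(conf) > 0
  if (any(!present))
    warning("class(es) absent from truth and prediction: ",
            paste(stages[!present], collapse = ", "))
  w <- support[present & support > 0]
  wsel <- names(w)
  wmean <- function(v) sum(v[wsel] * w) / sum(w)
  auc <- rep(NA_real_, 5); names(auc) <- stages
  if (!is.null(prob)) {
    for (k in seq_len(5)) {
      resp <- as.integer(truth == k - 1L)
      if (length(unique(resp)) == 2)
        auc[k] <- as.numeric(pROC::auc(pROC::roc(resp, prob[, k], quiet = TRUE,
                                                 direction = "<")))
    }
  }
  list(metrics = c(accuracy = acc, f1 = wmean(f1), precision = wmean(prec),
                   recall = wmean(rec), kappa = as.numeric(cohenKappa(tl, pl))),
       confusion = unclass(conf), auc = auc,
       perClass = data.frame(stage = stages, support = as.numeric(support),
                             precision = as.numeric(prec), recall = as.numeric(rec),
                             f1 = as.numeric(f1)))
}

#' Cross-validation mean of a per-fold metric
#'
#' Arithmetic mean over folds; the value is returned at full precision with
#' a `rounded` attribute giving the 3-decimal presentation used in
#' reports.
#'
#' @param values numeric vector of per-fold values.
#' @return Scalar mean with attribute `rounded`.
#' @export
cvMean <- function(values) {
  if (!length(values)) stop("no fold values")
  m <- mean(values)
  attr(m, "rounded") <- round(m, 3)
  m
}

## inner-CV accuracy of one hyperparameter assignment (PSO fitness)
innerCVAccuracy <- function(x, y, params, innerK = 3, seed = 1, balance = TRUE) {
  folds <- stratifiedFolds(y, k = innerK, seed = childSeed(seed, "inner-folds"))
  accs <- vapply(seq_len(innerK), function(f) {
    tr <- which(folds != f); te <- which(folds == f)
    idx <- if (balance) tr[balanceTraining(y[tr], seed = childSeed(seed, paste0("inner-bal", f)))] else tr
    model <- trainSleepModel(x[idx, , drop = FALSE], y[idx], params,
                             seed = childSeed(seed, paste0("inner-train", f)))
    mean(predictStage(model, x[te, , drop = FALSE]) == y[te])
  }, numeric(1))
  mean(accs)
}

#' Run a cross-validated classification experiment
#'
#' The full evaluation protocol on an assembled (and normally shifted)
#' feature matrix: in `"pso"` mode the hyperparameters are first tuned once
#' by particle swarm optimisation, with mean inner stratified-CV accuracy
#' as the fitness; then (both modes) an outer stratified k-fold loop
#' trains on the balanced training folds and evaluates on the untouched
#' test folds, collecting per-fold accuracy, weighted F1/precision/recall,
#' kappa, confusion matrices, AUC and train/test logloss curves.
#'
#' @param fm feature matrix from [extractFeatures()] /
#'   [shiftFeatures()], with a `stage` column.
#' @param mode `"default"` (stock hyperparameters) or `"pso"`.
#' @param k outer folds (default 10).
#' @param seed master seed; fans out to fold assignment, balancing,
#'   training and the swarm.
#' @param params hyperparameters for default mode (or the starting point).
#' @param space search space for pso mode.
#' @param pso [psoConfig()] for pso mode.
#' @param innerK inner CV folds of the PSO fitness (default 3).
#' @param balance oversample training folds to class balance (default TRUE).
#' @return A [CVReport-class].
#' @export
runExperiment <- function(fm, mode = c("default", "pso"), k = 10, seed = 1,
                          params = defaultHyperparams(),
                          space = defaultSearchSpace(), pso = psoConfig(),
                          innerK = 3, balance = TRUE) {
  mode <- match.arg(mode)
  if (!"stage" %in% names(fm) || anyNA(fm$stage)) stop("feature matrix must carry stage labels")
  x <- as.matrix(fm[, featureCols(fm), drop = FALSE])
  y <- stageToCode(fm$stage)
  history <- data.frame()
  if (mode == "pso") {
    pso$seed <- childSeed(seed, "pso")
    fit <- function(assignment)
      innerCVAccuracy(x, y, resolveParams(assignment), innerK = innerK,
                      seed = childSeed(seed, "fitness"), balance = balance)
    opt <- psoOptimise(space, fit, pso)
    params <- resolveParams(opt$best)
    history <- opt$history
  } else {
    params <- resolveParams(params)
  }
  folds <- stratifiedFolds(y, k = k, seed = childSeed(seed, "outer-folds"))
  rows <- vector("list", k); confs <- vector("list", k)
  curves <- vector("list", k); aucs <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(folds != f); te <- which(folds == f)
    idx <- if (balance) tr[balanceTraining(y[tr], seed = childSeed(seed, paste0("bal", f)))] else tr
    model <- trainSleepModel(x[idx, , drop = FALSE], y[idx], params,
                             seed = childSeed(seed, paste0("train", f)),
                             evalSets = list(test = list(x = x[te, , drop = FALSE],
                                                         y = y[te])))
    prob <- predictStageProb(model, x[te, , drop = FALSE])
    pred <- max.col(prob, ties.method = "first") - 1L
    m <- foldMetrics(y[te], pred, prob)
    rows[[f]] <- data.frame(fold = f, t(m$metrics),
                            logloss = multiclassLogloss(y[te], prob))
    confs[[f]] <- m$confusion
    aucs[[f]] <- data.frame(fold = f, t(m$auc))
    curves[[f]] <- model$curves
  }
  foldsDf <- do.call(rbind, rows)
  met <- c("accuracy", "f1", "precision", "recall", "kappa")
  methods::new("CVReport", folds = foldsDf,
               summary = vapply(foldsDf[met], mean, numeric(1)),
               confusion = confs, auc = do.call(rbind, aucs), curves = curves,
               params = params, mode = mode, seed = as.numeric(seed),
               history = history)
}

#' Serialise a CVReport to JSON and CSV
#'
#' Writes `<prefix>.json` (folds, means, confusion matrices, resolved
#' parameters, seeds), `<prefix>-folds.csv` (the Fold/Accuracy/F1/
#' Precision/Recall/Kappa table) and `<prefix>-curves-<fold>.csv`
#' (per-round train/test logloss).
#'
#' @param report a [CVReport-class].
#' @param prefix output path prefix.
#' @return Invisibly, the JSON path.
#' @export
writeCVReport <- function(report, prefix) {
  json <- list(mode = report@mode, seed = report@seed,
               params = report@params, folds = report@folds,
               summary = as.list(report@summary),
               confusion = lapply(report@confusion, function(m)
                 as.data.frame(as.table(m))),
               auc = report@auc, history = report@history)
  jsonPath <- paste0(prefix, ".json")
  jsonlite::write_json(json, jsonPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  utils::write.csv(report@folds, paste0(prefix, "-folds.csv"), row.names = FALSE)
  for (f in seq_along(report@curves))
    if (nrow(report@curves[[f]]))
      utils::write.csv(report@curves[[f]],
                       sprintf("%s-curves-%02d.csv", prefix, f), row.names = FALSE)
  invisible(jsonPath)
}
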
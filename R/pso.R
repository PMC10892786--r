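## Particle swarm optimisation over a mixed continuous/integer/categorical
## hyperparameter space. Particles live in a continuous internal
## representation; integer and categorical axes are decoded only when a
## position is evaluated.

#' Define one search-space dimension
#'
#' @param name hyperparameter name.
#' @param kind one of `"continuous"`, `"integer"`, `"categorical"`.
#' @param lower,upper bounds (continuous/integer kinds).
#' @param values category labels (categorical kind).
#' @return A `psoDim` list.
#' @export
psoDim <- function(name, kind = c("continuous", "integer", "categorical"),
                   lower = NULL, upper = NULL, values = NULL) {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    if (!length(values)) stop("categorical dimension '", name, "' needs a nonempty value list")
    lower <- 0; upper <- length(values)
  } else {
    if (is.null(lower) || is.null(upper) || !is.finite(lower) || !is.finite(upper) ||
        lower >= upper)
      stop("dimension '", name, "' needs finite bounds with lower < upper")
  }
  structure(list(name = name, kind = kind, lower = lower, upper = upper,
                 values = values), class = "psoDim")
}

#' Assemble a search space
#'
#' @param ... `psoDim` objects (or a single list of them).
#' @return A `psoSpace` object.
#' @export
psoSpace <- function(...) {
  dims <- list(...)
  if (length(dims) == 1 && !inherits(dims[[1]], "psoDim")) dims <- dims[[1]]
  if (!length(dims)) stop("empty search space")
  stopifnot(all(vapply(dims, inherits, logical(1), "psoDim")))
  names(dims) <- vapply(dims, `[[`, character(1), "name")
  structure(dims, class = "psoSpace")
}

spaceBounds <- function(space) {
  list(lower = vapply(space, `[[`, numeric(1), "lower"),
       upper = vapply(space, `[[`, numeric(1), "upper"))
}

#' Decode an internal position into a hyperparameter assignment
#'
#' Continuous axes pass through; integer axes round to the nearest integer;
#' categorical axes map to the category whose unit cell `[i, i+1)` contains
#' the coordinate.
#'
#' @param position numeric vector over the space's dimensions.
#' @param space a `psoSpace`.
#' @return Named list of hyperparameter values.
#' @export
psoDecode <- function(position, space) {
  b <- spaceBounds(space)
  if (any(position < b$lower - 1e-9 | position > b$upper + 1e-9))
    stop("position outside the search-space bounds")
  out <- vector("list", length(space))
  names(out) <- names(space)
  for (j in seq_along(space)) {
    d <- space[[j]]
    out[[j]] <- switch(d$kind,
      continuous = unname(position[j]),
      integer = as.integer(round(position[j])),
      categorical = d$values[[min(length(d$values), floor(position[j]) + 1L)]])
  }
  out
}

#' Encode a hyperparameter assignment into an internal position
#'
#' Inverse of [psoDecode()] (categories encode to their cell centre).
#'
#' @param assignment named list of hyperparameter values.
#' @param space a `psoSpace`.
#' @return Numeric position vector.
#' @export
psoEncode <- function(assignment, space) {
  vapply(seq_along(space), function(j) {
    d <- space[[j]]
    v <- assignment[[d$name]]
    switch(d$kind,
      continuous = as.numeric(v),
      integer = as.numeric(v),
      categorical = {
        i <- match(v, d$values)
        if (is.na(i)) stop("unknown category '", v, "' for '", d$name, "'")
        i - 0.5
      })
  }, numeric(1))
}

#' PSO configuration
#'
#' Constriction-equivalent defaults: inertia 0.7298, cognitive = social =
#' 1.49618, swarm of 20, 30 iterations.
#'
#' @param swarm number of particles (>= 2).
#' @param maxIter number of iterations.
#' @param inertia inertia weight omega.
#' @param cognitive,social acceleration coefficients c1, c2.
#' @param seed RNG seed.
#' @return Named list.
#' @export
psoConfig <- function(swarm = 20, maxIter = 30, inertia = 0.7298,
                      cognitive = 1.49618, social = 1.49618, seed = 1) {
  stopifnot(swarm >= 2, maxIter >= 1, inertia >= 0, cognitive >= 0, social >= 0)
  list(swarm = swarm, maxIter = maxIter, inertia = inertia,
       cognitive = cognitive, social = social, seed = seed)
}

#' Initialise a swarm
#'
#' Positions drawn uniformly within bounds (seeded); velocities all zero;
#' every particle's personal best is its initial position.
#'
#' @param space a `psoSpace`.
#' @param config a [psoConfig()] list.
#' @return List with matrices `position`, `velocity`, `pbest` (particles x
#'   dimensions) and vector `pbestFitness` (all `-Inf`, not yet evaluated).
#' @export
psoInit <- function(space, config = psoConfig()) {
  b <- spaceBounds(space)
  d <- length(space)
  pos <- withSeed(config$seed, {
    matrix(stats::runif(config$swarm * d, rep(b$lower, each = config$swarm),
                        rep(b$upper, each = config$swarm)),
           nrow = config$swarm, ncol = d,
           dimnames = list(NULL, names(space)))
  })
  list(position = pos,
       velocity = matrix(0, config$swarm, d, dimnames = list(NULL, names(space))),
       pbest = pos,
       pbestFitness = rep(-Inf, config$swarm))
}

#' One velocity/position update of the swarm
#'
#' Per particle and dimension:
#' `v' = w v + c1 r1 (pbest - p) + c2 r2 (gbest - p)`, then `p' = p + v'`,
#' with fresh `r1, r2 ~ U(0,1)` per particle per dimension. Velocities are
#' clamped to half the dimension range and positions to the bounds.
#'
#' @param swarm swarm state from [psoInit()].
#' @param gbest numeric vector, the global best position.
#' @param space a `psoSpace`.
#' @param config a [psoConfig()] list.
#' @param r1,r2 optional matrices (particles x dimensions) of fixed random
#'   factors — intended for verification; by default drawn from the RNG.
#' @return The updated swarm state.
#' @export
psoStep <- function(swarm, gbest, space, config = psoConfig(), r1 = NULL, r2 = NULL) {
  b <- spaceBounds(space)
  np <- nrow(swarm$position); d <- ncol(swarm$position)
  if (is.null(r1)) r1 <- matrix(stats::runif(np * d), np, d)
  if (is.null(r2)) r2 <- matrix(stats::runif(np * d), np, d)
  G <- matrix(gbest, np, d, byrow = TRUE)
  v <- config$inertia * swarm$velocity +
    config$cognitive * r1 * (swarm$pbest - swarm$position) +
    config$social * r2 * (G - swarm$position)
  vmax <- matrix((b$upper - b$lower) / 2, np, d, byrow = TRUE)
  v <- pmin(pmax(v, -vmax), vmax)
  p <- swarm$position + v
  p <- pmin(pmax(p, matrix(b$lower, np, d, byrow = TRUE)),
            matrix(b$upper - 1e-9, np, d, byrow = TRUE))
  swarm$velocity <- v
  swarm$position <- p
  swarm
}

#' Particle swarm optimisation
#'
#' Maximises `fitness` over the search space: initialise, evaluate all
#' particles, update personal/global bests, move the swarm, repeat for
#' `maxIter` iterations (the stopping criterion). A fitness failure scores
#' that particle `-Inf` and the run continues. The global-best fitness is
#' non-decreasing across iterations by construction.
#'
#' @param space a `psoSpace`.
#' @param fitness function taking a decoded assignment (named list) and
#'   returning a scalar score to maximise.
#' @param config a [psoConfig()] list.
#' @param verbose print per-iteration progress.
#' @return List: `best` (decoded assignment), `bestFitness`,
#'   `bestPosition`, `history` (data.frame iteration/fitness/position
#'   columns), `failures` (count of failed evaluations).
#' @export
psoOptimise <- function(space, fitness, config = psoConfig(), verbose = FALSE) {
  swarm <- psoInit(space, config)
  d <- length(space)
  gbest <- swarm$position[1, ]
  gbestFit <- -Inf
  hist <- matrix(NA_real_, config$maxIter, d + 2,
                 dimnames = list(NULL, c("iteration", "fitness", names(space))))
  failures <- 0L
  withSeed(childSeed(config$seed, "pso-step"), {
    for (it in seq_len(config$maxIter)) {
      for (kk in seq_len(nrow(swarm$position))) {
        f <- tryCatch(fitness(psoDecode(swarm$position[kk, ], space)),
                      error = function(e) {
                        failures <<- failures + 1L
                        -Inf
                      })
        if (!is.finite(f)) f <- -Inf
        if (f > swarm$pbestFitness[kk]) {
          swarm$pbestFitness[kk] <- f
          swarm$pbest[kk, ] <- swarm$position[kk, ]
        }
        if (f > gbestFit) {
          gbestFit <- f
          gbest <- swarm$position[kk, ]
        }
      }
      hist[it, ] <- c(it, gbestFit, gbest)
      if (verbose)
        message(sprintf("iteration %d: best fitness %.5f", it, gbestFit))
      if (it < config$maxIter) swarm <- psoStep(swarm, gbest, space, config)
    }
  })
  list(best = psoDecode(gbest, space), bestFitness = gbestFit,
       bestPosition = gbest, history = as.data.frame(hist),
       failures = failures)
}

#' Default XGBoost hyperparameter search space
#'
#' Bounds for the tuned booster and tree parameters; `dart` extras
#' (sample/normalize type, drop rates) are part of the space and take
#' effect only when the decoded booster is `dart`.
#'
#' @param boosters candidate boosters.
#' @return A `psoSpace`.
#' @export
defaultSearchSpace <- function(boosters = c("gbtree", "dart")) {
  psoSpace(
    psoDim("booster", "categorical", values = boosters),
    psoDim("learning_rate", "continuous", 0.01, 0.5),
    psoDim("max_depth", "integer", 3, 12),
    psoDim("n_estimators", "integer", 100, 800),
    psoDim("min_child_weight", "integer", 1, 10),
    psoDim("gamma", "continuous", 0, 5),
    psoDim("subsample", "continuous", 0.5, 1),
    psoDim("colsample_bytree", "continuous", 0.5, 1),
    psoDim("reg_alpha", "continuous", 0, 2),
    psoDim("reg_lambda", "continuous", 0.5, 4),
    psoDim("sample_type", "categorical", values = c("uniform", "weighted")),
    psoDim("normalize_type", "categorical", values = c("tree", "forest")),
    psoDim("rate_drop", "continuous", 0, 0.5),
    psoDim("skip_drop", "continuous", 0, 0.5))
}

#' A reduced search space for quick tuning runs
#'
#' Same parameter classes as [defaultSearchSpace()] with tighter tree-count
#' and depth bounds, keeping swarm evaluation affordable on desk-scale
#' problems.
#'
#' @return A `psoSpace`.
#' @export
compactSearchSpace <- function() {
  psoSpace(
    psoDim("booster", "categorical", values = c("gbtree", "dart")),
    psoDim("learning_rate", "continuous", 0.05, 0.5),
    psoDim("max_depth", "integer", 3, 8),
    psoDim("n_estimators", "integer", 50, 150),
    psoDim("min_child_weight", "integer", 1, 6),
    psoDim("subsample", "continuous", 0.6, 1),
    psoDim("colsample_bytree", "continuous", 0.6, 1))
}
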
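#' Search-space bounds
#'
#' Componentwise lower/upper bounds of the continuous search region, with an
#' optional mask marking dimensions that are decoded to integers (rounding
#' half away from zero at decode time only — the search itself stays
#' continuous).
#'
#' @param lower,upper length-D numeric with `lower < upper` componentwise.
#' @param integerMask length-D logical (default all `FALSE`).
#' @return a `goaBounds` list.
#' @export
goaBounds <- function(lower, upper, integerMask = NULL) {
  lower <- as.numeric(lower); upper <- as.numeric(upper)
  stopifnot(length(lower) == length(upper), all(lower < upper))
  if (is.null(integerMask)) integerMask <- rep(FALSE, length(lower))
  stopifnot(length(integerMask) == length(lower))
  structure(list(lower = lower, upper = upper,
                 integerMask = as.logical(integerMask)),
            class = "goaBounds")
}

#' Grasshopper optimizer configuration
#'
#' @param populationSize N >= 2 grasshoppers.
#' @param maxIterations t_max >= 1.
#' @param cMax,cMin endpoints of the linearly shrinking comfort
#'   coefficient (defaults 1 and 0.00001).
#' @param socialIntensity f, intensity of attraction (default 0.5).
#' @param attractiveLengthScale l, attractive length scale (default 1.5).
#' @param seed integer seed for the whole run.
#' @return a `goaConfig` list.
#' @export
goaConfig <- function(populationSize = 30, maxIterations = 200,
                      cMax = 1, cMin = 0.00001,
                      socialIntensity = 0.5, attractiveLengthScale = 1.5,
                      seed = 1) {
  stopifnot(populationSize >= 2, maxIterations >= 1, cMin < cMax,
            socialIntensity > 0, attractiveLengthScale > 0)
  structure(list(populationSize = as.integer(populationSize),
                 maxIterations = as.integer(maxIterations),
                 cMax = cMax, cMin = cMin,
                 socialIntensity = socialIntensity,
                 attractiveLengthScale = attractiveLengthScale,
                 seed = as.integer(seed)),
            class = "goaConfig")
}

#' Social force between two grasshoppers
#'
#' s(y) = f exp(-y / l) - exp(-y): attraction at long range, repulsion at
#' short range, with a comfort distance where the two balance
#' (y* = log(1/f) / (1/l - 1), about 2.08 at the defaults f = 0.5, l = 1.5).
#'
#' @param y non-negative distance.
#' @param f intensity of attraction.
#' @param l attractive length scale.
#' @return signed force value.
#' @export
socialForce <- function(y, f = 0.5, l = 1.5) {
  if (any(y < 0)) stop("distance must be non-negative")
  f * exp(-y / l) - exp(-y)
}

#' Comfort coefficient schedule
#'
#' c(t) = cMax - t (cMax - cMin) / tMax: shrinks linearly from `cMax` at
#' t = 0 to `cMin` at t = tMax, trading exploration for exploitation.
#'
#' @param t iteration, 0 <= t <= tMax.
#' @param config a [goaConfig()].
#' @return comfort coefficient value.
#' @export
comfortCoefficient <- function(t, config) {
  if (any(t < 0) || any(t > config$maxIterations))
    stop("iteration out of [0, maxIterations]")
  # barycentric form: exactly cMax at t = 0 and cMin at t = maxIterations
  frac <- t / config$maxIterations
  (1 - frac) * config$cMax + frac * config$cMin
}

# Canonical distance remapping: s saturates to ~0 for large raw distances,
# freezing the swarm, so per-dimension distances are folded into [1, 4).
normalizeDistance <- function(d) 1 + d %% 3

#' One grasshopper position update
#'
#' Each grasshopper moves under the comfort-scaled sum of pairwise social
#' forces plus the attraction target (the best solution found so far):
#' x_i <- c * sum_j!=i c ((u_d - l_d) / 2) s(|x_j^d - x_i^d|)
#' (x_j - x_i) / d_ij + T_d, with per-dimension distances remapped into
#' \[1, 4) before applying s, d_ij the Euclidean distance, and the result
#' clamped to the bounds. Gravity and wind drift terms are omitted; the
#' drift direction is taken as the target T_d.
#'
#' @param swarm list with `positions` (N x D matrix), `best` (list with
#'   `position`), `iteration` (current t, used for c).
#' @param bounds a [goaBounds()].
#' @param config a [goaConfig()].
#' @return the swarm with updated, clamped positions.
#' @export
goaUpdate <- function(swarm, bounds, config) {
  x <- swarm$positions
  n <- nrow(x); D <- ncol(x)
  cc <- comfortCoefficient(swarm$iteration, config)
  half <- (bounds$upper - bounds$lower) / 2
  newX <- matrix(0, n, D)
  for (i in seq_len(n)) {
    social <- numeric(D)
    if (n > 1) for (j in seq_len(n)) {
      if (j == i) next
      diff <- x[j, ] - x[i, ]
      dij <- sqrt(sum(diff^2))
      unit <- if (dij > 0) diff / dij else numeric(D)
      s <- socialForce(normalizeDistance(abs(diff)),
                       config$socialIntensity, config$attractiveLengthScale)
      social <- social + cc * half * s * unit
    }
    newX[i, ] <- cc * social + swarm$best$position
  }
  for (d in seq_len(D)) newX[, d] <- clamp(newX[, d], bounds$lower[d], bounds$upper[d])
  swarm$positions <- newX
  swarm
}

#' Opposite position (opposition-based learning)
#'
#' The bounds-mirrored point: opposite_d = upper_d + lower_d - x_d. An
#' involution whose fixed point is the box midpoint.
#'
#' @param x position within bounds.
#' @param bounds a [goaBounds()].
#' @return the opposite position.
#' @export
oppositePosition <- function(x, bounds) {
  bounds$upper + bounds$lower - x
}

#' Opposition-based elite selection
#'
#' Evaluates the bounds-mirrored opposite of a candidate and keeps
#' whichever of the pair has the lower fitness; ties keep the original.
#'
#' @param candidate list with `position` and `fitness`.
#' @param fitnessFn function(position) -> scalar (lower = better).
#' @param bounds a [goaBounds()].
#' @return the selected candidate (list with `position`, `fitness`).
#' @export
oblSelect <- function(candidate, fitnessFn, bounds) {
  opp <- oppositePosition(candidate$position, bounds)
  fOpp <- fitnessFn(opp)
  if (is.finite(fOpp) && fOpp < candidate$fitness)
    list(position = opp, fitness = fOpp)
  else candidate
}

#' Enhanced grasshopper optimization
#'
#' Minimises `fitnessFn` over the box `bounds`. Initialisation draws N
#' uniform positions plus their N opposites and keeps the best N
#' (opposition-based initialisation); each iteration shrinks the comfort
#' coefficient, moves the swarm with [goaUpdate()], re-evaluates, applies
#' [oblSelect()] to the global best only, and records the best-so-far
#' fitness. Candidates with non-finite fitness are re-sampled uniformly
#' (counted in `resampled`). Fully reproducible from `config$seed`; the
#' total number of fitness evaluations is
#' 2 N + tMax + N tMax (+ resampling).
#'
#' @param fitnessFn function(position) -> scalar, lower is better.
#' @param bounds a [goaBounds()].
#' @param config a [goaConfig()].
#' @return list with `bestPosition`, `bestFitness`, `history` (length
#'   tMax best-so-far trace), `evaluations`, `resampled`.
#' @export
egoaOptimize <- function(fitnessFn, bounds, config = goaConfig()) {
  D <- length(bounds$lower)
  evals <- 0L; resampled <- 0L
  evalSafe <- function(x) { evals <<- evals + 1L; fitnessFn(x) }
  withSeed(config$seed, {
    sampleUniform <- function()
      bounds$lower + stats::runif(D) * (bounds$upper - bounds$lower)
    evalOrResample <- function(x) {
      f <- evalSafe(x)
      while (!is.finite(f)) {
        resampled <<- resampled + 1L
        x <- sampleUniform()
        f <- evalSafe(x)
      }
      list(position = x, fitness = f)
    }
    n <- config$populationSize
    # opposition-based initialisation: N uniform + N opposites, keep best N
    init <- lapply(seq_len(n), function(i) evalOrResample(sampleUniform()))
    opps <- lapply(init, function(cand)
      evalOrResample(oppositePosition(cand$position, bounds)))
    pool <- c(init, opps)
    ord <- order(vapply(pool, `[[`, numeric(1), "fitness"))[seq_len(n)]
    pool <- pool[ord]
    positions <- do.call(rbind, lapply(pool, `[[`, "position"))
    fitness <- vapply(pool, `[[`, numeric(1), "fitness")
    bestIdx <- which.min(fitness)
    best <- list(position = positions[bestIdx, ], fitness = fitness[bestIdx])
    history <- numeric(config$maxIterations)
    swarm <- list(positions = positions, fitness = fitness, best = best,
                  iteration = 0L)
    for (t in seq_len(config$maxIterations)) {
      swarm$iteration <- t
      swarm <- goaUpdate(swarm, bounds, config)
      for (i in seq_len(n)) {
        cand <- evalOrResample(swarm$positions[i, ])
        swarm$positions[i, ] <- cand$position
        swarm$fitness[i] <- cand$fitness
        if (cand$fitness < swarm$best$fitness) swarm$best <- cand
      }
      swarm$best <- oblSelect(swarm$best, evalSafe, bounds)
      history[t] <- swarm$best$fitness
    }
    list(bestPosition = swarm$best$position, bestFitness = swarm$best$fitness,
         history = history, evaluations = evals, resampled = resampled)
  })
}

#' Default DBN hyperparameter search space
#'
#' Five dimensions: log10 learning rate in (-4, -1); first and second
#' hidden layer sizes in \[16, 256\] and \[8, 128\] (integer);
#' pretraining epochs in \[5, 50\] (integer); batch size in \[8, 64\]
#' (integer).
#'
#' @return a [goaBounds()] with named dimensions.
#' @export
defaultSearchSpace <- function() {
  b <- goaBounds(lower = c(-4, 16, 8, 5, 8),
                 upper = c(-1, 256, 128, 50, 64),
                 integerMask = c(FALSE, TRUE, TRUE, TRUE, TRUE))
  b$names <- c("log10_learning_rate", "hidden1", "hidden2",
               "epochs_pretrain", "batch_size")
  b
}

# Integer dimensions: round half away from zero at decode time only.
decodePosition <- function(position, bounds) {
  out <- position
  out[bounds$integerMask] <- roundHalfUp(out[bounds$integerMask], 0)
  out <- clamp(out, bounds$lower, bounds$upper)
  names(out) <- bounds$names
  out
}

#' Tune DBN hyperparameters with the enhanced grasshopper optimizer
#'
#' Minimises 1 - validation accuracy over the search space, where the
#' validation accuracy comes from a seeded stratified 80/20 split of the
#' supplied (training) data: the tuner never sees test data. Positions are
#' decoded with [defaultSearchSpace()]'s conventions.
#'
#' @param features N x D matrix scaled into \[0, 1\].
#' @param labels length-N labels (>= 2 per class in the inner validation
#'   fold).
#' @param searchSpace a [goaBounds()] with a `names` field (default
#'   [defaultSearchSpace()]).
#' @param config a [goaConfig()].
#' @param baseConfig a [trainConfig()] supplying the settings not searched
#'   over (`cdSteps`, `epochsFinetune`, seed).
#' @return list with `trainConfig`, `hidden`, `fitness` (1 - validation
#'   accuracy), `history`, `evaluations`.
#' @export
tuneDBN <- function(features, labels, searchSpace = defaultSearchSpace(),
                    config = goaConfig(populationSize = 8, maxIterations = 10),
                    baseConfig = trainConfig()) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  sp <- splitDataset(labels, trainFraction = 0.8,
                     seed = stageSeed(config$seed, 17))
  if (any(table(labels[sp$test]) < 2) || any(table(labels[sp$train]) < 2))
    stop("each class needs >= 2 samples on both sides of the inner split")
  xTr <- features[sp$train, , drop = FALSE]; yTr <- labels[sp$train]
  xVa <- features[sp$test, , drop = FALSE];  yVa <- labels[sp$test]
  decodeAll <- function(position) {
    p <- decodePosition(position, searchSpace)
    list(config = trainConfig(learningRate = 10^p[["log10_learning_rate"]],
                              batchSize = p[["batch_size"]],
                              cdSteps = baseConfig$cdSteps,
                              epochsPretrain = p[["epochs_pretrain"]],
                              epochsFinetune = baseConfig$epochsFinetune,
                              seed = baseConfig$seed),
         hidden = c(p[["hidden1"]], p[["hidden2"]]))
  }
  fitnessFn <- function(position) {
    dec <- decodeAll(position)
    model <- trainDBN(xTr, yTr, hidden = dec$hidden, config = dec$config)
    1 - mean(predict(model, xVa) == yVa)
  }
  opt <- egoaOptimize(fitnessFn, searchSpace, config)
  dec <- decodeAll(opt$bestPosition)
  list(trainConfig = dec$config, hidden = dec$hidden,
       fitness = opt$bestFitness, history = opt$history,
       evaluations = opt$evaluations)
}

#' Write an optimization trace as CSV
#'
#' @param result an [egoaOptimize()] result.
#' @param path CSV path.
#' @param config the [goaConfig()] used (for the comfort column).
#' @return invisibly, `path`.
#' @export
writeOptimizationTrace <- function(result, path, config) {
  df <- data.frame(iteration = seq_along(result$history),
                   comfort = comfortCoefficient(seq_along(result$history), config),
                   best_fitness = result$history)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
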
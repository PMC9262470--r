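sphere <- function(x) sum(x^2)

test_that("the social force has the expected shape, values and root", {
  expect_equal(socialForce(0), -0.5)                       # f - 1 at defaults
  expect_equal(socialForce(1.5), 0.5 * exp(-1) - exp(-1.5), tolerance = 1e-12)
  # comfort distance: f exp(-y/l) = exp(-y) at y* = log(1/f)/(1/l - 1)... solved
  yStar <- log(2) / (1 - 1 / 1.5)
  expect_equal(yStar, 2.0794415, tolerance = 1e-6)
  expect_equal(socialForce(yStar), 0, tolerance = 1e-12)
  expect_lt(socialForce(yStar - 0.2), 0)                   # repulsion inside
  expect_gt(socialForce(yStar + 0.2), 0)                   # attraction outside
  expect_error(socialForce(-1), "non-negative")
})

test_that("the comfort coefficient shrinks linearly between its endpoints", {
  cfg <- goaConfig(maxIterations = 200)
  expect_identical(comfortCoefficient(0, cfg), 1)
  expect_identical(comfortCoefficient(200, cfg), 0.00001)
  expect_equal(comfortCoefficient(100, cfg), 0.500005, tolerance = 1e-12)
  ts <- c(0, 50, 100, 150, 200)
  cs <- comfortCoefficient(ts, cfg)
  expect_equal(diff(cs), rep(diff(cs)[1], 4), tolerance = 1e-12)  # linear
  expect_true(all(diff(cs) < 0))
  expect_error(comfortCoefficient(201, cfg), "out of")
})

test_that("a lone grasshopper jumps to the target exactly", {
  b <- goaBounds(c(-5, -5), c(5, 5))
  swarm <- list(positions = matrix(c(2, 3), 1), fitness = 13,
                best = list(position = c(1, -1), fitness = 2), iteration = 10L)
  up <- goaUpdate(swarm, b, goaConfig(maxIterations = 100))
  expect_equal(up$positions[1, ], c(1, -1))
})

test_that("symmetric neighbours feel opposite social pulls", {
  b <- goaBounds(-10, 10)
  cfg <- goaConfig(maxIterations = 100)
  best <- list(position = 0, fitness = 0)
  swarm <- list(positions = matrix(c(-2, 2), 2), fitness = c(4, 4),
                best = best, iteration = 5L)
  up <- goaUpdate(swarm, b, cfg)
  # same magnitude displacement from T_d, opposite signs
  expect_equal(up$positions[1, ], -up$positions[2, ], tolerance = 1e-12)
})

test_that("as the comfort coefficient vanishes the swarm collapses onto the target", {
  b <- goaBounds(c(-10, -10), c(10, 10))
  cfg <- goaConfig(maxIterations = 10)
  set.seed(2)
  swarm <- list(positions = matrix(runif(10, -10, 10), 5),
                fitness = runif(5),
                best = list(position = c(1.5, -2.5), fitness = 0),
                iteration = 10L)  # c = cMin = 1e-5
  up <- goaUpdate(swarm, b, cfg)
  expect_lt(max(abs(sweep(up$positions, 2, c(1.5, -2.5)))), 1e-3)
})

test_that("opposition is an involution with the midpoint fixed", {
  b <- goaBounds(c(1, -2), c(5, 4))
  expect_equal(oppositePosition(c(2, 0), b), c(4, 2))
  mid <- (b$lower + b$upper) / 2
  expect_equal(oppositePosition(mid, b), mid)
  x <- c(1.3, 3.9)
  expect_equal(oppositePosition(oppositePosition(x, b), b), x)
})

test_that("opposition selection keeps the fitter point and breaks ties to the original", {
  b <- goaBounds(0, 10)
  id <- function(x) x
  sel <- oblSelect(list(position = 8, fitness = 8), id, b)
  expect_equal(sel$position, 2)                  # opposite 2 beats 8
  symm <- function(x) abs(x - 5)                 # symmetric about midpoint
  sel2 <- oblSelect(list(position = 8, fitness = 3), symm, b)
  expect_equal(sel2$position, 8)                 # tie keeps original
  sel3 <- oblSelect(list(position = 5, fitness = 0), id, b)
  expect_equal(sel3$position, 5)                 # fixed point unchanged
})

test_that("the optimizer solves the sphere and a 1-D vee benchmark", {
  r <- egoaOptimize(sphere, goaBounds(rep(-10, 5), rep(10, 5)),
                    goaConfig(populationSize = 30, maxIterations = 200,
                              seed = 1))
  expect_lt(r$bestFitness, 1e-2)
  expect_true(all(diff(r$history) <= 0))          # best-so-far is monotone
  expect_length(r$history, 200)
  r2 <- egoaOptimize(function(x) abs(x - 3), goaBounds(0, 10),
                     goaConfig(populationSize = 10, maxIterations = 100,
                               seed = 2))
  expect_lt(abs(r2$bestPosition - 3), 0.1)
})

test_that("runs are reproducible and respect bounds throughout", {
  b <- goaBounds(c(-3, 0), c(2, 4))
  trace <- list()
  fn <- function(x) { trace[[length(trace) + 1]] <<- x; sphere(x - 1) }
  cfg <- goaConfig(populationSize = 6, maxIterations = 20, seed = 5)
  r1 <- egoaOptimize(fn, b, cfg)
  inb <- vapply(trace, function(x)
    all(x >= b$lower - 1e-12) && all(x <= b$upper + 1e-12), logical(1))
  expect_true(all(inb))                           # every evaluated point in box
  r2 <- egoaOptimize(function(x) sphere(x - 1), b, cfg)
  expect_identical(r1$history, r2$history)
})

test_that("the evaluation budget is exactly 2N + tMax + N tMax", {
  counter <- 0L
  fn <- function(x) { counter <<- counter + 1L; sphere(x) }
  n <- 7; tmax <- 13
  r <- egoaOptimize(fn, goaBounds(rep(-1, 3), rep(1, 3)),
                    goaConfig(populationSize = n, maxIterations = tmax,
                              seed = 3))
  expect_identical(counter, as.integer(2 * n + tmax + n * tmax))
  expect_identical(r$evaluations, counter)
  expect_identical(r$resampled, 0L)
})

test_that("non-finite fitness triggers uniform resampling", {
  fn <- function(x) if (x[1] > 0) NaN else sphere(x)
  r <- egoaOptimize(fn, goaBounds(-1, 1),
                    goaConfig(populationSize = 4, maxIterations = 5, seed = 8))
  expect_gt(r$resampled, 0)
  expect_true(is.finite(r$bestFitness))
})

test_that("a collapsed search space returns its single configuration", {
  eps <- 1e-9
  space <- goaBounds(lower = c(-2, 32 - eps, 16 - eps, 10 - eps, 16 - eps),
                     upper = c(-2 + eps, 32, 16, 10, 16),
                     integerMask = c(FALSE, TRUE, TRUE, TRUE, TRUE))
  space$names <- c("log10_learning_rate", "hidden1", "hidden2",
                   "epochs_pretrain", "batch_size")
  cl <- makeFeatureClusters(30, 6, 6, seed = 13)
  tuned <- tuneDBN(cl$features, cl$labels, searchSpace = space,
                   config = goaConfig(populationSize = 2, maxIterations = 1,
                                      seed = 4),
                   baseConfig = trainConfig(epochsPretrain = 2,
                                            epochsFinetune = 5, seed = 2))
  expect_equal(tuned$hidden, c(32, 16), ignore_attr = TRUE)
  expect_equal(tuned$trainConfig$learningRate, 1e-2, tolerance = 1e-6)
  expect_identical(tuned$trainConfig$batchSize, 16L)
  expect_identical(tuned$trainConfig$epochsPretrain, 10L)
})

test_that("tuning never returns a configuration worse than the best one evaluated", {
  cl <- makeFeatureClusters(40, 8, 6, seed = 17)
  tuned <- tuneDBN(cl$features, cl$labels,
                   config = goaConfig(populationSize = 3, maxIterations = 2,
                                      seed = 6),
                   baseConfig = trainConfig(epochsPretrain = 2,
                                            epochsFinetune = 10, seed = 2))
  expect_equal(tuned$fitness, min(tuned$history))
  expect_lte(tuned$fitness, tuned$history[1])     # elitism across iterations
})
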
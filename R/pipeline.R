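#' Stratified train/test split
#'
#' Per-class test counts are `round(class size * test fraction)` (half
#' away from zero), then adjusted by +/- 1 starting from the largest class
#' until the global total `round(n * test fraction)` is met. Sampling
#' within classes is uniform under the seed; train and test partition all
#' indices and each class appears on both sides.
#'
#' @param labels length-N label vector.
#' @param trainFraction fraction of samples to train on, in (0, 1).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @export
splitDataset <- function(labels, trainFraction, seed = 1) {
  labels <- as.character(labels)
  n <- length(labels)
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie strictly between 0 and 1")
  counts <- table(labels)
  if (any(counts < 2)) stop("need >= 2 samples per class")
  testFraction <- 1 - trainFraction
  target <- as.integer(roundHalfUp(n * testFraction, 0))
  perClass <- vapply(counts, function(k)
    as.integer(roundHalfUp(k * testFraction, 0)), integer(1))
  # keep both sides non-empty per class
  perClass <- pmin(pmax(perClass, 1L), as.integer(counts) - 1L)
  ord <- order(counts, decreasing = TRUE)
  i <- 1L
  while (sum(perClass) != target) {
    k <- ord[(i - 1L) %% length(ord) + 1L]
    step <- if (sum(perClass) < target) 1L else -1L
    cand <- perClass[k] + step
    if (cand >= 1L && cand <= counts[k] - 1L) perClass[k] <- cand
    i <- i + 1L
  }
  withSeed(seed, {
    test <- integer(0)
    for (cl in names(counts)) {
      idx <- which(labels == cl)
      test <- c(test, sort(sample(idx, perClass[[cl]])))
    }
    test <- sort(test)
    list(train = setdiff(seq_len(n), test), test = test)
  })
}

#' End-to-end pipeline configuration
#'
#' @param dataPath image folder (class-per-subfolder) or `NULL` to use the
#'   synthetic generator.
#' @param synthetic a [syntheticConfig()] used when `dataPath` is `NULL`.
#' @param bank Gabor bank for preprocessing.
#' @param extractor a [featureExtractorSpec()].
#' @param searchSpace tuning search space ([goaBounds()]).
#' @param goa a [goaConfig()] for the tuner (default reduced budget
#'   N = 8, tMax = 10, sized for desk-scale runs).
#' @param train a [trainConfig()] supplying non-tuned settings.
#' @param splitRatios training fractions evaluated (defaults 0.9, 0.8,
#'   0.7, 0.6).
#' @param seed master seed; stage seeds are derived by fixed offsets.
#' @param outDir optional report directory.
#' @param tune if `FALSE`, skip hyperparameter tuning and use `train`'s
#'   settings directly.
#' @return a `pipelineConfig` list.
#' @export
pipelineConfig <- function(dataPath = NULL, synthetic = syntheticConfig(),
                           bank = defaultGaborBank(),
                           extractor = featureExtractorSpec(),
                           searchSpace = defaultSearchSpace(),
                           goa = goaConfig(populationSize = 8, maxIterations = 10),
                           train = trainConfig(),
                           splitRatios = c(0.9, 0.8, 0.7, 0.6),
                           seed = 7, outDir = NULL, tune = TRUE) {
  stopifnot(all(splitRatios > 0), all(splitRatios < 1))
  structure(list(dataPath = dataPath, synthetic = synthetic, bank = bank,
                 extractor = extractor, searchSpace = searchSpace,
                 goa = goa, train = train, splitRatios = splitRatios,
                 seed = as.integer(seed), outDir = outDir, tune = tune),
            class = "pipelineConfig")
}

# Fixed stage-seed offsets (master seed + offset).
.stageOffsets <- c(data = 101L, extractor = 503L, split = 211L,
                   tune = 307L, train = 401L)

ratioLabel <- function(trainFraction) {
  sprintf("%d:%d", round(100 * trainFraction), round(100 * (1 - trainFraction)))
}

#' Run the full classification pipeline
#'
#' For each split ratio: stratified split, Gabor preprocessing and feature
#' extraction (computed once, shared across ratios — both are per-image
#' operations that see no labels), min-max scaler fitted on the training
#' portion only (test features are clipped into \[0, 1\] and the clipped
#' count logged), hyperparameter tuning on the training portion via
#' [tuneDBN()], final DBN training, and held-out evaluation. All stage
#' seeds derive from the master seed by fixed offsets, so a re-run with
#' the same config reproduces every report bitwise.
#'
#' @param config a [pipelineConfig()].
#' @param verbose print stage messages to stderr.
#' @return list of split reports, one per ratio, each with `ratioLabel`,
#'   `confusion`, `metrics`, `roc`, `pr`, `auroc`, `tuned`,
#'   `clippedCount`, `predictions`, `model`.
#' @export
runPipeline <- function(config, verbose = FALSE) {
  say <- function(...) if (verbose) message("[pipeline] ", sprintf(...))
  dataset <- if (is.null(config$dataPath)) {
    syn <- config$synthetic
    syn$seed <- stageSeed(config$seed, .stageOffsets[["data"]])
    say("generating synthetic dataset (%d + %d images)", syn$nClassA, syn$nClassB)
    makeTextureDataset(syn)
  } else {
    say("reading images from %s", config$dataPath)
    readImageFolder(config$dataPath)
  }

  say("preprocessing %d images with a %d-filter bank",
      length(dataset$images), length(config$bank))
  pre <- dataset
  pre$images <- lapply(dataset$images, preprocessImage, bank = config$bank)

  extractor <- config$extractor
  extractor$seed <- stageSeed(config$seed, .stageOffsets[["extractor"]])
  say("extracting %d-dimensional features (%s)", extractor$outputDim,
      extractor$kind)
  fm <- extractFeatureMatrix(pre, extractor)

  reports <- list()
  for (tf in config$splitRatios) {
    lab <- ratioLabel(tf)
    say("split %s", lab)
    sp <- splitDataset(fm$labels, tf,
                       seed = stageSeed(config$seed, .stageOffsets[["split"]]))
    scaler <- fitScaler(fm$features[sp$train, , drop = FALSE])
    xTr <- applyScaler(scaler, fm$features[sp$train, , drop = FALSE])
    xTe <- applyScaler(scaler, fm$features[sp$test, , drop = FALSE])
    clipped <- attr(xTe, "clipped")
    say("  %d test feature values clipped to [0, 1]", clipped)
    yTr <- fm$labels[sp$train]; yTe <- fm$labels[sp$test]

    base <- config$train
    base$seed <- stageSeed(config$seed, .stageOffsets[["train"]])
    if (config$tune) {
      goa <- config$goa
      goa$seed <- stageSeed(config$seed, .stageOffsets[["tune"]])
      say("  tuning (N=%d, tMax=%d)", goa$populationSize, goa$maxIterations)
      tuned <- tuneDBN(xTr, yTr, searchSpace = config$searchSpace,
                       config = goa, baseConfig = base)
      finalConfig <- tuned$trainConfig
      hidden <- tuned$hidden
    } else {
      tuned <- NULL
      finalConfig <- base
      hidden <- c(64, 32)
    }
    say("  training final DBN (hidden = %s)", paste(hidden, collapse = ", "))
    model <- trainDBN(xTr, yTr, hidden = hidden, config = finalConfig)

    proba <- predictProba(model, xTe)
    predicted <- predict(model, xTe)
    cm <- confusionCounts(yTe, predicted, classes = model@classLabels)
    scores <- proba[, model@classLabels[1]]
    roc <- rocPoints(scores, yTe, positive = model@classLabels[1])
    report <- list(
      ratioLabel = lab,
      confusion = cm,
      metrics = metricsFromConfusion(cm),
      roc = roc,
      pr = prPoints(scores, yTe, positive = model@classLabels[1]),
      auroc = aucFromROC(roc),
      tuned = if (is.null(tuned)) NULL else
        list(hidden = tuned$hidden,
             learningRate = tuned$trainConfig$learningRate,
             batchSize = tuned$trainConfig$batchSize,
             epochsPretrain = tuned$trainConfig$epochsPretrain,
             validationFitness = tuned$fitness),
      clippedCount = clipped,
      predictions = data.frame(id = fm$ids[sp$test], true = yTe,
                               predicted = predicted, score = scores),
      model = model)
    say("  accuracy %.2f%%", report$metrics$accuracy[1])
    if (!is.null(config$outDir)) {
      writeSplitReport(report, config$outDir)
      saveDBN(model, file.path(config$outDir,
                               paste0("dbn_", gsub(":", "_", lab), ".json")))
    }
    reports[[lab]] <- report
  }
  reports
}
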
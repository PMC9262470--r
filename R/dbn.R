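#' Training configuration for the DBN
#'
#' The same learning rate alpha drives both phases, with different batch
#' conventions: CD updates move by (alpha / batchSize) times the summed
#' batch statistics (the mean-gradient form), while fine-tuning takes
#' plain gradient steps of alpha on each mini-batch's summed
#' cross-entropy loss.
#'
#' @param learningRate alpha > 0 for both CD pretraining and fine-tuning.
#' @param batchSize beta >= 1, mini-batch size.
#' @param cdSteps k >= 1 alternating Gibbs steps per CD update.
#' @param epochsPretrain CD epochs per RBM layer, >= 1.
#' @param epochsFinetune backpropagation epochs, >= 0.
#' @param seed integer driving all stochastic choices (initialisation,
#'   Gibbs sampling, batch shuffling).
#' @return a `trainConfig` list.
#' @export
trainConfig <- function(learningRate = 0.1, batchSize = 16, cdSteps = 1,
                        epochsPretrain = 15, epochsFinetune = 100, seed = 1) {
  stopifnot(learningRate > 0, batchSize >= 1, cdSteps >= 1,
            epochsPretrain >= 1, epochsFinetune >= 0)
  structure(list(learningRate = learningRate,
                 batchSize = as.integer(batchSize),
                 cdSteps = as.integer(cdSteps),
                 epochsPretrain = as.integer(epochsPretrain),
                 epochsFinetune = as.integer(epochsFinetune),
                 seed = as.integer(seed)),
            class = "trainConfig")
}

# Mini-batch index list over a shuffled order (uses current RNG stream).
makeBatches <- function(n, batchSize) {
  ord <- sample.int(n)
  split(ord, ceiling(seq_along(ord) / batchSize))
}

softmaxRows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Mean-field forward pass through the RBM stack; returns list of layer
# activations (input first) and softmax class probabilities.
dbnForward <- function(model, x) {
  acts <- list(x)
  for (r in model@rbmStack)
    acts[[length(acts) + 1L]] <- matrix(hiddenConditional(r, acts[[length(acts)]]),
                                        nrow = nrow(x))
  logits <- sweep(acts[[length(acts)]] %*% model@outputWeights, 2,
                  model@outputBias, "+")
  list(activations = acts, proba = softmaxRows(logits))
}

#' Train a deep belief network classifier
#'
#' Greedy layer-wise pretraining — each RBM is trained by contrastive
#' divergence on the previous layer's hidden conditional means, the first
#' on the \[0, 1\]-scaled features used as visible probabilities — followed
#' by appending a softmax output layer and fine-tuning the whole stack by
#' mini-batch gradient descent on the cross-entropy loss. With
#' `epochsFinetune = 0` the output layer keeps its random initialisation
#' (prediction near chance); the RBM stack alone is never a classifier.
#' Deterministic given `config$seed`.
#'
#' @param features N x D matrix scaled into \[0, 1\].
#' @param labels length-N character/factor labels, >= 2 classes with >= 2
#'   samples each.
#' @param hidden integer vector of hidden layer sizes (default c(64, 32)).
#' @param config a [trainConfig()].
#' @return a [DBNModel-class].
#' @export
trainDBN <- function(features, labels, hidden = c(64, 32),
                     config = trainConfig()) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  if (min(features) < -1e-12 || max(features) > 1 + 1e-12)
    stop("features must be min-max scaled into [0, 1]")
  features <- clamp(features, 0, 1)
  classes <- sort(unique(labels))
  if (length(classes) < 2) stop("need at least two classes")
  if (any(table(labels) < 2)) stop("need >= 2 samples per class")
  nC <- length(classes)
  y <- outer(labels, classes, "==") + 0  # one-hot, class order = sorted labels

  withSeed(config$seed, {
    stack <- list()
    input <- features
    for (hSize in hidden) {
      rbm <- newRBM(matrix(stats::rnorm(ncol(input) * hSize, sd = 0.01),
                           ncol(input), hSize))
      for (ep in seq_len(config$epochsPretrain))
        for (idx in makeBatches(nrow(input), config$batchSize))
          rbm <- cdUpdate(rbm, input[idx, , drop = FALSE], config)
      stack[[length(stack) + 1L]] <- rbm
      input <- matrix(hiddenConditional(rbm, input), nrow = nrow(input))
    }
    model <- new("DBNModel",
                 rbmStack = stack,
                 outputWeights = matrix(stats::rnorm(hidden[length(hidden)] * nC,
                                                     sd = 0.01),
                                        hidden[length(hidden)], nC),
                 outputBias = numeric(nC),
                 classLabels = classes)
    if (config$epochsFinetune > 0)
      model <- finetuneDBN(model, features, y, config)
    model
  })
}

# Backpropagation fine-tuning: sigmoid hidden layers, softmax output,
# plain gradient descent with step alpha on the summed cross-entropy loss
# of each mini-batch (so the effective step per epoch scales with the
# batch, unlike the CD updates which use the alpha/beta mean form).
finetuneDBN <- function(model, features, y, config) {
  alpha <- config$learningRate
  nL <- length(model@rbmStack)
  for (ep in seq_len(config$epochsFinetune)) {
    for (idx in makeBatches(nrow(features), config$batchSize)) {
      xb <- features[idx, , drop = FALSE]
      yb <- y[idx, , drop = FALSE]
      fw <- dbnForward(model, xb)
      acts <- fw$activations
      delta <- fw$proba - yb                      # d batch loss / d logits
      gradW <- t(acts[[nL + 1L]]) %*% delta
      gradB <- colSums(delta)
      back <- delta %*% t(model@outputWeights)
      model@outputWeights <- model@outputWeights - alpha * gradW
      model@outputBias <- model@outputBias - alpha * gradB
      for (k in nL:1) {
        a <- acts[[k + 1L]]
        dz <- back * a * (1 - a)                  # sigmoid derivative
        r <- model@rbmStack[[k]]
        gW <- t(acts[[k]]) %*% dz
        gB <- colSums(dz)
        if (k > 1) back <- dz %*% t(r@weights)
        model@rbmStack[[k]] <- newRBM(r@weights - alpha * gW,
                                      r@visibleBias,
                                      r@hiddenBias - alpha * gB)
      }
    }
  }
  model
}

#' Class probabilities from a trained DBN
#'
#' Deterministic mean-field forward pass (no sampling); each row sums to 1.
#'
#' @param model a [DBNModel-class].
#' @param features N x D matrix, D matching the first RBM's visible size.
#' @return N x C matrix of probabilities, columns ordered as
#'   `classLabels(model)`.
#' @export
predictProba <- function(model, features) {
  features <- as.matrix(features)
  if (ncol(features) != nrow(model@rbmStack[[1]]@weights))
    stop("feature dimension does not match the model")
  p <- dbnForward(model, features)$proba
  colnames(p) <- model@classLabels
  p
}

#' Predict class labels
#'
#' Argmax of [predictProba()], ties broken toward the lexicographically
#' smaller class label (class columns are stored sorted, so the first
#' maximal column wins).
#'
#' @param object a [DBNModel-class].
#' @param features N x D feature matrix.
#' @return character vector of predicted labels.
#' @export
setMethod("predict", "DBNModel", function(object, features) {
  p <- predictProba(object, features)
  object@classLabels[apply(p, 1, which.max)]
})

#' DBN JSON serialization
#'
#' Writes shapes, row-major parameter arrays and class labels to a single
#' JSON file at full precision; `loadDBN()` restores a bitwise-identical
#' model.
#'
#' @param model a [DBNModel-class].
#' @param path JSON file path.
#' @return invisibly, `path`.
#' @export
saveDBN <- function(model, path) {
  ser <- list(
    class_labels = model@classLabels,
    rbm_stack = lapply(model@rbmStack, function(r) list(
      m = nrow(r@weights), n = ncol(r@weights),
      weights = as.numeric(t(r@weights)),   # row-major
      visible_bias = r@visibleBias, hidden_bias = r@hiddenBias)),
    output = list(rows = nrow(model@outputWeights),
                  cols = ncol(model@outputWeights),
                  weights = as.numeric(t(model@outputWeights)),
                  bias = model@outputBias))
  jsonlite::write_json(ser, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveDBN
#' @export
loadDBN <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  stack <- lapply(ser$rbm_stack, function(r)
    newRBM(matrix(num(r$weights), r$m, r$n, byrow = TRUE),
           num(r$visible_bias), num(r$hidden_bias)))
  new("DBNModel", rbmStack = stack,
      outputWeights = matrix(num(ser$output$weights), ser$output$rows,
                             ser$output$cols, byrow = TRUE),
      outputBias = num(ser$output$bias),
      classLabels = as.character(unlist(ser$class_labels)))
}
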
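#' Construct an RBM
#'
#' @param weights m x n numeric matrix.
#' @param visibleBias length-m numeric (default zeros).
#' @param hiddenBias length-n numeric (default zeros).
#' @return an [RBM-class] object.
#' @export
newRBM <- function(weights, visibleBias = numeric(nrow(weights)),
                   hiddenBias = numeric(ncol(weights))) {
  new("RBM", weights = as.matrix(weights),
      visibleBias = as.numeric(visibleBias),
      hiddenBias = as.numeric(hiddenBias))
}

#' Randomly initialised RBM
#'
#' Weights drawn from N(0, 0.01^2) under the given seed; biases zero.
#'
#' @param m,n visible and hidden layer sizes.
#' @param seed integer seed.
#' @param sd weight initialisation standard deviation.
#' @return an [RBM-class] object.
#' @export
randomRBM <- function(m, n, seed = 1, sd = 0.01) {
  withSeed(seed, newRBM(matrix(stats::rnorm(m * n, sd = sd), m, n)))
}

#' RBM energy function
#'
#' E(v, h) = -sum_ij w_ij v_i h_j - sum_i a_i v_i - sum_j b_j h_j.
#'
#' @param rbm an [RBM-class].
#' @param v binary visible vector (length m).
#' @param h binary hidden vector (length n).
#' @return scalar energy.
#' @export
rbmEnergy <- function(rbm, v, h) {
  stopifnot(is(rbm, "RBM"))
  if (length(v) != nrow(rbm@weights) || length(h) != ncol(rbm@weights))
    stop("state dimensions do not match the RBM")
  -as.numeric(t(v) %*% rbm@weights %*% h) -
    sum(rbm@visibleBias * v) - sum(rbm@hiddenBias * h)
}

# All binary vectors of length k as rows of a 2^k x k matrix.
binaryStates <- function(k) {
  if (k == 0) return(matrix(numeric(0), 1, 0))
  as.matrix(expand.grid(rep(list(c(0, 1)), k)))[, k:1, drop = FALSE]
}

# Enumeration oracle: every joint state with its unnormalised weight.
rbmStateTable <- function(rbm) {
  m <- nrow(rbm@weights); n <- ncol(rbm@weights)
  if (m + n > 20) stop("enumeration refused for m + n > 20")
  vs <- binaryStates(m); hs <- binaryStates(n)
  grid <- expand.grid(vi = seq_len(nrow(vs)), hi = seq_len(nrow(hs)))
  e <- mapply(function(vi, hi) rbmEnergy(rbm, vs[vi, ], hs[hi, ]),
              grid$vi, grid$hi)
  w <- exp(-e)
  list(v = vs[grid$vi, , drop = FALSE], h = hs[grid$hi, , drop = FALSE],
       energy = e, weight = w, Z = sum(w))
}

#' Exact joint probability by enumeration
#'
#' p(v, h) = exp(-E(v, h)) / Z with the partition function Z summed over all
#' 2^(m+n) binary states. Only usable for small models (m + n <= 20); this
#' is the exact oracle the sampling-free conditionals are tested against.
#'
#' @param rbm a small [RBM-class].
#' @param v,h binary state vectors.
#' @return probability in \[0, 1\].
#' @export
rbmJointProbability <- function(rbm, v, h) {
  tab <- rbmStateTable(rbm)
  exp(-rbmEnergy(rbm, v, h)) / tab$Z
}

#' Exact visible marginal by enumeration
#'
#' p(v) = sum_h p(v, h); small models only.
#'
#' @param rbm a small [RBM-class].
#' @param v binary visible vector.
#' @return probability in \[0, 1\].
#' @export
rbmMarginalVisible <- function(rbm, v) {
  n <- ncol(rbm@weights)
  tab <- rbmStateTable(rbm)
  hs <- binaryStates(n)
  sum(exp(-vapply(seq_len(nrow(hs)),
                  function(i) rbmEnergy(rbm, v, hs[i, ]), numeric(1)))) / tab$Z
}

#' Hidden-unit conditional probabilities
#'
#' p(h_j = 1 | v) = logistic(sum_i w_ij v_i + b_j), with the standard
#' logistic 1 / (1 + exp(-x)). `v` may hold probabilities in \[0, 1\]
#' (mean-field input).
#'
#' @param rbm an [RBM-class].
#' @param v visible vector or row matrix of visible vectors.
#' @return vector (or matrix) of probabilities for each hidden unit.
#' @export
hiddenConditional <- function(rbm, v) {
  v <- if (is.matrix(v)) v else matrix(v, 1)
  if (ncol(v) != nrow(rbm@weights)) stop("visible dimension mismatch")
  p <- stats::plogis(sweep(v %*% rbm@weights, 2, rbm@hiddenBias, "+"))
  if (nrow(p) == 1) as.numeric(p) else p
}

#' Visible-unit conditional probabilities
#'
#' p(v_i = 1 | h) = logistic(sum_j w_ij h_j + a_i).
#'
#' @param rbm an [RBM-class].
#' @param h hidden vector or row matrix of hidden vectors.
#' @return vector (or matrix) of probabilities for each visible unit.
#' @export
visibleConditional <- function(rbm, h) {
  h <- if (is.matrix(h)) h else matrix(h, 1)
  if (ncol(h) != ncol(rbm@weights)) stop("hidden dimension mismatch")
  p <- stats::plogis(sweep(h %*% t(rbm@weights), 2, rbm@visibleBias, "+"))
  if (nrow(p) == 1) as.numeric(p) else p
}

#' One contrastive-divergence parameter update
#'
#' CD-k on a mini-batch: the positive phase uses hidden probabilities given
#' the data; the negative phase runs k alternating Gibbs steps in which
#' hidden states are sampled (Bernoulli) and visible states are mean-field
#' probabilities, with the final statistics taken from probabilities.
#' Parameters move by (alpha / beta) times the difference of the positive
#' and negative phase statistics, beta being the batch size. Uses R's
#' current RNG stream; seed it with the training seed for reproducibility.
#'
#' @param rbm an [RBM-class].
#' @param batch beta x m matrix with entries in \[0, 1\].
#' @param config a [trainConfig()] supplying `learningRate` and `cdSteps`.
#' @return the updated [RBM-class].
#' @export
cdUpdate <- function(rbm, batch, config) {
  batch <- as.matrix(batch)
  if (nrow(batch) == 0) stop("empty batch")
  if (ncol(batch) != nrow(rbm@weights)) stop("batch dimension mismatch")
  if (min(batch) < 0 || max(batch) > 1) stop("batch values must lie in [0, 1]")
  beta <- nrow(batch)
  alpha <- config$learningRate
  hPos <- hiddenConditional(rbm, batch)
  hPos <- matrix(hPos, nrow = beta)
  hState <- matrix(stats::rbinom(length(hPos), 1, hPos), nrow = beta)
  for (step in seq_len(config$cdSteps)) {
    vNeg <- matrix(visibleConditional(rbm, hState), nrow = beta)
    hNeg <- matrix(hiddenConditional(rbm, vNeg), nrow = beta)
    if (step < config$cdSteps)
      hState <- matrix(stats::rbinom(length(hNeg), 1, hNeg), nrow = beta)
  }
  scale <- alpha / beta
  newRBM(rbm@weights + scale * (t(batch) %*% hPos - t(vNeg) %*% hNeg),
         rbm@visibleBias + scale * colSums(batch - vNeg),
         rbm@hiddenBias + scale * colSums(hPos - hNeg))
}

#' Exact data log-likelihood of a small RBM
#'
#' sum over data rows of log p(v) computed by enumeration; used to verify
#' that contrastive divergence behaves as approximate likelihood ascent.
#'
#' @param rbm a small [RBM-class] (m + n <= 20).
#' @param data rows of binary visible vectors.
#' @return scalar log-likelihood.
#' @export
rbmLogLikelihood <- function(rbm, data) {
  data <- as.matrix(data)
  sum(log(vapply(seq_len(nrow(data)),
                 function(i) rbmMarginalVisible(rbm, data[i, ]), numeric(1))))
}
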
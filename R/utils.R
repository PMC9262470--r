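#' @useDynLib GaborDBN, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Stage seeds are derived from one master seed by fixed offsets so that stages
# are reproducible independently of each other.
stageSeed <- function(master, offset) {
  (as.integer(master) + as.integer(offset)) %% .Machine$integer.max
}

#' Round half away from zero
#'
#' Display rounding used for metric tables: ties go away from zero
#' (92.305 -> 92.31), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Rescale to [0, 1]; a constant input maps to all zeros.
rescale01 <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= .Machine$double.eps) return(x * 0)
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Min-max scaler fitted on training data
#'
#' Records per-column minima and maxima; [applyScaler()] maps columns into
#' \[0, 1\] and clips values that fall outside the training range (counted in
#' the `"clipped"` attribute). Constant columns map to 0.
#'
#' @param x numeric matrix (rows = samples).
#' @return object of class `minMaxScaler`.
#' @export
fitScaler <- function(x) {
  x <- as.matrix(x)
  structure(list(min = apply(x, 2, min), max = apply(x, 2, max)),
            class = "minMaxScaler")
}

#' @rdname fitScaler
#' @param scaler a fitted `minMaxScaler`.
#' @export
applyScaler <- function(scaler, x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == length(scaler$min))
  rng <- scaler$max - scaler$min
  rng[rng <= .Machine$double.eps] <- 1
  out <- sweep(sweep(x, 2, scaler$min), 2, rng, "/")
  clipped <- sum(out < 0 | out > 1)
  out <- clamp(out, 0, 1)
  attr(out, "clipped") <- clipped
  out
}
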
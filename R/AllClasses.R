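#' Gabor filter parameters
#'
#' Five-parameter complex Gabor function: wavelength of the sinusoidal
#' carrier (pixels per cycle), orientation (radians, normalised into
#' \[0, pi) since opposite directions are redundant), phase offset (radians),
#' Gaussian envelope standard deviation sigma (pixels) and spatial aspect
#' ratio gamma controlling the ellipticity of the envelope. Sigma may be
#' given directly or derived from a spatial-frequency bandwidth in octaves
#' via [sigmaFromBandwidth()].
#'
#' @slot wavelength pixels per sinusoid cycle, > 0.
#' @slot orientation radians in \[0, pi).
#' @slot phaseOffset radians.
#' @slot sigma envelope standard deviation in pixels, > 0.
#' @slot aspectRatio dimensionless ellipticity, default 0.5.
#' @slot bandwidth octaves (NA when sigma was given directly).
#' @export
setClass("GaborParams", representation(
  wavelength = "numeric",
  orientation = "numeric",
  phaseOffset = "numeric",
  sigma = "numeric",
  aspectRatio = "numeric",
  bandwidth = "numeric"
))

setValidity("GaborParams", function(object) {
  msg <- character()
  if (length(object@wavelength) != 1 || !is.finite(object@wavelength) ||
      object@wavelength <= 0)
    msg <- c(msg, "wavelength must be a single positive number")
  if (length(object@sigma) != 1 || !is.finite(object@sigma) || object@sigma <= 0)
    msg <- c(msg, "sigma must be a single positive number")
  if (object@orientation < 0 || object@orientation >= pi)
    msg <- c(msg, "orientation must lie in [0, pi)")
  if (!is.finite(object@aspectRatio) || object@aspectRatio <= 0)
    msg <- c(msg, "aspectRatio must be positive")
  if (!is.na(object@bandwidth) && object@bandwidth <= 0)
    msg <- c(msg, "bandwidth must be positive when set")
  if (length(msg)) msg else TRUE
})

#' Sampled complex Gabor kernel
#'
#' A square, odd-sided grid sampling the real and imaginary parts of the
#' Gabor function; the centre sample is the origin, so the centre of the
#' real part equals cos(phase) and of the imaginary part sin(phase).
#' Matrix rows index the vertical coordinate (downward, image convention)
#' and columns the horizontal one.
#'
#' @slot realPart,imagPart numeric matrices of equal odd square size.
#' @slot size odd integer side length.
#' @slot params the generating [GaborParams-class].
#' @export
setClass("GaborKernel", representation(
  realPart = "matrix",
  imagPart = "matrix",
  size = "integer",
  params = "GaborParams"
))

setValidity("GaborKernel", function(object) {
  msg <- character()
  d <- dim(object@realPart)
  if (d[1] != d[2]) msg <- c(msg, "kernel must be square")
  if (d[1] %% 2 == 0) msg <- c(msg, "kernel side must be odd")
  if (!identical(dim(object@imagPart), d))
    msg <- c(msg, "real and imaginary parts must have equal dimensions")
  if (object@size != d[1]) msg <- c(msg, "size slot inconsistent with matrices")
  if (!all(is.finite(object@realPart)) || !all(is.finite(object@imagPart)))
    msg <- c(msg, "kernel values must be finite")
  if (length(msg)) msg else TRUE
})

#' Restricted Boltzmann machine
#'
#' Bipartite energy-based model over binary visible and hidden units with
#' energy E(v, h) = -sum_ij w_ij v_i h_j - sum_i a_i v_i - sum_j b_j h_j.
#'
#' @slot weights m x n matrix linking visible unit i to hidden unit j.
#' @slot visibleBias length-m numeric.
#' @slot hiddenBias length-n numeric.
#' @export
setClass("RBM", representation(
  weights = "matrix",
  visibleBias = "numeric",
  hiddenBias = "numeric"
))

setValidity("RBM", function(object) {
  msg <- character()
  if (nrow(object@weights) != length(object@visibleBias))
    msg <- c(msg, "visibleBias length must equal nrow(weights)")
  if (ncol(object@weights) != length(object@hiddenBias))
    msg <- c(msg, "hiddenBias length must equal ncol(weights)")
  if (!all(is.finite(object@weights)) || !all(is.finite(object@visibleBias)) ||
      !all(is.finite(object@hiddenBias)))
    msg <- c(msg, "all parameters must be finite")
  if (length(msg)) msg else TRUE
})

#' Deep belief network classifier
#'
#' A stack of [RBM-class] layers (layer k's hidden size equals layer k+1's
#' visible size) topped by a softmax output layer over the class labels.
#'
#' @slot rbmStack list of [RBM-class] objects.
#' @slot outputWeights (last hidden size) x C matrix.
#' @slot outputBias length-C numeric.
#' @slot classLabels ordered character vector of class labels.
#' @export
setClass("DBNModel", representation(
  rbmStack = "list",
  outputWeights = "matrix",
  outputBias = "numeric",
  classLabels = "character"
))

setValidity("DBNModel", function(object) {
  msg <- character()
  if (length(object@rbmStack) < 1) msg <- c(msg, "need at least one RBM layer")
  if (!all(vapply(object@rbmStack, is, logical(1), class2 = "RBM")))
    msg <- c(msg, "rbmStack must contain RBM objects")
  sizes <- vapply(object@rbmStack, function(r) dim(r@weights), integer(2))
  if (length(object@rbmStack) > 1) {
    for (k in seq_len(length(object@rbmStack) - 1))
      if (sizes[2, k] != sizes[1, k + 1])
        msg <- c(msg, "adjacent RBM layer dimensions must chain")
  }
  if (nrow(object@outputWeights) != sizes[2, length(object@rbmStack)])
    msg <- c(msg, "output layer input size must equal last hidden size")
  nc <- ncol(object@outputWeights)
  if (length(object@outputBias) != nc)
    msg <- c(msg, "outputBias length must equal number of classes")
  if (length(object@classLabels) != nc || nc < 2)
    msg <- c(msg, "need >= 2 ordered class labels matching output width")
  if (length(msg)) msg else TRUE
})

#' @describeIn GaborKernel-class accessor for the sampled real part.
#' @param object a `GaborKernel`.
#' @export
setGeneric("kernelReal", function(object) standardGeneric("kernelReal"))
setMethod("kernelReal", "GaborKernel", function(object) object@realPart)

#' @describeIn GaborKernel-class accessor for the sampled imaginary part.
#' @export
setGeneric("kernelImag", function(object) standardGeneric("kernelImag"))
setMethod("kernelImag", "GaborKernel", function(object) object@imagPart)

#' @describeIn GaborKernel-class accessor for the generating parameters.
#' @export
setGeneric("kernelParams", function(object) standardGeneric("kernelParams"))
setMethod("kernelParams", "GaborKernel", function(object) object@params)

#' @describeIn RBM-class accessor for the weight matrix.
#' @param object an `RBM` or `DBNModel`.
#' @export
setGeneric("rbmWeights", function(object) standardGeneric("rbmWeights"))
setMethod("rbmWeights", "RBM", function(object) object@weights)

#' @describeIn RBM-class accessor for the visible bias.
#' @export
setGeneric("visibleBias", function(object) standardGeneric("visibleBias"))
setMethod("visibleBias", "RBM", function(object) object@visibleBias)

#' @describeIn RBM-class accessor for the hidden bias.
#' @export
setGeneric("hiddenBias", function(object) standardGeneric("hiddenBias"))
setMethod("hiddenBias", "RBM", function(object) object@hiddenBias)

#' @describeIn DBNModel-class accessor for the list of stacked RBMs.
#' @export
setGeneric("rbmStack", function(object) standardGeneric("rbmStack"))
setMethod("rbmStack", "DBNModel", function(object) object@rbmStack)

#' @describeIn DBNModel-class accessor for the ordered class labels.
#' @export
setGeneric("classLabels", function(object) standardGeneric("classLabels"))
setMethod("classLabels", "DBNModel", function(object) object@classLabels)

setMethod("show", "GaborParams", function(object) {
  cat(sprintf(
    "GaborParams: wavelength=%.4g orientation=%.4g rad phase=%.4g sigma=%.4g gamma=%.4g%s\n",
    object@wavelength, object@orientation, object@phaseOffset, object@sigma,
    object@aspectRatio,
    if (is.na(object@bandwidth)) "" else sprintf(" bandwidth=%.4g oct", object@bandwidth)))
})

setMethod("show", "GaborKernel", function(object) {
  cat(sprintf("GaborKernel: %d x %d complex kernel\n", object@size, object@size))
  show(object@params)
})

setMethod("show", "RBM", function(object) {
  cat(sprintf("RBM: %d visible x %d hidden units\n",
              nrow(object@weights), ncol(object@weights)))
})

setMethod("show", "DBNModel", function(object) {
  sizes <- c(nrow(object@rbmStack[[1]]@weights),
             vapply(object@rbmStack, function(r) ncol(r@weights), integer(1)))
  cat(sprintf("DBNModel: %s -> %d classes (%s)\n",
              paste(sizes, collapse = " -> "),
              length(object@classLabels),
              paste(object@classLabels, collapse = ", ")))
})
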
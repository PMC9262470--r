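#' Envelope width from spatial-frequency bandwidth
#'
#' Converts a half-response spatial-frequency bandwidth in octaves into the
#' Gaussian envelope standard deviation of a Gabor filter:
#' sigma = (wavelength / pi) * sqrt(ln 2 / 2) * (2^bw + 1) / (2^bw - 1).
#' Sigma shrinks as the bandwidth grows and scales linearly with wavelength.
#'
#' @param wavelength pixels per sinusoid cycle, > 0.
#' @param bandwidth bandwidth in octaves, > 0.
#' @return envelope standard deviation in pixels.
#' @examples
#' sigmaFromBandwidth(10, 1)  # ~5.62 px
#' @export
sigmaFromBandwidth <- function(wavelength, bandwidth) {
  if (any(!is.finite(wavelength)) || any(wavelength <= 0))
    stop("wavelength must be positive")
  if (any(!is.finite(bandwidth)) || any(bandwidth <= 0))
    stop("bandwidth must be positive")
  (wavelength / pi) * sqrt(log(2) / 2) * (2^bandwidth + 1) / (2^bandwidth - 1)
}

#' Construct Gabor filter parameters
#'
#' Exactly one of `sigma` and `bandwidth` may be omitted; when `sigma` is
#' missing it is derived from the bandwidth via [sigmaFromBandwidth()].
#' The orientation is normalised into \[0, pi): opposite directions give
#' the same filter up to conjugation.
#'
#' @param wavelength pixels per cycle of the sinusoidal carrier, > 0.
#' @param orientation radians; normalised modulo pi.
#' @param phaseOffset radians, default 0.
#' @param sigma envelope standard deviation in pixels (optional).
#' @param aspectRatio envelope ellipticity, default 0.5.
#' @param bandwidth octaves (optional).
#' @return a [GaborParams-class] object.
#' @examples
#' gaborParams(8, orientation = pi / 4, bandwidth = 1)
#' @export
gaborParams <- function(wavelength, orientation = 0, phaseOffset = 0,
                        sigma = NULL, aspectRatio = 0.5, bandwidth = NULL) {
  if (is.null(sigma) && is.null(bandwidth))
    stop("one of sigma or bandwidth must be given")
  if (is.null(sigma)) sigma <- sigmaFromBandwidth(wavelength, bandwidth)
  orientation <- orientation %% pi
  new("GaborParams",
      wavelength = as.numeric(wavelength),
      orientation = as.numeric(orientation),
      phaseOffset = as.numeric(phaseOffset),
      sigma = as.numeric(sigma),
      aspectRatio = as.numeric(aspectRatio),
      bandwidth = if (is.null(bandwidth)) NA_real_ else as.numeric(bandwidth))
}

#' Sample a complex Gabor kernel
#'
#' Evaluates the Gabor function on an odd square grid centred at the origin.
#' With rotated coordinates a' = a cos(theta) + b sin(theta) and
#' b' = -a sin(theta) + b cos(theta), the real part is
#' exp(-(a'^2 + gamma^2 b'^2) / (2 sigma^2)) * cos(2 pi a' / wavelength + psi)
#' and the imaginary part uses sin. Rows run downward (image convention),
#' columns rightward.
#'
#' @param params a [GaborParams-class] object.
#' @param size odd integer side length, or `"auto"` for the smallest odd size
#'   covering +/- 3 sigma / max(gamma, 1) in each direction.
#' @return a [GaborKernel-class] object.
#' @examples
#' k <- gaborKernel(gaborParams(4, sigma = 2), size = 9)
#' kernelReal(k)[5, 5]  # cos(0) = 1
#' @export
gaborKernel <- function(params, size = "auto") {
  stopifnot(is(params, "GaborParams"))
  if (identical(size, "auto")) {
    half <- ceiling(3 * params@sigma / max(params@aspectRatio, 1))
    size <- 2L * as.integer(half) + 1L
  } else {
    size <- as.integer(size)
    if (size %% 2L == 0L) stop("kernel size must be odd")
  }
  half <- (size - 1L) %/% 2L
  a <- matrix(rep(-half:half, each = size), nrow = size)   # columns: horizontal
  b <- matrix(rep(-half:half, times = size), nrow = size)  # rows: vertical
  th <- params@orientation
  ap <- a * cos(th) + b * sin(th)
  bp <- -a * sin(th) + b * cos(th)
  env <- exp(-(ap^2 + params@aspectRatio^2 * bp^2) / (2 * params@sigma^2))
  phase <- 2 * pi * ap / params@wavelength + params@phaseOffset
  new("GaborKernel",
      realPart = env * cos(phase),
      imagPart = env * sin(phase),
      size = size, params = params)
}

#' Default Gabor filter bank
#'
#' Sixteen filters: eight orientations evenly covering \[0, pi) crossed with
#' two carrier wavelengths (4 and 8 px), zero phase, aspect ratio 0.5 and a
#' one-octave bandwidth. This is the bank used by the preprocessing stage
#' and by the pooled texture feature extractor.
#'
#' @param wavelengths carrier wavelengths in pixels.
#' @param nOrientations number of evenly spaced orientations in \[0, pi).
#' @param bandwidth octaves.
#' @param aspectRatio envelope ellipticity.
#' @return list of [GaborParams-class] objects.
#' @export
defaultGaborBank <- function(wavelengths = c(4, 8), nOrientations = 8,
                             bandwidth = 1, aspectRatio = 0.5) {
  thetas <- (seq_len(nOrientations) - 1) * pi / nOrientations
  out <- list()
  for (w in wavelengths)
    for (th in thetas)
      out[[length(out) + 1L]] <- gaborParams(w, orientation = th,
                                             bandwidth = bandwidth,
                                             aspectRatio = aspectRatio)
  out
}

# Raw (unrescaled) magnitude of the complex correlation response.
gaborMagnitude <- function(image, kernel) {
  stopifnot(is(kernel, "GaborKernel"))
  image <- asImageGrid(image)
  if (!is.matrix(image)) stop("applyGabor expects a grayscale image")
  .correlate2dMagnitude(image, kernel@realPart, kernel@imagPart)
}

#' Apply one Gabor kernel to a grayscale image
#'
#' Computes the magnitude sqrt(Re^2 + Im^2) of the complex 2-D correlation
#' of the image with the kernel (reflect padding, output size = input size)
#' and rescales it into \[0, 1\].
#'
#' @param image grayscale image matrix with values in \[0, 1\].
#' @param kernel a [GaborKernel-class].
#' @return matrix of the image's dimensions with values in \[0, 1\].
#' @export
applyGabor <- function(image, kernel) {
  rescale01(gaborMagnitude(image, kernel))
}

#' Gabor filter-bank preprocessing
#'
#' Denoises and enhances an image by a bank of oriented bandpass filters:
#' colour input is first converted to luminance (weights 0.299/0.587/0.114),
#' each bank kernel's raw magnitude response is computed, and the per-pixel
#' maximum across the bank is rescaled into \[0, 1\]. Texture at any bank
#' orientation/frequency is preserved while unoriented noise is attenuated.
#'
#' @param image grayscale matrix or H x W x 3 array, values in \[0, 1\].
#' @param bank non-empty list of [GaborParams-class]; default
#'   [defaultGaborBank()].
#' @param size kernel size passed to [gaborKernel()].
#' @return grayscale matrix in \[0, 1\] of the input's dimensions.
#' @export
preprocessImage <- function(image, bank = defaultGaborBank(), size = "auto") {
  if (length(bank) == 0) stop("bank must be non-empty")
  image <- toGrayscale(asImageGrid(image))
  acc <- NULL
  for (p in bank) {
    resp <- gaborMagnitude(image, gaborKernel(p, size = size))
    acc <- if (is.null(acc)) resp else pmax(acc, resp)
  }
  rescale01(acc)
}

#' Export a Gabor kernel as plain text
#'
#' Writes the real (and optionally imaginary) part as a plain-text matrix,
#' one kernel row per line, space-separated, full precision — a simple
#' interchange format for cross-implementation checks.
#'
#' @param kernel a [GaborKernel-class].
#' @param realPath output path for the real part.
#' @param imagPath optional output path for the imaginary part.
#' @return invisibly, the paths written.
#' @export
exportKernel <- function(kernel, realPath, imagPath = NULL) {
  stopifnot(is(kernel, "GaborKernel"))
  writeMat <- function(m, path) {
    lines <- apply(m, 1, function(r)
      paste(formatC(r, format = "g", digits = 17), collapse = " "))
    writeLines(lines, path)
  }
  writeMat(kernel@realPart, realPath)
  if (!is.null(imagPath)) writeMat(kernel@imagPart, imagPath)
  invisible(c(realPath, imagPath))
}

#' @rdname exportKernel
#' @param path a file written by [exportKernel()].
#' @export
readKernelMatrix <- function(path) {
  rows <- lapply(strsplit(readLines(path), " +"), as.numeric)
  do.call(rbind, rows)
}
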
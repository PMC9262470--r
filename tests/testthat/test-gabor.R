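test_that("bandwidth-to-sigma conversion matches the closed form and its limits", {
  expect_equal(sigmaFromBandwidth(10, 1), 5.6217187538783274, tolerance = 1e-12)
  # prefactor forced to 1: wavelength pi*sqrt(2/ln 2) at 1 octave gives exactly 3
  expect_equal(sigmaFromBandwidth(pi * sqrt(2 / log(2)), 1), 3, tolerance = 1e-12)
  # wide-band limit: (2^bw + 1)/(2^bw - 1) -> 1
  expect_equal(sigmaFromBandwidth(10, 60), 10 / pi * sqrt(log(2) / 2),
               tolerance = 1e-9)
  # strictly decreasing in bandwidth, strictly increasing in wavelength
  bws <- c(0.25, 0.5, 1, 2, 4)
  expect_true(all(diff(sigmaFromBandwidth(6, bws)) < 0))
  wls <- c(2, 4, 8, 16)
  expect_true(all(diff(sigmaFromBandwidth(wls, 1)) > 0))
  expect_error(sigmaFromBandwidth(-1, 1), "positive")
  expect_error(sigmaFromBandwidth(4, 0), "positive")
})

test_that("kernel construction samples the Gabor function on the centred grid", {
  k <- gaborKernel(gaborParams(4, sigma = 2), size = 9)
  ctr <- 5
  expect_equal(kernelReal(k)[ctr, ctr], 1)          # cos(0) * Gaussian(0)
  expect_equal(kernelImag(k)[ctr, ctr], 0)
  # hand evaluation at (a = 2, b = 0), theta = 0, gamma = 0.5:
  # exp(-4/8) * cos(pi) = -exp(-0.5)
  expect_equal(kernelReal(k)[ctr, ctr + 2], -exp(-0.5), tolerance = 1e-12)
  # nonzero phase moves the centre to (cos psi, sin psi)
  kp <- gaborKernel(gaborParams(4, sigma = 2, phaseOffset = 0.7), size = 9)
  expect_equal(kernelReal(kp)[ctr, ctr], cos(0.7))
  expect_equal(kernelImag(kp)[ctr, ctr], sin(0.7))
  expect_error(gaborKernel(gaborParams(4, sigma = 2), size = 8), "odd")
})

test_that("rotating the kernel by 90 degrees transposes it (gamma = 1)", {
  p0 <- gaborParams(5, orientation = 0, sigma = 3, aspectRatio = 1)
  p90 <- gaborParams(5, orientation = pi / 2, sigma = 3, aspectRatio = 1)
  k0 <- gaborKernel(p0, size = 13)
  k90 <- gaborKernel(p90, size = 13)
  expect_equal(kernelReal(k90), t(kernelReal(k0)), tolerance = 1e-12)
})

test_that("zero-phase kernels have even real and odd imaginary parts", {
  for (th in c(0, pi / 5, 2)) {
    k <- gaborKernel(gaborParams(5, orientation = th, sigma = 2.5), size = 11)
    flip <- function(m) m[nrow(m):1, ncol(m):1]
    expect_equal(kernelReal(k), flip(kernelReal(k)), tolerance = 1e-12)
    expect_equal(kernelImag(k), -flip(kernelImag(k)), tolerance = 1e-12)
  }
})

test_that("kernel energy concentrates inside the 3-sigma envelope ellipse", {
  p <- gaborParams(6, orientation = pi / 7, sigma = 3, aspectRatio = 0.5)
  k <- gaborKernel(p, size = 61)  # generous grid
  e <- kernelReal(k)^2 + kernelImag(k)^2
  half <- (nrow(e) - 1) / 2
  a <- matrix(rep(-half:half, each = nrow(e)), nrow(e))
  b <- matrix(rep(-half:half, times = nrow(e)), nrow(e))
  ap <- a * cos(p@orientation) + b * sin(p@orientation)
  bp <- -a * sin(p@orientation) + b * cos(p@orientation)
  inside <- (ap^2 + p@aspectRatio^2 * bp^2) <= (3 * p@sigma)^2
  expect_true(is.finite(sum(e)))
  expect_gte(sum(e[inside]) / sum(e), 0.98)
})

test_that("orientation normalisation and parameter validation behave", {
  expect_equal(gaborParams(4, orientation = pi + 0.3, sigma = 1)@orientation,
               0.3, tolerance = 1e-12)
  expect_equal(gaborParams(4, orientation = -0.2, sigma = 1)@orientation,
               pi - 0.2, tolerance = 1e-12)
  expect_equal(gaborParams(4, sigma = 1)@aspectRatio, 0.5)
  expect_error(gaborParams(4), "sigma or bandwidth")
  # sigma derived from bandwidth when omitted
  expect_equal(gaborParams(10, bandwidth = 1)@sigma, sigmaFromBandwidth(10, 1))
})

test_that("correlation with an impulse reproduces the mirrored kernel magnitude", {
  k <- gaborKernel(gaborParams(4, orientation = pi / 3, sigma = 2), size = 9)
  img <- matrix(0, 31, 31); img[16, 16] <- 1
  resp <- GaborDBN:::gaborMagnitude(img, k)
  km <- sqrt(kernelReal(k)^2 + kernelImag(k)^2)
  expect_equal(resp[16 + (-4:4), 16 + (-4:4)], km[9:1, 9:1], tolerance = 1e-12)
  expect_equal(max(abs(resp[1:5, ])), 0)  # far field is zero
})

test_that("a matched grating maximises the bank's mean magnitude response", {
  grating <- makeGrating(64, 64, wavelength = 8, orientation = pi / 4)
  bank <- lapply((0:7) * pi / 8, function(th)
    gaborParams(8, orientation = th, bandwidth = 1))
  means <- vapply(bank, function(p)
    mean(GaborDBN:::gaborMagnitude(grating, gaborKernel(p))), numeric(1))
  expect_equal(which.max(means), 3)  # pi/4 is the third orientation
})

test_that("constant images give a near-zero raw bandpass response", {
  k <- gaborKernel(gaborParams(6, orientation = 0.4, bandwidth = 1))
  img <- matrix(0.7, 40, 40)
  resp <- GaborDBN:::gaborMagnitude(img, k)
  # DC leakage of the truncated Gaussian envelope only
  expect_lt(max(resp), 0.05 * sum(abs(kernelReal(k))))
})

test_that("filtering commutes with translation away from borders", {
  k <- gaborKernel(gaborParams(4, orientation = pi / 6, sigma = 2), size = 9)
  set.seed(11)
  base <- matrix(runif(80 * 80), 80, 80)
  shifted <- base[c(4:80, 1:3), ]  # translate rows by 3
  r1 <- GaborDBN:::gaborMagnitude(base, k)
  r2 <- GaborDBN:::gaborMagnitude(shifted, k)
  interior <- 20:60
  expect_equal(r2[interior, interior], r1[interior + 3, interior], tolerance = 1e-10)
})

test_that("applyGabor output matches the input size, lies in [0,1], and checks sizes", {
  k <- gaborKernel(gaborParams(4, sigma = 2), size = 9)
  img <- makeGrating(30, 40, 4, 0)
  out <- applyGabor(img, k)
  expect_identical(dim(out), dim(img))
  expect_gte(min(out), 0); expect_lte(max(out), 1)
  expect_error(applyGabor(matrix(0.5, 5, 5), k), "larger than image")
})

test_that("preprocessing reduces to applyGabor for a singleton bank and bounds output", {
  img <- makeGrating(48, 48, 6, pi / 3)
  p <- gaborParams(6, orientation = pi / 3, bandwidth = 1)
  expect_equal(preprocessImage(img, list(p)), applyGabor(img, gaborKernel(p)))
  out <- preprocessImage(img)  # default 16-filter bank
  expect_gte(min(out), 0); expect_lte(max(out), 1)
  expect_error(preprocessImage(img, list()), "non-empty")
})

test_that("preprocessing converts colour to luminance before filtering", {
  g <- makeGrating(32, 32, 4, 0)
  col <- array(0, dim = c(32, 32, 3))
  col[, , 1] <- g; col[, , 2] <- g; col[, , 3] <- g
  expect_equal(preprocessImage(col), preprocessImage(g))
})

test_that("Gabor preprocessing denoises an oriented texture", {
  clean <- makeGrating(64, 64, 8, pi / 8)
  set.seed(5)
  noisy <- pmin(pmax(clean + matrix(rnorm(64 * 64, sd = 0.25), 64), 0), 1)
  bank <- list(gaborParams(8, orientation = pi / 8, bandwidth = 1))
  cleanResp <- preprocessImage(clean, bank)
  noisyResp <- preprocessImage(noisy, bank)
  corFiltered <- cor(as.numeric(noisyResp), as.numeric(cleanResp))
  corRaw <- cor(as.numeric(noisy), as.numeric(clean))
  expect_gt(corFiltered, corRaw)
})

test_that("kernel plain-text export round-trips", {
  k <- gaborKernel(gaborParams(5, orientation = 1, sigma = 2, phaseOffset = 0.3),
                   size = 11)
  re <- tempfile(fileext = ".txt"); im <- tempfile(fileext = ".txt")
  exportKernel(k, re, im)
  expect_equal(readKernelMatrix(re), kernelReal(k), tolerance = 1e-15,
               ignore_attr = TRUE)
  expect_equal(readKernelMatrix(im), kernelImag(k), tolerance = 1e-15,
               ignore_attr = TRUE)
})
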
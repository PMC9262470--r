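#' Synthetic two-class texture dataset configuration
#'
#' Emulates a small, roughly 2:1 imbalanced two-class photographic dataset
#' in which the classes differ in oriented texture frequency and in blob
#' statistics: each image is an oriented sinusoidal grating (per-image
#' random phase plus mild orientation/wavelength jitter) with dark
#' elliptical blobs and additive Gaussian noise, clipped into \[0, 1\].
#' Class "cancer" (A) uses a finer, differently oriented carrier and more
#' blobs than class "noncancer" (B).
#'
#' @param nClassA,nClassB image counts per class (defaults 87 and 44).
#' @param imageSize `(height, width)` in pixels (default 128 x 128).
#' @param wavelengthA,orientationA class-A carrier wavelength (px) and
#'   orientation (radians).
#' @param wavelengthB,orientationB class-B carrier parameters.
#' @param blobsA,blobsB dark elliptical blob counts per image.
#' @param blobDepth peak blob darkening (intensity units).
#' @param noiseSd additive Gaussian noise standard deviation (>= 0).
#' @param seed integer; the dataset is a pure function of the config.
#' @return a `syntheticConfig` list.
#' @export
syntheticConfig <- function(nClassA = 87, nClassB = 44,
                            imageSize = c(128, 128),
                            wavelengthA = 4, orientationA = pi / 8,
                            wavelengthB = 8, orientationB = 5 * pi / 8,
                            blobsA = 6, blobsB = 2,
                            blobDepth = 0.35, noiseSd = 0.08, seed = 1) {
  stopifnot(nClassA >= 2, nClassB >= 2, noiseSd >= 0, all(imageSize >= 16))
  structure(list(nClassA = as.integer(nClassA), nClassB = as.integer(nClassB),
                 imageSize = as.integer(imageSize),
                 wavelengthA = wavelengthA, orientationA = orientationA,
                 wavelengthB = wavelengthB, orientationB = orientationB,
                 blobsA = as.integer(blobsA), blobsB = as.integer(blobsB),
                 blobDepth = blobDepth, noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "syntheticConfig")
}

# One textured image; consumes the current RNG stream.
makeTextureImage <- function(h, w, wavelength, orientation, nBlobs,
                             blobDepth, noiseSd) {
  th <- orientation + stats::rnorm(1, sd = 0.05)
  wl <- wavelength * exp(stats::rnorm(1, sd = 0.05))
  phase <- stats::runif(1, 0, 2 * pi)
  a <- matrix(rep(seq_len(w), each = h), h)   # horizontal coordinate
  b <- matrix(rep(seq_len(h), times = w), h)  # vertical coordinate
  img <- 0.5 + 0.25 * sin(2 * pi * (a * cos(th) + b * sin(th)) / wl + phase)
  for (k in seq_len(nBlobs)) {
    cx <- stats::runif(1, 1, w); cy <- stats::runif(1, 1, h)
    rx <- stats::runif(1, 0.04, 0.12) * w
    ry <- stats::runif(1, 0.04, 0.12) * h
    ang <- stats::runif(1, 0, pi)
    da <- a - cx; db <- b - cy
    u <- da * cos(ang) + db * sin(ang)
    v <- -da * sin(ang) + db * cos(ang)
    img <- img - blobDepth * exp(-(u^2 / (2 * rx^2) + v^2 / (2 * ry^2)))
  }
  if (noiseSd > 0) img <- img + matrix(stats::rnorm(h * w, sd = noiseSd), h)
  clamp(img, 0, 1)
}

#' Generate the synthetic labelled image dataset
#'
#' Deterministic given `config$seed`: the same config yields bitwise
#' identical pixels. Class A images are labelled `"cancer"`, class B
#' `"noncancer"`.
#'
#' @param config a [syntheticConfig()].
#' @return list with `images` (list of grayscale matrices), `labels`
#'   (character), `ids` (character).
#' @export
makeTextureDataset <- function(config) {
  stopifnot(inherits(config, "syntheticConfig"))
  h <- config$imageSize[1]; w <- config$imageSize[2]
  withSeed(config$seed, {
    imgsA <- lapply(seq_len(config$nClassA), function(i)
      makeTextureImage(h, w, config$wavelengthA, config$orientationA,
                       config$blobsA, config$blobDepth, config$noiseSd))
    imgsB <- lapply(seq_len(config$nClassB), function(i)
      makeTextureImage(h, w, config$wavelengthB, config$orientationB,
                       config$blobsB, config$blobDepth, config$noiseSd))
    list(images = c(imgsA, imgsB),
         labels = c(rep("cancer", config$nClassA),
                    rep("noncancer", config$nClassB)),
         ids = c(sprintf("cancer_%03d", seq_len(config$nClassA)),
                 sprintf("noncancer_%03d", seq_len(config$nClassB))))
  })
}

#' Separable Gaussian feature clusters
#'
#' Two isotropic unit-variance Gaussian clusters centred at
#' +/- (separation / 2) along the first coordinate axis, min-max scaled
#' into \[0, 1\] per dimension. With separation 6 the Bayes error is below
#' 1%; with separation 0 the classes are indistinguishable.
#'
#' @param nPerClass samples per class.
#' @param dim feature dimensionality.
#' @param separation distance between the class means (>= 0).
#' @param seed integer seed.
#' @return list with `features` (2 nPerClass x dim matrix in \[0, 1\]) and
#'   `labels` (`"classA"` / `"classB"`).
#' @export
makeFeatureClusters <- function(nPerClass, dim, separation, seed = 1) {
  stopifnot(separation >= 0, nPerClass >= 1, dim >= 1)
  withSeed(seed, {
    x <- matrix(stats::rnorm(2 * nPerClass * dim), ncol = dim)
    x[seq_len(nPerClass), 1] <- x[seq_len(nPerClass), 1] + separation / 2
    x[nPerClass + seq_len(nPerClass), 1] <-
      x[nPerClass + seq_len(nPerClass), 1] - separation / 2
    for (d in seq_len(dim)) x[, d] <- rescale01(x[, d])
    list(features = x,
         labels = rep(c("classA", "classB"), each = nPerClass))
  })
}

#' Write a dataset as a class-per-subfolder PNG tree
#'
#' Writes 8-bit grayscale PNGs under `path/cancer` and `path/noncancer`;
#' re-running overwrites the same files, and a round-trip read reproduces
#' the pixels to within 8-bit quantization.
#'
#' @param dataset a [makeTextureDataset()] result.
#' @param path output directory.
#' @return invisibly, the written file paths.
#' @export
writeImageFolder <- function(dataset, path) {
  paths <- character(length(dataset$images))
  for (cl in unique(dataset$labels))
    dir.create(file.path(path, cl), recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(dataset$images)) {
    paths[i] <- file.path(path, dataset$labels[i],
                          paste0(dataset$ids[i], ".png"))
    png::writePNG(dataset$images[[i]], paths[i])
  }
  invisible(paths)
}

#' Read a class-per-subfolder image tree
#'
#' Expects one subfolder per class label containing PNG/JPEG files.
#'
#' @param path dataset root directory.
#' @return list with `images`, `labels`, `ids` as in
#'   [makeTextureDataset()].
#' @export
readImageFolder <- function(path) {
  classes <- sort(list.dirs(path, recursive = FALSE, full.names = FALSE))
  if (length(classes) == 0) stop("no class subfolders under ", path)
  images <- list(); labels <- character(); ids <- character()
  for (cl in classes) {
    files <- sort(list.files(file.path(path, cl),
                             pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                             full.names = TRUE))
    for (f in files) {
      images[[length(images) + 1L]] <- readImageGrid(f)
      labels <- c(labels, cl)
      ids <- c(ids, tools::file_path_sans_ext(basename(f)))
    }
  }
  list(images = images, labels = labels, ids = ids)
}
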
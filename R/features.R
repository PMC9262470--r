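#' Feature extractor specification
#'
#' Describes how a preprocessed image is turned into a fixed-length real
#' feature vector. The default `pooled_gabor` extractor is fully
#' self-contained and bitwise deterministic: it pools filter-bank response
#' statistics over a spatial grid and projects them with a seeded random
#' matrix. The `cnn_adapter` kind runs a user-registered pretrained
#' convolutional backbone (see [cnnAdapterFeatures()]); it is never
#' substituted silently.
#'
#' @param kind `"pooled_gabor"` or `"cnn_adapter"`.
#' @param outputDim feature vector length, >= 2 (default 128).
#' @param targetSize `(height, width)` images are resized to before
#'   extraction (default 224 x 224).
#' @param seed integer seeding the deterministic projection matrix.
#' @param bank Gabor bank used by the pooled extractor.
#' @return a `featureExtractorSpec` list.
#' @export
featureExtractorSpec <- function(kind = c("pooled_gabor", "cnn_adapter"),
                                 outputDim = 128, targetSize = c(224, 224),
                                 seed = 1, bank = defaultGaborBank()) {
  kind <- match.arg(kind)
  outputDim <- as.integer(outputDim)
  if (outputDim < 2) stop("outputDim must be >= 2")
  stopifnot(length(targetSize) == 2, all(targetSize > 0))
  structure(list(kind = kind, outputDim = outputDim,
                 targetSize = as.integer(targetSize),
                 seed = as.integer(seed), bank = bank),
            class = "featureExtractorSpec")
}

#' Extract a feature vector from an image
#'
#' Dispatches on the spec's `kind`. The returned vector always has length
#' `spec$outputDim` and contains only finite values.
#'
#' @param image grayscale matrix or colour array in \[0, 1\].
#' @param spec a [featureExtractorSpec()].
#' @return numeric vector of length `spec$outputDim`.
#' @export
extractFeatures <- function(image, spec) {
  stopifnot(inherits(spec, "featureExtractorSpec"))
  v <- switch(spec$kind,
              pooled_gabor = pooledGaborFeatures(image, spec),
              cnn_adapter = cnnAdapterFeatures(image, spec))
  if (length(v) != spec$outputDim || !all(is.finite(v)))
    stop("extractor returned an invalid feature vector")
  v
}

#' Pooled Gabor-bank texture features
#'
#' The image is converted to luminance, resized to `spec$targetSize`, and
#' each bank filter's raw magnitude response is summarised by \{mean,
#' standard deviation, energy (mean square)\} over a 4 x 4 spatial grid:
#' 16 filters x 16 cells x 3 statistics = 768 raw values. These are
#' projected to `spec$outputDim` dimensions by a fixed random projection
#' matrix with N(0, 1/768) entries regenerated identically from
#' `spec$seed` on every call, so the extractor is a pure function of the
#' image bytes and the spec.
#'
#' @param image image grid.
#' @param spec a [featureExtractorSpec()].
#' @param project if `FALSE`, return the 768 raw pooled statistics instead
#'   of the projected vector (used for diagnostics and tests).
#' @return numeric vector of length `spec$outputDim` (or raw length).
#' @export
pooledGaborFeatures <- function(image, spec, project = TRUE) {
  img <- toGrayscale(asImageGrid(image))
  img <- resizeImage(img, spec$targetSize[1], spec$targetSize[2])
  grid <- 4L
  rowCut <- cut(seq_len(nrow(img)), grid, labels = FALSE)
  colCut <- cut(seq_len(ncol(img)), grid, labels = FALSE)
  raw <- numeric(0)
  for (p in spec$bank) {
    resp <- gaborMagnitude(img, gaborKernel(p))
    for (rc in seq_len(grid)) for (cc in seq_len(grid)) {
      cell <- resp[rowCut == rc, colCut == cc]
      raw <- c(raw, mean(cell), stats::sd(as.numeric(cell)), mean(cell^2))
    }
  }
  if (!project) return(raw)
  proj <- withSeed(spec$seed,
                   matrix(stats::rnorm(length(raw) * spec$outputDim),
                          nrow = length(raw)) / sqrt(length(raw)))
  as.numeric(raw %*% proj)
}

#' Pretrained CNN adapter features
#'
#' Runs a pretrained convolutional backbone in inference mode: the image is
#' resized to 224 x 224 x 3 (grayscale broadcast to three channels), the
#' backbone's final spatial feature map is global-average-pooled, and the
#' pooled vector is truncated or zero-padded to `spec$outputDim`. No
#' backbone ships with the package: register one by setting
#' `options(GaborDBN.cnn_backbone = function(array224) numeric_vector)`.
#' When none is registered the function fails with an explicit
#' "adapter unavailable" error rather than silently substituting the
#' pooled extractor.
#'
#' @param image image grid.
#' @param spec a [featureExtractorSpec()].
#' @return numeric vector of length `spec$outputDim`.
#' @export
cnnAdapterFeatures <- function(image, spec) {
  backbone <- getOption("GaborDBN.cnn_backbone", NULL)
  if (is.null(backbone))
    stop("adapter unavailable: no pretrained CNN backbone is registered; ",
         "set options(GaborDBN.cnn_backbone = <function>) or use the ",
         "pooled_gabor extractor")
  img <- asImageGrid(image)
  if (is.matrix(img)) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img <- resizeImage(img, 224L, 224L)
  v <- as.numeric(backbone(img))
  if (!all(is.finite(v))) stop("backbone returned non-finite values")
  if (length(v) >= spec$outputDim) v[seq_len(spec$outputDim)]
  else c(v, numeric(spec$outputDim - length(v)))
}

#' Extract a feature matrix from a dataset
#'
#' Applies [extractFeatures()] to every image of a labelled dataset.
#'
#' @param dataset list with elements `images` (list of image grids),
#'   `labels` (character) and optionally `ids`.
#' @param spec a [featureExtractorSpec()].
#' @return list with `features` (N x D matrix), `labels`, `ids`.
#' @export
extractFeatureMatrix <- function(dataset, spec) {
  n <- length(dataset$images)
  feats <- matrix(NA_real_, n, spec$outputDim)
  for (i in seq_len(n)) feats[i, ] <- extractFeatures(dataset$images[[i]], spec)
  ids <- if (is.null(dataset$ids)) sprintf("img%03d", seq_len(n)) else dataset$ids
  list(features = feats, labels = dataset$labels, ids = ids)
}

#' Feature matrix CSV checkpointing
#'
#' One row per image: `source_id`, `label`, then `v1..vD`, full precision.
#'
#' @param fm list with `features`, `labels`, `ids` as returned by
#'   [extractFeatureMatrix()].
#' @param path CSV path.
#' @return invisibly, `path`.
#' @export
writeFeatureCSV <- function(fm, path) {
  df <- data.frame(source_id = fm$ids, label = fm$labels,
                   fm$features, check.names = FALSE)
  colnames(df) <- c("source_id", "label", paste0("v", seq_len(ncol(fm$features))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  list(features = as.matrix(df[, -(1:2), drop = FALSE]),
       labels = as.character(df$label),
       ids = as.character(df$source_id))
}
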
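#' Validate an image grid
#'
#' Images are plain numeric matrices (grayscale, rows = height) or
#' H x W x 3 arrays (colour) with finite intensities in \[0, 1\],
#' origin top-left, row-major convention.
#'
#' @param pixels matrix or 3-d array.
#' @return the validated pixels, unchanged.
#' @export
asImageGrid <- function(pixels) {
  if (!(is.matrix(pixels) || (is.array(pixels) && length(dim(pixels)) == 3 &&
                              dim(pixels)[3] == 3)))
    stop("image must be a grayscale matrix or an H x W x 3 array")
  if (!all(is.finite(pixels))) stop("image intensities must be finite")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("image intensities must lie in [0, 1]")
  pixels
}

#' Read an image file into an image grid
#'
#' PNG files are read with the png package, JPEGs with EBImage. Integer
#' sample depths are normalised to \[0, 1\] by the readers (division by the
#' type maximum); an alpha channel, if present, is dropped.
#'
#' @param path path to a PNG or JPEG file.
#' @return grayscale matrix or H x W x 3 array in \[0, 1\].
#' @export
readImageGrid <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3 && dim(px)[3] == 4) px <- px[, , 1:3, drop = FALSE]
    if (length(dim(px)) == 3 && dim(px)[3] == 2) px <- px[, , 1]
    if (length(dim(px)) == 3 && dim(px)[3] == 1) px <- px[, , 1]
  } else if (ext %in% c("jpg", "jpeg")) {
    img <- EBImage::readImage(path)
    px <- fromEBImage(img)
  } else stop("unsupported image format: ", ext)
  asImageGrid(clamp(px, 0, 1))
}

#' Convert a colour image grid to luminance
#'
#' Uses the Rec. 601 luma weights 0.299 R + 0.587 G + 0.114 B. Grayscale
#' input passes through unchanged.
#'
#' @param image grayscale matrix or H x W x 3 array.
#' @return grayscale matrix.
#' @export
toGrayscale <- function(image) {
  if (is.matrix(image)) return(image)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

# EBImage stores pixels x-by-y (width first); our grids are row-major H x W.
toEBImage <- function(image) {
  if (is.matrix(image)) EBImage::Image(t(image))
  else EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
}

fromEBImage <- function(img) {
  d <- dim(img)
  px <- EBImage::imageData(img)
  if (length(d) == 2) t(px)
  else if (d[3] >= 3) aperm(px[, , 1:3], c(2, 1, 3))
  else t(px[, , 1])
}

#' Resize an image grid
#'
#' Bilinear resampling via EBImage.
#'
#' @param image grayscale matrix or H x W x 3 array in \[0, 1\].
#' @param height,width target dimensions in pixels.
#' @return resized image grid, clipped back into \[0, 1\].
#' @export
resizeImage <- function(image, height, width) {
  image <- asImageGrid(image)
  d <- dim(image)
  if (d[1] == height && d[2] == width) return(image)
  out <- fromEBImage(EBImage::resize(toEBImage(image), w = width, h = height,
                                     filter = "bilinear"))
  clamp(out, 0, 1)
}
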
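#' Grayscale image helpers
#'
#' Images throughout the package are plain numeric matrices with intensities
#' in `[0, 1]`. `as_gray_image()` validates (and optionally rescales) a
#' matrix; `read_gray()` / `write_gray()` move images between PNG/TIFF files
#' and matrices.
#'
#' @param x A numeric matrix.
#' @param rescale If `TRUE`, linearly map the observed range onto `[0, 1]`
#'   when values fall outside it; if `FALSE` (default), out-of-range values
#'   are an error.
#' @return A numeric matrix with values in `[0, 1]`.
#' @export
as_gray_image <- function(x, rescale = FALSE) {
  if (!is.matrix(x) || !is.numeric(x)) stop("image must be a numeric matrix")
  if (nrow(x) < 1L || ncol(x) < 1L) stop("image must have at least one pixel")
  if (anyNA(x) || any(!is.finite(x))) stop("image intensities must be finite")
  rng <- range(x)
  if (rng[1] < 0 || rng[2] > 1) {
    if (!rescale) stop("image intensities must lie in [0, 1]")
    span <- rng[2] - rng[1]
    x <- if (span > 0) (x - rng[1]) / span else x * 0
  }
  x
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' @rdname as_gray_image
#' @param path Path to a PNG or TIFF file (grayscale or RGB; RGB is averaged).
#' @export
read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: ", ext)
  )
  if (length(dim(img)) == 3L) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
  as_gray_image(clamp01(img))
}

#' @rdname as_gray_image
#' @param image Matrix to write.
#' @export
write_gray <- function(image, path) {
  image <- as_gray_image(image)
  storage.mode(image) <- "double" # PNG/TIFF writers reject integer matrices
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(image, path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("writing TIFF requires the 'tiff' package")
      tiff::writeTIFF(image, path)
    },
    stop("unsupported image format: ", ext)
  )
  invisible(path)
}

#' Binary mask helpers
#'
#' Masks are integer 0/1 matrices with the same shape as their source image.
#'
#' @param x Matrix coercible to 0/1 (logical or numeric).
#' @return An integer matrix of 0s and 1s.
#' @export
as_binary_mask <- function(x) {
  if (!is.matrix(x)) stop("mask must be a matrix")
  v <- as.integer(x != 0)
  if (anyNA(v)) stop("mask contains NA")
  matrix(v, nrow(x), ncol(x))
}
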
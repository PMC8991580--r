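#' Crop a square region of interest
#'
#' Extracts a `side` x `side` crop centered on a user-supplied seed point
#' (the manual initialisation step of the semi-automated workflow). Pixels
#' of the box that fall outside the source image are filled by edge
#' replication.
#'
#' @param image Grayscale matrix in `[0, 1]`.
#' @param center `(row, col)` of the box center, inside the image.
#' @param side Box side in pixels (default 250, the standard crop size).
#' @return A `side` x `side` matrix.
#' @export
crop_roi <- function(image, center, side = 250L) {
  image <- as_gray_image(image)
  side <- as.integer(side)
  if (side < 1L) stop("side must be positive")
  r0 <- as.integer(round(center[1])); c0 <- as.integer(round(center[2]))
  if (r0 < 1L || r0 > nrow(image) || c0 < 1L || c0 > ncol(image))
    stop(sprintf("center (%d, %d) lies outside the %d x %d image",
                 r0, c0, nrow(image), ncol(image)))
  half <- side %/% 2L
  rows <- (r0 - half):(r0 - half + side - 1L)
  cols <- (c0 - half):(c0 - half + side - 1L)
  rows <- pmin(pmax(rows, 1L), nrow(image))
  cols <- pmin(pmax(cols, 1L), ncol(image))
  image[rows, cols, drop = FALSE]
}

#' Percentile contrast stretch
#'
#' Linearly rescales intensities so the `low_pct` / `high_pct` percentiles
#' map to 0 / 1, clipping the tails. A constant image (degenerate percentile
#' span) is returned unchanged.
#'
#' @param image Grayscale matrix in `[0, 1]`.
#' @param low_pct,high_pct Percentiles in `[0, 100]`, `low_pct < high_pct`.
#' @return Rescaled matrix in `[0, 1]`.
#' @export
adjust_intensity <- function(image, low_pct = 1, high_pct = 99) {
  image <- as_gray_image(image)
  if (!(low_pct >= 0 && low_pct < high_pct && high_pct <= 100))
    stop("need 0 <= low_pct < high_pct <= 100")
  q <- quantile(image, c(low_pct, high_pct) / 100, names = FALSE, type = 7)
  if (q[2] <= q[1]) return(image)
  clamp01((image - q[1]) / (q[2] - q[1]))
}

#' Median filter with edge replication
#'
#' Each output pixel is the median of its `kernel` x `kernel` neighborhood,
#' with borders handled by edge replication. Removes impulse (salt and
#' pepper) noise while preserving edges; every output value is a member of
#' the input's value set.
#'
#' @param image Grayscale matrix in `[0, 1]`.
#' @param kernel Odd window side, >= 3 (default 7).
#' @return Filtered matrix.
#' @export
median_filter <- function(image, kernel = 7L) {
  image <- as_gray_image(image)
  kernel <- as.integer(kernel)
  if (kernel < 3L || kernel %% 2L == 0L) stop("kernel must be odd and >= 3")
  .cpp_median_filter(image, kernel)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Local contrast enhancement on a tile grid with histogram clipping.
#' Backed by EBImage for grids of at least 2 x 2 tiles; a single-tile grid
#' degenerates to clipped-histogram global equalization, computed directly.
#'
#' @param image Grayscale matrix in `[0, 1]`.
#' @param clip_limit Histogram clip limit as a fraction of tile pixels per
#'   bin-uniform level (default 0.01; larger means more contrast).
#' @param tile_grid `(rows, cols)` tile counts (default `c(8, 8)`).
#' @param bins Number of histogram bins (default 256).
#' @return Enhanced matrix in `[0, 1]`.
#' @export
enhance_clahe <- function(image, clip_limit = 0.01, tile_grid = c(8L, 8L),
                          bins = 256L) {
  image <- as_gray_image(image)
  tile_grid <- as.integer(tile_grid)
  if (clip_limit <= 0) stop("clip_limit must be positive")
  if (any(tile_grid < 1L)) stop("tile_grid entries must be >= 1")
  if (any(tile_grid > dim(image)))
    stop("tile grid finer than the image: each tile must hold >= 1 pixel")
  if (diff(range(image)) == 0) return(image)
  if (prod(tile_grid) < 4L) {
    return(.clahe_global(image, clip_limit, bins))
  }
  # EBImage's limit is the clip factor relative to a uniform histogram
  limit <- clip_limit * bins
  out <- EBImage::imageData(EBImage::clahe(
    EBImage::Image(image),
    nx = tile_grid[2], ny = tile_grid[1], bins = bins, limit = limit,
    keep.range = FALSE
  ))
  clamp01(matrix(out, nrow(image), ncol(image)))
}

# Clipped-histogram global equalization: the 1-tile degenerate case of CLAHE.
.clahe_global <- function(image, clip_limit, bins) {
  n <- length(image)
  idx <- pmin(floor(image * bins) + 1L, bins)
  h <- tabulate(idx, nbins = bins)
  cap <- max(1, clip_limit * bins * n / bins) # = clip_limit * n
  excess <- sum(pmax(h - cap, 0))
  h <- pmin(h, cap) + excess / bins
  cdf <- cumsum(h) / sum(h)
  # map each level to its cdf, anchored like standard histogram equalization
  matrix(cdf[idx], nrow(image), ncol(image))
}

#' Standard ROI preprocessing chain
#'
#' Crop about the seed point, stretch intensities, median-filter; optionally
#' CLAHE-enhance (the enhancement used on the segmentation path).
#'
#' @inheritParams crop_roi
#' @inheritParams adjust_intensity
#' @inheritParams median_filter
#' @param clahe Apply CLAHE after filtering (default `FALSE`).
#' @param ... Passed to [enhance_clahe()].
#' @return Preprocessed `side` x `side` matrix.
#' @export
preprocess_roi <- function(image, center = NULL, side = 250L, low_pct = 1,
                           high_pct = 99, kernel = 7L, clahe = FALSE, ...) {
  if (is.null(center)) center <- (dim(image) + 1) / 2
  out <- crop_roi(image, center, side)
  out <- adjust_intensity(out, low_pct, high_pct)
  out <- median_filter(out, kernel)
  if (clahe) out <- enhance_clahe(out, ...)
  out
}
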
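#' Augmentation plan
#'
#' Describes how each labeled image is expanded into `factor` variants.
#' The transform families are geometric and photometric perturbations that
#' preserve the stage label: down/up-resampling ("resize"), content zoom
#' ("rescale"), rotation, horizontal flip, crop-and-restore, mild Gaussian
#' blur ("filter") and brightness shifts. Magnitudes default to
#' anatomy-plausible ranges.
#'
#' @param factor Variants per input, original included (default 10).
#' @param transforms Subset of
#'   `c("resize","rescale","rotate","flip","crop","filter","brightness")`.
#' @param rotate_deg Max absolute rotation, degrees (default 15).
#' @param flip_prob Probability of a horizontal flip (default 0.5).
#' @param crop_range Retained side fraction before restoring size
#'   (default `c(0.9, 1)`).
#' @param brightness_delta Max absolute intensity shift (default 0.1).
#' @param blur_sigma Range of the Gaussian blur s.d. in pixels
#'   (default `c(0, 1)`).
#' @param rescale_range Content zoom factor range (default `c(0.9, 1.1)`).
#' @param resize_range Resampling factor range for the resolution
#'   degradation transform (default `c(0.7, 1)`).
#' @return An `augment_plan` list.
#' @export
augment_plan <- function(factor = 10L,
                         transforms = c("resize", "rescale", "rotate",
                                        "flip", "crop", "filter",
                                        "brightness"),
                         rotate_deg = 15, flip_prob = 0.5,
                         crop_range = c(0.9, 1), brightness_delta = 0.1,
                         blur_sigma = c(0, 1), rescale_range = c(0.9, 1.1),
                         resize_range = c(0.7, 1)) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be >= 1")
  known <- c("resize", "rescale", "rotate", "flip", "crop", "filter",
             "brightness")
  if (length(transforms) == 0L) {
    if (factor > 1L)
      stop("factor > 1 requires at least one enabled transform")
  } else {
    transforms <- match.arg(transforms, known, several.ok = TRUE)
  }
  structure(
    list(factor = factor, transforms = transforms, rotate_deg = rotate_deg,
         flip_prob = flip_prob, crop_range = crop_range,
         brightness_delta = brightness_delta, blur_sigma = blur_sigma,
         rescale_range = rescale_range, resize_range = resize_range),
    class = "augment_plan"
  )
}

# zoom the content by factor f about the center, keeping the frame size
.zoom_keep_frame <- function(img, f) {
  side_r <- nrow(img); side_c <- ncol(img)
  z <- EBImage::resize(EBImage::Image(img), w = max(round(side_r * f), 2),
                       h = max(round(side_c * f), 2))
  z <- EBImage::imageData(z)
  if (f >= 1) { # crop center back to frame
    r0 <- (nrow(z) - side_r) %/% 2; c0 <- (ncol(z) - side_c) %/% 2
    z[r0 + seq_len(side_r), c0 + seq_len(side_c), drop = FALSE]
  } else {      # pad with the image's background level
    out <- matrix(stats::median(img[c(1, nrow(img)), ]), side_r, side_c)
    r0 <- (side_r - nrow(z)) %/% 2; c0 <- (side_c - ncol(z)) %/% 2
    out[r0 + seq_len(nrow(z)), c0 + seq_len(ncol(z))] <- z
    out
  }
}

.apply_random_transforms <- function(img, plan) {
  side_r <- nrow(img); side_c <- ncol(img)
  tf <- plan$transforms
  if ("rotate" %in% tf) {
    ang <- runif(1, -plan$rotate_deg, plan$rotate_deg)
    bg <- stats::median(img[c(1, nrow(img)), ])
    rot <- EBImage::rotate(EBImage::Image(img), ang, bg.col = bg,
                           output.dim = c(side_r, side_c))
    img <- clamp01(matrix(EBImage::imageData(rot), side_r, side_c))
  }
  if ("flip" %in% tf && runif(1) < plan$flip_prob)
    img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
  if ("rescale" %in% tf)
    img <- .zoom_keep_frame(img, runif(1, plan$rescale_range[1],
                                       plan$rescale_range[2]))
  if ("crop" %in% tf) {
    keep <- runif(1, plan$crop_range[1], plan$crop_range[2])
    kr <- max(round(side_r * keep), 2); kc <- max(round(side_c * keep), 2)
    r0 <- sample.int(side_r - kr + 1L, 1L) - 1L
    c0 <- sample.int(side_c - kc + 1L, 1L) - 1L
    sub <- img[r0 + seq_len(kr), c0 + seq_len(kc), drop = FALSE]
    img <- EBImage::imageData(EBImage::resize(EBImage::Image(sub),
                                              w = side_r, h = side_c))
  }
  if ("resize" %in% tf) { # resolution degradation: down- then up-sample
    f <- runif(1, plan$resize_range[1], plan$resize_range[2])
    small <- EBImage::resize(EBImage::Image(img),
                             w = max(round(side_r * f), 2),
                             h = max(round(side_c * f), 2))
    img <- EBImage::imageData(EBImage::resize(small, w = side_r, h = side_c))
  }
  if ("filter" %in% tf) {
    s <- runif(1, plan$blur_sigma[1], plan$blur_sigma[2])
    if (s > 0.05)
      img <- EBImage::imageData(EBImage::gblur(EBImage::Image(img),
                                               sigma = s))
  }
  if ("brightness" %in% tf)
    img <- img + runif(1, -plan$brightness_delta, plan$brightness_delta)
  clamp01(matrix(img, side_r, side_c))
}

#' Augment a single image
#'
#' Returns exactly `plan$factor` label-preserving variants; the unmodified
#' original is variant 1. All randomness derives from `seed`, so a fixed
#' seed reproduces identical variants.
#'
#' @param image Grayscale matrix in `[0, 1]`.
#' @param plan An [augment_plan()].
#' @param seed Integer seed.
#' @return List of `plan$factor` matrices of the input's size.
#' @export
augment_image <- function(image, plan = augment_plan(), seed = 1L) {
  image <- as_gray_image(image)
  stopifnot(inherits(plan, "augment_plan"))
  if (plan$factor == 1L) return(list(image))
  variants <- withr::with_seed(as.integer(seed), {
    purrr::map(seq_len(plan$factor - 1L),
               function(i) .apply_random_transforms(image, plan))
  })
  c(list(image), variants)
}

#' Expand a labeled dataset by augmentation
#'
#' Applies [augment_image()] to every row: the output has
#' `factor * nrow(data)` rows and every per-(stage, cohort) cell count is
#' multiplied by `factor` (e.g. 240 cases expand to 2400). Augmentation is
#' meant for the training partition; split first ([split_dataset()]) to
#' keep augmented copies out of the test set.
#'
#' @param data Tibble with list-column `image` and column `stage` (plus any
#'   other columns, which are carried along).
#' @param plan An [augment_plan()].
#' @param seed Integer seed; each row's variants derive from
#'   `seed + row index`.
#' @return Tibble like `data` with an added `variant` column (1 =
#'   original).
#' @export
expand_dataset <- function(data, plan = augment_plan(), seed = 1L) {
  if (!is.data.frame(data)) stop("data must be a data frame")
  if (nrow(data) == 0L) return(dplyr::mutate(data, variant = integer()))
  if (!"image" %in% names(data)) stop("data needs an 'image' list-column")
  seeds <- as.integer((as.numeric(seed) + seq_len(nrow(data))) %% 2147483647)
  out <- data
  out$.variants <- purrr::map2(data$image, seeds,
                               function(img, s) augment_image(img, plan, s))
  out$image <- NULL
  out <- tidyr::unnest_longer(out, ".variants", values_to = "image",
                              indices_to = "variant")
  dplyr::relocate(as_tibble(out), "image", "variant",
                  .after = dplyr::last_col())
}
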
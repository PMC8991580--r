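#' Segmentation overlap scores
#'
#' `dice()` is `2|A∩B| / (|A| + |B|)` (the F1 score of the foreground);
#' `jaccard()` is `|A∩B| / |A∪B|`. Both are 1 when the two masks are both
#' empty, and satisfy `jaccard = dice / (2 - dice)`.
#'
#' @param a,b Binary masks of equal shape.
#' @return A score in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- as_binary_mask(a); b <- as_binary_mask(b)
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(1)
  2 * sum(a & b) / (na + nb)
}

#' @rdname dice
#' @export
jaccard <- function(a, b) {
  a <- as_binary_mask(a); b <- as_binary_mask(b)
  if (!all(dim(a) == dim(b))) stop("mask shapes differ")
  u <- sum(a | b)
  if (u == 0L) return(1)
  sum(a & b) / u
}

#' Qualitative segmentation grade
#'
#' Classifies a predicted mask against ground truth as under-segmented
#' (missing more than `tol` of the true region while adding little),
#' over-segmented (spurious area exceeding `tol` of the true region), or
#' well-segmented. The thresholded rule makes the visual judgement of
#' segmentation quality reproducible.
#'
#' @param pred,truth Binary masks of equal shape; `truth` must be nonempty.
#' @param tol Tolerated fraction of the true area (default 0.2).
#' @return One of `"under"`, `"well"`, `"over"`.
#' @export
grade_segmentation <- function(pred, truth, tol = 0.2) {
  pred <- as_binary_mask(pred); truth <- as_binary_mask(truth)
  if (!all(dim(pred) == dim(truth))) stop("mask shapes differ")
  nt <- sum(truth)
  if (nt == 0L) stop("truth mask is empty")
  excess <- sum(pred & !truth) / nt
  missing <- sum(truth & !pred) / nt
  if (excess > tol) "over" else if (missing > tol) "under" else "well"
}
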
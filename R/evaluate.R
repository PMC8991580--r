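#' Confusion matrix over stages
#'
#' Cross-tabulates reference stages (rows) against predicted stages
#' (columns) in the fixed order C-H.
#'
#' @param true_labels,pred_labels Equal-length vectors of stages C-H.
#' @return A `stage_confusion` 6x6 integer matrix.
#' @export
confusion <- function(true_labels, pred_labels) {
  t <- as_stage(true_labels); p <- as_stage(pred_labels)
  if (length(t) != length(p)) stop("label vectors differ in length")
  m <- table(reference = t, predicted = p)
  structure(matrix(as.integer(m), 6, 6,
                   dimnames = list(reference = stage_levels(),
                                   predicted = stage_levels())),
            class = "stage_confusion")
}

as_confusion <- function(m) {
  if (inherits(m, "stage_confusion")) return(unclass(m))
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("need a square count matrix")
  if (any(m < 0) || any(m != round(m))) stop("counts must be nonnegative integers")
  unclass(m)
}

#' @export
print.stage_confusion <- function(x, ...) {
  cat("Stage confusion matrix (rows = reference, cols = predicted)\n")
  print(unclass(x))
  invisible(x)
}

#' Row-normalized confusion proportions
#'
#' Each row is divided by its total (zero rows stay zero), matching the
#' conventional display of per-reference-stage proportions.
#'
#' @param m A confusion matrix (counts).
#' @param digits Optional rounding for display (`NULL` = none).
#' @return Matrix of fractions; nonzero rows sum to 1.
#' @export
row_normalize <- function(m, digits = NULL) {
  m <- as_confusion(m)
  rs <- rowSums(m)
  out <- sweep(m, 1, ifelse(rs == 0, 1, rs), "/")
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Overall accuracy
#'
#' @param m A confusion matrix (counts), nonempty.
#' @return `trace / total`.
#' @export
overall_accuracy <- function(m) {
  m <- as_confusion(m)
  n <- sum(m)
  if (n == 0) stop("empty confusion matrix")
  sum(diag(m)) / n
}

#' Cohen's kappa
#'
#' Unweighted chance-corrected agreement:
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = trace/total` and chance agreement
#' `p_e = sum_k row_k * col_k / total^2`. When `p_e = 1` (all mass in one
#' cell) kappa is 1 if agreement is perfect and an error otherwise.
#'
#' @param m A confusion matrix (counts), nonempty.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(m) {
  m <- as_confusion(m)
  n <- sum(m)
  if (n == 0) stop("empty confusion matrix")
  po <- sum(diag(m)) / n
  pe <- sum(rowSums(m) * colSums(m)) / n^2
  if (abs(1 - pe) < 1e-12) {
    if (abs(1 - po) < 1e-12) return(1)
    stop("degenerate margins: chance agreement is 1 but agreement is not perfect")
  }
  (po - pe) / (1 - pe)
}

#' Per-stage recall
#'
#' @param m A confusion matrix (counts).
#' @return Named vector of `diag / rowSums` (NA for absent stages).
#' @export
per_stage_recall <- function(m) {
  m <- as_confusion(m)
  rs <- rowSums(m)
  r <- ifelse(rs == 0, NA_real_, diag(m) / rs)
  names(r) <- rownames(m)
  r
}

#' Agreement report
#'
#' The full evaluation of predictions against reference stages: counts,
#' row-normalized proportions, overall accuracy, Cohen's kappa and
#' per-stage recall.
#'
#' @inheritParams confusion
#' @return An `agreement_report` list.
#' @export
agreement_report <- function(true_labels, pred_labels) {
  m <- confusion(true_labels, pred_labels)
  structure(
    list(counts = m, proportions = row_normalize(m),
         overall_accuracy = overall_accuracy(m), kappa = cohen_kappa(m),
         per_stage_recall = per_stage_recall(m), n = sum(unclass(m))),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement over %d cases\n", x$n))
  print(round(x$proportions, 2))
  cat(sprintf("Overall accuracy: %.2f   Kappa index: %.2f\n",
              x$overall_accuracy, x$kappa))
  invisible(x)
}

#' Learning-curve summary
#'
#' Reports the best epoch (argmin of validation loss), the minimum
#' validation loss, and the overfitting onset: the first epoch at which
#' validation loss exceeds its running minimum for at least two
#' consecutive epochs (NA when that never happens).
#'
#' @param history Tibble with columns `epoch` and `val_loss` (as produced
#'   by [train_stage_cnn()]).
#' @return Tibble: `best_epoch`, `min_val_loss`, `overfit_onset`.
#' @export
summarize_history <- function(history) {
  if (!all(c("epoch", "val_loss") %in% names(history)))
    stop("history needs columns 'epoch' and 'val_loss'")
  vl <- history$val_loss
  best <- which.min(vl)
  onset <- NA_integer_
  runmin <- Inf
  streak <- 0L
  for (i in seq_along(vl)) {
    if (vl[i] > runmin) {
      streak <- streak + 1L
      if (streak >= 2L) { onset <- history$epoch[i - streak + 1L]; break }
    } else {
      streak <- 0L
    }
    runmin <- min(runmin, vl[i])
  }
  tibble(best_epoch = history$epoch[best], min_val_loss = vl[best],
         overfit_onset = onset)
}

#' Evaluate a trained model on labeled data
#'
#' @param model A trained `stage_cnn`.
#' @param data Labeled tibble (`image`, `stage`).
#' @return An [agreement_report()].
#' @export
evaluate_model <- function(model, data) {
  pred <- predict(model, data, type = "stage")
  agreement_report(data$stage, pred)
}
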
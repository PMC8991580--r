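#' Tidy a fitted classifier
#'
#' One row per layer with output shape and parameter count, broom-style.
#'
#' @param x A `stage_cnn`.
#' @param ... Unused.
#' @return A tibble (see [layer_shapes()]).
#' @export
tidy.stage_cnn <- function(x, ...) layer_shapes(x)

#' One-row model summary
#'
#' @param x A `stage_cnn`.
#' @param ... Unused.
#' @return Tibble with `input_side`, `n_layers`, `total_params`,
#'   `flatten_length`, `trained`, and final accuracies when trained.
#' @export
glance.stage_cnn <- function(x, ...) {
  sh <- x$shapes
  out <- tibble(
    input_side = x$spec$input_side, n_layers = nrow(sh),
    total_params = attr(sh, "total"),
    flatten_length = attr(sh, "flatten_length"), trained = x$trained,
    final_train_accuracy = NA_real_, final_val_accuracy = NA_real_
  )
  if (x$trained && !is.null(x$history)) {
    out$final_train_accuracy <- x$history$train_accuracy[nrow(x$history)]
    out$final_val_accuracy <- x$history$val_accuracy[nrow(x$history)]
  }
  out
}

#' Tidy an agreement report
#'
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @return Long tibble: `reference`, `predicted`, `n`, `proportion`.
#' @export
tidy.agreement_report <- function(x, ...) {
  m <- unclass(x$counts)
  p <- x$proportions
  tidyr::crossing(reference = factor(stage_levels(), stage_levels()),
                  predicted = factor(stage_levels(), stage_levels())) |>
    dplyr::mutate(
      n = as.integer(m[cbind(as.character(.data$reference),
                             as.character(.data$predicted))]),
      proportion = p[cbind(as.character(.data$reference),
                           as.character(.data$predicted))]
    )
}

#' @rdname tidy.agreement_report
#' @export
glance.agreement_report <- function(x, ...) {
  tibble(n = x$n, overall_accuracy = x$overall_accuracy, kappa = x$kappa)
}

# broom generics re-exported so tidy()/glance() work without loading broom
#' @export
tidy <- function(x, ...) UseMethod("tidy")
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot a training history
#'
#' Loss and accuracy learning curves, faceted, for one history tibble or
#' the long output of [compare_optimizers()].
#'
#' @param history Tibble with `epoch`, `train_loss`, `train_accuracy`,
#'   `val_loss`, `val_accuracy` and optionally `optimizer`.
#' @return A ggplot object.
#' @export
plot_history <- function(history) {
  long <- tidyr::pivot_longer(history,
                              cols = c("train_loss", "train_accuracy",
                                       "val_loss", "val_accuracy"),
                              names_to = c("split", "metric"),
                              names_pattern = "(train|val)_(.*)")
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                          linetype = .data$split))
  p <- if ("optimizer" %in% names(history)) {
    p + ggplot2::geom_line(ggplot2::aes(color = .data$optimizer))
  } else {
    p + ggplot2::geom_line(color = "steelblue")
  }
  p + ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a confusion matrix
#'
#' Row-normalized proportions as a heat map with counts printed.
#'
#' @param x An `agreement_report` or `stage_confusion`.
#' @return A ggplot object.
#' @export
plot_confusion <- function(x) {
  rep <- if (inherits(x, "agreement_report")) x
         else list(counts = x, proportions = row_normalize(x))
  df <- tidy.agreement_report(list(counts = as_confusion(rep$counts),
                                   proportions = rep$proportions))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted,
                                   y = factor(.data$reference,
                                              rev(stage_levels())),
                                   fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "predicted stage", y = "reference stage") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @method autoplot agreement_report
#' @export
autoplot.agreement_report <- function(object, ...) plot_confusion(object)

#' Plot a segmentation result
#'
#' The image with the optimal contour overlaid.
#'
#' @param object A `tooth_segmentation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tooth_segmentation
#' @export
autoplot.tooth_segmentation <- function(object, ...) {
  df <- tidyr::crossing(row = seq_len(nrow(object$mask)),
                        col = seq_len(ncol(object$mask)))
  df$value <- as.numeric(t(object$roi))
  pts <- as.data.frame(object$contour$points)
  names(pts) <- c("row", "col")
  ggplot2::ggplot() +
    ggplot2::geom_raster(data = df,
                         ggplot2::aes(x = .data$col, y = .data$row,
                                      fill = .data$value)) +
    ggplot2::geom_path(data = rbind(pts, pts[1, ]),
                       ggplot2::aes(x = .data$col, y = .data$row),
                       color = "red") +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::guides(fill = "none")
}
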
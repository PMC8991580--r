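#' Architecture grid search
#'
#' Trains one model per combination of hidden-dense-layer count, layer
#' size and convolution-stage count (27 candidates at the default
#' options) on a shared stratified split, and ranks them by final
#' validation loss — lowest first, the selection rule used for the model
#' family.
#'
#' @param data Labeled tibble (`image`, `stage`).
#' @param dense_options,size_options,conv_options Option vectors; defaults
#'   `c(0, 1, 2)`, `c(16, 32, 64)`, `c(1, 2, 3)`.
#' @param config A [train_config()]; the same seed is reused for every
#'   candidate so splits and shuffling match.
#' @param input_side Input side for the candidate family (default 90).
#' @param keep_models Keep every trained model in a list-column (default
#'   `FALSE`: only the best model is retained, in attribute
#'   `"best_model"`).
#' @return Tibble ranked by `val_loss` with columns `conv_layers`,
#'   `layer_size`, `dense_layers`, `val_loss`, `val_accuracy`,
#'   `train_loss`, `train_accuracy` (finals), plus `model` if
#'   `keep_models`.
#' @export
grid_search_models <- function(data, dense_options = c(0L, 1L, 2L),
                               size_options = c(16L, 32L, 64L),
                               conv_options = c(1L, 2L, 3L),
                               config = train_config(),
                               input_side = 90L, keep_models = FALSE) {
  combos <- expand.grid(dense_layers = dense_options,
                        layer_size = size_options,
                        conv_layers = conv_options)
  fits <- purrr::pmap(combos, function(dense_layers, layer_size, conv_layers) {
    spec <- grid_architecture(conv_layers, layer_size, dense_layers,
                              input_side = input_side)
    model <- build_model(spec, seed = config$seed)
    train_stage_cnn(model, data, config)
  })
  out <- as_tibble(combos)
  out$train_loss <- purrr::map_dbl(fits, ~ .x$history$train_loss[config$epochs])
  out$train_accuracy <- purrr::map_dbl(fits, ~ .x$history$train_accuracy[config$epochs])
  out$val_loss <- purrr::map_dbl(fits, ~ .x$history$val_loss[config$epochs])
  out$val_accuracy <- purrr::map_dbl(fits, ~ .x$history$val_accuracy[config$epochs])
  if (keep_models) out$model <- fits
  ord <- order(out$val_loss)
  out <- out[ord, , drop = FALSE]
  out <- dplyr::relocate(out, "conv_layers", "layer_size", "dense_layers")
  attr(out, "best_model") <- fits[[ord[1]]]
  out
}

#' Optimizer comparison
#'
#' Trains the same architecture from the same initial weights under each
#' optimizer (Adam, SGD, RMSProp, AdaGrad by default) over a longer run,
#' on identical splits and shuffling seeds. An epoch-0 row records the
#' shared pre-training loss/accuracy.
#'
#' @param data Labeled tibble (`image`, `stage`).
#' @param config A [train_config()]; its `epochs` is overridden by
#'   `epochs`.
#' @param optimizers Character vector of optimizers to run.
#' @param epochs Epochs per optimizer (default 50).
#' @param spec Architecture (default the reference one).
#' @return Long tibble: `optimizer`, `epoch` (0..epochs), `train_loss`,
#'   `train_accuracy`, `val_loss`, `val_accuracy`.
#' @export
compare_optimizers <- function(data, config = train_config(),
                               optimizers = c("adam", "sgd", "rmsprop",
                                              "adagrad"),
                               epochs = 50L,
                               spec = reference_architecture()) {
  model0 <- build_model(spec, seed = config$seed)
  parts <- split_dataset(data, 1 - config$validation_fraction,
                         seed = config$seed)
  ini <- .model_loss(model0, parts$test)
  purrr::map_dfr(optimizers, function(opt) {
    cfg <- config
    cfg$optimizer <- opt
    cfg$epochs <- as.integer(epochs)
    fit <- train_stage_cnn(model0, data, cfg)
    dplyr::bind_rows(
      tibble(optimizer = opt, epoch = 0L, train_loss = NA_real_,
             train_accuracy = NA_real_, val_loss = ini$loss,
             val_accuracy = ini$accuracy),
      dplyr::mutate(fit$history, optimizer = opt, .before = 1)
    )
  })
}

#' Dropout study
#'
#' Re-trains the reference architecture with dropout on the 30-unit dense
#' layer at each rate and reports the final training and validation
#' accuracies — the capacity/regularization trade-off table.
#'
#' @param data Labeled tibble (`image`, `stage`).
#' @param config A [train_config()].
#' @param rates Dropout rates; `NA` means no dropout layer (default
#'   `c(NA, 0.1, 0.5, 0.7, 0.9)`).
#' @param spec_fn Function mapping a dropout rate (or `NULL`) to an
#'   `arch_spec`; defaults to [reference_architecture()].
#' @return Tibble: `rate`, `train_accuracy`, `val_accuracy`.
#' @export
dropout_study <- function(data, config = train_config(),
                          rates = c(NA, 0.1, 0.5, 0.7, 0.9),
                          spec_fn = reference_architecture) {
  purrr::map_dfr(rates, function(r) {
    spec <- spec_fn(dropout = if (is.na(r) || r == 0) NULL else r)
    fit <- train_stage_cnn(build_model(spec, seed = config$seed), data, config)
    tibble(rate = r,
           train_accuracy = fit$history$train_accuracy[config$epochs],
           val_accuracy = fit$history$val_accuracy[config$epochs])
  })
}
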
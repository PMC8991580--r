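#' Convolutional architecture specification
#'
#' Describes the six-stage classifier as a stack of 3x3 convolutions (some
#' strided, for in-layer downsampling), 2x2 max pools, a flatten, hidden
#' dense layers and a softmax output. Spatial bookkeeping uses "same"
#' padding, so a stride-s convolution maps side `n` to `ceiling(n / s)`
#' and a 2x2 pool to `floor(n / 2)`.
#'
#' @param input_side Input image side in pixels (images are resized to
#'   this with bilinear interpolation before entering the network).
#' @param channels Input channels (1 for grayscale).
#' @param conv_filters Filters per convolution stage.
#' @param conv_strides Stride per convolution stage (same length).
#' @param pool_after Indices of convolution stages followed by a 2x2 pool.
#' @param dense_widths Hidden dense layer widths (may be empty).
#' @param n_classes Output classes (default 6, stages C-H).
#' @param dropout Dropout rate applied after the last hidden dense layer,
#'   or `NULL` for none.
#' @return An `arch_spec` object.
#' @export
architecture_spec <- function(input_side = 90L, channels = 1L,
                              conv_filters = c(64, 64, 64, 64),
                              conv_strides = c(1, 3, 1, 3),
                              pool_after = c(2, 4), dense_widths = 30,
                              n_classes = 6L, dropout = NULL) {
  if (length(conv_strides) != length(conv_filters))
    stop("conv_strides and conv_filters must have equal length")
  if (!is.null(dropout) && (dropout < 0 || dropout >= 1))
    stop("dropout must be in [0, 1)")
  spec <- structure(
    list(input_side = as.integer(input_side), channels = as.integer(channels),
         conv_filters = as.integer(conv_filters),
         conv_strides = as.integer(conv_strides),
         pool_after = as.integer(pool_after),
         dense_widths = as.integer(dense_widths),
         n_classes = as.integer(n_classes),
         dropout = dropout),
    class = "arch_spec"
  )
  layer_shapes(spec) # validates spatial dims
  spec
}

#' The reference architecture
#'
#' The fully specified network used throughout: 90x90x1 input; four
#' stages of 64 3x3 filters with strides 1, 3, 1, 3; 2x2 pools after
#' stages 2 and 4 (feature-map sides 90, 30, 15, 15, 5, 2); flatten to
#' 256; dense 30; dense 6 with softmax. 119,320 trainable parameters.
#'
#' @param dropout Optional dropout rate on the 30-unit dense layer.
#' @return An `arch_spec`.
#' @export
reference_architecture <- function(dropout = NULL) {
  architecture_spec(dropout = dropout)
}

#' Architecture for the model-family grid search
#'
#' The family searched over in model selection: `conv_layers` stages of
#' `layer_size` 3x3 stride-1 filters, each followed by a 2x2 pool, then
#' `dense_layers` hidden dense layers of `layer_size` units.
#'
#' @param conv_layers,layer_size,dense_layers Family coordinates.
#' @inheritParams architecture_spec
#' @return An `arch_spec`.
#' @export
grid_architecture <- function(conv_layers, layer_size, dense_layers,
                              input_side = 90L, dropout = NULL) {
  architecture_spec(
    input_side = input_side,
    conv_filters = rep(layer_size, conv_layers),
    conv_strides = rep(1L, conv_layers),
    pool_after = seq_len(conv_layers),
    dense_widths = rep(layer_size, dense_layers),
    dropout = dropout
  )
}

# engine layer list for an arch_spec
.arch_layers <- function(spec) {
  layers <- list()
  for (i in seq_along(spec$conv_filters)) {
    layers <- c(layers, list(list(type = "conv",
                                  filters = spec$conv_filters[i],
                                  kernel = 3L,
                                  stride = spec$conv_strides[i]),
                             list(type = "relu")))
    if (i %in% spec$pool_after)
      layers <- c(layers, list(list(type = "pool", size = 2L)))
  }
  layers <- c(layers, list(list(type = "flatten")))
  for (w in spec$dense_widths) {
    layers <- c(layers, list(list(type = "dense", units = w),
                             list(type = "relu")))
    }
  if (!is.null(spec$dropout) && spec$dropout > 0)
    layers <- c(layers, list(list(type = "dropout", rate = spec$dropout)))
  c(layers, list(list(type = "dense", units = spec$n_classes)))
}

#' Per-layer output shapes and parameter counts
#'
#' Closed-form bookkeeping: a convolution holds
#' `(k^2 * c_in + 1) * c_out` parameters, a dense layer
#' `(n_in + 1) * n_out`; activations, pools, flatten and dropout hold
#' none. Rejects any specification whose feature map collapses to a
#' non-positive size, naming the offending layer.
#'
#' @param spec An `arch_spec` (or a `stage_cnn`, whose spec is used).
#' @return Tibble with `layer`, `type`, `output_shape` (string), `side`,
#'   `channels`, `n_param`; total parameters in attribute `"total"`.
#' @export
layer_shapes <- function(spec) {
  if (inherits(spec, "stage_cnn")) spec <- spec$spec
  side <- spec$input_side; ch <- spec$channels
  rows <- list()
  add <- function(name, type, side, ch, params) {
    rows[[length(rows) + 1L]] <<- tibble(
      layer = name, type = type,
      output_shape = sprintf("(%d, %d, %d)", side, side, ch),
      side = side, channels = ch, n_param = params)
  }
  ci <- 0L
  for (i in seq_along(spec$conv_filters)) {
    s <- spec$conv_strides[i]
    new_side <- as.integer(ceiling(side / s))
    if (new_side < 1L)
      stop(sprintf("conv stage %d collapses the feature map (side %d, stride %d)",
                   i, side, s))
    params <- (9L * ch + 1L) * spec$conv_filters[i]
    add(sprintf("conv2d_%d", i), "conv", new_side, spec$conv_filters[i], params)
    add(sprintf("activation_%d", i), "relu", new_side, spec$conv_filters[i], 0L)
    side <- new_side; ch <- spec$conv_filters[i]
    if (i %in% spec$pool_after) {
      side <- side %/% 2L
      if (side < 1L)
        stop(sprintf("pool after conv stage %d collapses the feature map", i))
      add(sprintf("max_pooling2d_%d", i), "pool", side, ch, 0L)
    }
    ci <- i
  }
  flat <- side * side * ch
  rows[[length(rows) + 1L]] <- tibble(layer = "flatten", type = "flatten",
                                      output_shape = sprintf("(%d)", flat),
                                      side = NA_integer_, channels = NA_integer_,
                                      n_param = 0L)
  nin <- flat
  for (j in seq_along(spec$dense_widths)) {
    w <- spec$dense_widths[j]
    rows[[length(rows) + 1L]] <- tibble(
      layer = sprintf("dense_%d", j), type = "dense",
      output_shape = sprintf("(%d)", w), side = NA_integer_,
      channels = NA_integer_, n_param = (nin + 1L) * w)
    nin <- w
  }
  rows[[length(rows) + 1L]] <- tibble(
    layer = "dense_output", type = "dense",
    output_shape = sprintf("(%d)", spec$n_classes), side = NA_integer_,
    channels = NA_integer_, n_param = (nin + 1L) * spec$n_classes)
  out <- dplyr::bind_rows(rows)
  attr(out, "total") <- sum(out$n_param)
  attr(out, "flatten_length") <- flat
  out
}

#' Build an untrained model
#'
#' Instantiates the network with He-normal initial weights, deterministic
#' in `seed`.
#'
#' @param spec An `arch_spec` (default: the reference architecture).
#' @param seed Integer seed for weight initialization.
#' @return A `stage_cnn` object.
#' @export
build_model <- function(spec = reference_architecture(), seed = 1L) {
  stopifnot(inherits(spec, "arch_spec"))
  layers <- .arch_layers(spec)
  weights <- .cpp_cnn_init(layers, spec$input_side, spec$channels,
                           as.integer(seed))
  structure(
    list(spec = spec, layers = layers, weights = weights,
         shapes = layer_shapes(spec), trained = FALSE, history = NULL,
         config = NULL, classes = stage_levels(), seed = as.integer(seed)),
    class = "stage_cnn"
  )
}

#' @export
print.stage_cnn <- function(x, ...) {
  cat(sprintf("<stage_cnn> %dx%d input, %s parameters, %s\n",
              x$spec$input_side, x$spec$input_side,
              format(attr(x$shapes, "total"), big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Count model parameters
#'
#' @param model A `stage_cnn` or `arch_spec`.
#' @return Tibble of per-layer counts (see [layer_shapes()]); the total is
#'   in attribute `"total"`.
#' @export
count_parameters <- function(model) layer_shapes(model)

#' Training protocol
#'
#' @param optimizer One of `"adam"`, `"sgd"`, `"rmsprop"`, `"adagrad"`.
#' @param learning_rate Step size (default 1e-3).
#' @param beta1,beta2 Adam moment decays (defaults 0.9 and 0.999).
#' @param epochs Training epochs (default 10).
#' @param batch_size Mini-batch size (default 8).
#' @param validation_fraction Stratified fraction of the training data
#'   held out for the per-epoch validation curve (default 0.2).
#' @param seed Seed for shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(optimizer = c("adam", "sgd", "rmsprop", "adagrad"),
                         learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         epochs = 10L, batch_size = 8L,
                         validation_fraction = 0.2, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (epochs < 1L || batch_size < 1L) stop("epochs and batch_size must be >= 1")
  if (validation_fraction < 0 || validation_fraction >= 1)
    stop("validation_fraction must be in [0, 1)")
  structure(
    list(optimizer = optimizer, learning_rate = learning_rate,
         beta1 = beta1, beta2 = beta2, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size),
         validation_fraction = validation_fraction, seed = as.integer(seed)),
    class = "train_config"
  )
}

# images (list of matrices) -> d x n matrix in engine layout, resized
.prepare_x <- function(images, side) {
  cols <- purrr::map(images, function(m) {
    m <- as_gray_image(m)
    if (!all(dim(m) == c(side, side))) {
      m <- EBImage::imageData(EBImage::resize(EBImage::Image(m),
                                              w = side, h = side))
      m <- clamp01(matrix(m, side, side))
    }
    as.numeric(m)
  })
  matrix(unlist(cols), nrow = side * side, ncol = length(images))
}

.stage_index0 <- function(stage) as.integer(as_stage(stage)) - 1L

#' Stratified train/test split
#'
#' Splits per stage so class proportions are preserved; within each stage
#' the partition sizes differ from the exact fractions by at most one
#' case. Deterministic in `seed`.
#'
#' @param data Tibble with a `stage` column.
#' @param train_fraction Fraction allocated to training+validation
#'   (default 0.8).
#' @param seed Integer seed.
#' @return List with tibbles `train` and `test`.
#' @export
split_dataset <- function(data, train_fraction = 0.8, seed = 1L) {
  if (!is.data.frame(data) || !"stage" %in% names(data))
    stop("data must be a data frame with a 'stage' column")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  stages <- as_stage(data$stage)
  take <- withr::with_seed(as.integer(seed), {
    unlist(lapply(levels(stages), function(s) {
      idx <- which(stages == s)
      if (!length(idx)) return(integer())
      sample(idx, round(train_fraction * length(idx)))
    }))
  })
  list(train = data[sort(take), , drop = FALSE],
       test = data[setdiff(seq_len(nrow(data)), take), , drop = FALSE])
}

# internal: loss/accuracy of a model on a labeled tibble
.model_loss <- function(model, data) {
  p <- predict(model, data, type = "prob")
  y <- .stage_index0(data$stage) + 1L
  ptrue <- pmax(p[cbind(seq_len(nrow(p)), y)], 1e-12)
  list(loss = mean(-log(ptrue)),
       accuracy = mean(max.col(p, ties.method = "first") == y))
}

#' Train the classifier
#'
#' Trains with softmax cross-entropy. A stratified
#' `validation_fraction` of the supplied data is held out for the
#' per-epoch validation curve; the rest is the gradient set. All
#' randomness (shuffling, dropout) is seeded.
#'
#' @param model An untrained or trained `stage_cnn`.
#' @param data Tibble with list-column `image` and column `stage`.
#' @param config A [train_config()].
#' @return The trained `stage_cnn`, with `history`: a tibble
#'   `(epoch, train_loss, train_accuracy, val_loss, val_accuracy)`.
#' @export
train_stage_cnn <- function(model, data, config = train_config()) {
  stopifnot(inherits(model, "stage_cnn"), inherits(config, "train_config"))
  if (!all(c("image", "stage") %in% names(data)))
    stop("data needs columns 'image' and 'stage'")
  stages <- as_stage(data$stage) # rejects labels outside C-H
  side <- model$spec$input_side
  if (config$validation_fraction > 0) {
    parts <- split_dataset(data, 1 - config$validation_fraction,
                           seed = config$seed)
    tr <- parts$train; va <- parts$test
  } else {
    tr <- data; va <- data[0, , drop = FALSE]
  }
  X <- .prepare_x(tr$image, side)
  y <- .stage_index0(tr$stage)
  Xv <- if (nrow(va)) .prepare_x(va$image, side) else matrix(0, side * side, 0)
  yv <- if (nrow(va)) .stage_index0(va$stage) else integer()
  fit <- .cpp_cnn_train(model$layers, model$weights, X, y, Xv, yv,
                        side, model$spec$channels,
                        list(optimizer = config$optimizer,
                             learning_rate = config$learning_rate,
                             beta1 = config$beta1, beta2 = config$beta2,
                             epochs = config$epochs,
                             batch_size = config$batch_size,
                             seed = config$seed))
  h <- fit$history
  model$weights <- fit$weights
  model$trained <- TRUE
  model$config <- config
  no_val <- nrow(va) == 0L
  model$history <- tibble(
    epoch = seq_len(nrow(h)), train_loss = h[, 1], train_accuracy = h[, 2],
    val_loss = if (no_val) NA_real_ else h[, 3],
    val_accuracy = if (no_val) NA_real_ else h[, 4]
  )
  model
}

#' Predict stages
#'
#' @param object A `stage_cnn`.
#' @param newdata A tibble with an `image` list-column, a list of
#'   matrices, or a single matrix.
#' @param type `"stage"` for hard labels (argmax, lowest index on ties) or
#'   `"prob"` for the n x 6 probability matrix (columns C-H).
#' @param ... Unused.
#' @return Factor of stages, or a probability matrix.
#' @export
predict.stage_cnn <- function(object, newdata, type = c("stage", "prob"),
                              ...) {
  type <- match.arg(type)
  images <- if (is.data.frame(newdata)) newdata$image
            else if (is.matrix(newdata)) list(newdata)
            else newdata
  X <- .prepare_x(images, object$spec$input_side)
  p <- t(.cpp_cnn_predict(object$layers, object$weights, X,
                          object$spec$input_side, object$spec$channels))
  colnames(p) <- object$classes
  if (type == "prob") return(p)
  factor(object$classes[max.col(p, ties.method = "first")],
         levels = object$classes)
}

#' Predict a single image's stage with its class probabilities
#'
#' @param model A trained `stage_cnn`.
#' @param image Grayscale matrix.
#' @return List with `stage` (factor) and `probabilities` (named numeric,
#'   summing to 1).
#' @export
predict_stage <- function(model, image) {
  p <- predict(model, image, type = "prob")[1, ]
  list(stage = factor(names(p)[which.max(p)], levels = model$classes),
       probabilities = p)
}

#' Flattened conv/pool feature vector
#'
#' Pushes images through the convolution/pooling stack only and returns
#' the flatten-layer activations (length 256 for the reference
#' architecture).
#'
#' @param model A `stage_cnn`.
#' @param images As in [predict.stage_cnn()].
#' @return Matrix, one row per image.
#' @export
model_features <- function(model, images) {
  images <- if (is.data.frame(images)) images$image
            else if (is.matrix(images)) list(images)
            else images
  X <- .prepare_x(images, model$spec$input_side)
  t(.cpp_cnn_features(model$layers, model$weights, X,
                      model$spec$input_side, model$spec$channels))
}
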
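test_that("parameter bookkeeping matches the built weight tensors", {
  withr::with_seed(31, {
    for (t in 1:5) {
      nconv <- sample(1:3, 1)
      spec <- architecture_spec(
        input_side = 36L, conv_filters = sample(c(8L, 16L, 32L), nconv, TRUE),
        conv_strides = rep(1L, nconv), pool_after = seq_len(nconv),
        dense_widths = sample(c(8L, 16L, 24L), sample(0:2, 1))
      )
      model <- build_model(spec, seed = t)
      actual <- sum(vapply(model$weights,
                           function(w) length(w$W) + length(w$b), 0))
      expect_equal(actual, attr(model$shapes, "total"), ignore_attr = TRUE)
    }
  })
})

test_that("closed-form conv and dense counts hold layer by layer", {
  sh <- layer_shapes(reference_architecture())
  conv64 <- sh$n_param[sh$type == "conv"]
  expect_equal(conv64[1], (9 * 1 + 1) * 64) # 640, single input channel
  expect_true(all(conv64[-1] == (9 * 64 + 1) * 64)) # 36,928 each
  dense <- sh$n_param[sh$type == "dense"]
  expect_equal(dense, c((256 + 1) * 30, (30 + 1) * 6)) # 7,710 and 186
})

test_that("specs that collapse the feature map are rejected with the layer named", {
  expect_error(
    architecture_spec(input_side = 8L, conv_filters = rep(8L, 4),
                      conv_strides = rep(1L, 4), pool_after = 1:4),
    "pool after conv stage 4"
  )
})

test_that("an empty dense list yields a single 6-way output layer", {
  spec <- architecture_spec(input_side = 30L, conv_filters = 8L,
                            conv_strides = 1L, pool_after = 1L,
                            dense_widths = integer())
  sh <- layer_shapes(spec)
  expect_equal(sum(sh$type == "dense"), 1L)
  expect_equal(sh$output_shape[nrow(sh)], "(6)")
  m <- build_model(spec)
  p <- predict(m, rand_image(30), type = "prob")
  expect_equal(sum(p), 1, tolerance = 1e-6)
})

test_that("stratified split has per-stage sizes within one of the fraction", {
  data <- generate_phantom_set(10, seed = 3) # 120 cases, 20 per stage
  parts <- split_dataset(data, 0.8, seed = 5)
  expect_equal(nrow(parts$train), 96L)
  expect_equal(nrow(parts$test), 24L)
  expect_equal(as.vector(table(parts$train$stage)), rep(16L, 6))
  expect_equal(as.vector(table(parts$test$stage)), rep(4L, 6))
  expect_length(intersect(parts$train$case_id, parts$test$case_id), 0)
  parts2 <- split_dataset(data, 0.8, seed = 5)
  expect_identical(parts$train$case_id, parts2$train$case_id)
})

test_that("softmax outputs normalize and zero logits give uniform probabilities", {
  model <- build_model(tiny_spec(), seed = 2)
  imgs <- list(rand_image(30, seed = 1), rand_image(30, seed = 2))
  p <- predict(model, imgs, type = "prob")
  expect_equal(rowSums(p), c(1, 1), tolerance = 1e-6)
  # zero the output layer -> exactly uniform, argmax tie-break picks C
  k <- length(model$weights)
  model$weights[[k]]$W[] <- 0
  model$weights[[k]]$b[] <- 0
  p0 <- predict(model, imgs, type = "prob")
  expect_equal(as.numeric(p0), rep(1 / 6, 12), tolerance = 1e-7)
  expect_equal(as.character(predict(model, imgs, type = "stage")),
               c("C", "C"))
})

test_that("a zero learning rate leaves weights and loss untouched", {
  data <- small_phantom_data(2, seed = 6)
  model <- build_model(tiny_spec(), seed = 3)
  # batch size divides the gradient-set size so every epoch's mean loss is
  # the full-set mean, independent of shuffling
  cfg <- train_config(optimizer = "sgd", learning_rate = 0, epochs = 3,
                      batch_size = 8, validation_fraction = 0, seed = 4)
  fit <- train_stage_cnn(model, data, cfg)
  expect_equal(fit$weights, model$weights, tolerance = 1e-7)
  expect_equal(fit$history$train_loss,
               rep(fit$history$train_loss[1], 3), tolerance = 1e-5)
})

test_that("training is reproducible and rejects labels outside C-H", {
  data <- small_phantom_data(2, seed = 7)
  cfg <- train_config(epochs = 2, seed = 9)
  f1 <- train_stage_cnn(build_model(tiny_spec(), 1), data, cfg)
  f2 <- train_stage_cnn(build_model(tiny_spec(), 1), data, cfg)
  expect_identical(f1$history, f2$history)
  bad <- data
  bad$stage <- as.character(bad$stage)
  bad$stage[1] <- "A"
  expect_error(train_stage_cnn(build_model(tiny_spec(), 1), bad, cfg), "A")
})

test_that("training on phantoms reduces loss and never yields NaN", {
  data <- expand_dataset(small_phantom_data(2, seed = 8),
                         augment_plan(factor = 4), seed = 1)
  cfg <- train_config(epochs = 5, batch_size = 8, seed = 2)
  fit <- train_stage_cnn(build_model(tiny_spec(), 5), data, cfg)
  h <- fit$history
  expect_false(any(!is.finite(c(h$train_loss, h$val_loss))))
  expect_lt(h$train_loss[5], h$train_loss[1])
  expect_gt(h$train_accuracy[5], h$train_accuracy[1])
})

test_that("prediction with dropout disabled at inference is deterministic", {
  data <- small_phantom_data(1, seed = 10)
  cfg <- train_config(epochs = 2, seed = 3)
  fit <- train_stage_cnn(build_model(tiny_spec(dropout = 0.5), 4), data, cfg)
  p1 <- predict(fit, data, type = "prob")
  p2 <- predict(fit, data, type = "prob")
  expect_identical(p1, p2)
})

test_that("predict_stage reports a label with normalized probabilities", {
  model <- build_model(tiny_spec(), seed = 6)
  out <- predict_stage(model, rand_image(30, seed = 4))
  expect_s3_class(out$stage, "factor")
  expect_named(out$probabilities, stage_levels())
  expect_equal(sum(out$probabilities), 1, tolerance = 1e-6)
})
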
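test_that("confusion cross-tabulates in fixed stage order", {
  t <- c("C", "C", "D", "E", "F", "G", "H", "H", "D", "E", "F", "C")
  p <- c("C", "D", "D", "E", "G", "G", "H", "G", "D", "F", "F", "C")
  m <- confusion(t, p)
  expect_equal(dim(unclass(m)), c(6L, 6L))
  expect_equal(sum(unclass(m)), 12L)
  # hand tally
  expect_equal(unclass(m)["C", "C"], 2L)
  expect_equal(unclass(m)["C", "D"], 1L)
  expect_equal(unclass(m)["F", "G"], 1L)
  expect_equal(unclass(m)["H", "G"], 1L)
  expect_equal(sum(diag(unclass(m))), 8L)

  perfect <- confusion(t, t)
  expect_true(all(unclass(perfect)[upper.tri(unclass(perfect))] == 0))
  expect_true(all(unclass(perfect)[lower.tri(unclass(perfect))] == 0))

  empty <- confusion(character(), character())
  expect_true(all(unclass(empty) == 0L))

  # permutation equivariance
  ord <- c(5, 3, 12, 1, 7, 9, 2, 11, 4, 10, 8, 6)
  expect_identical(unclass(confusion(t[ord], p[ord])), unclass(m))
})

test_that("row normalization leaves zero rows and unit row sums", {
  m <- matrix(0L, 6, 6, dimnames = list(stage_levels(), stage_levels()))
  diag(m) <- c(3L, 0L, 2L, 1L, 4L, 5L)
  nm <- row_normalize(m)
  expect_equal(diag(nm), c(1, 0, 1, 1, 1, 1), ignore_attr = TRUE)
  m2 <- m; m2["D", c("C", "D")] <- c(2L, 2L)
  expect_equal(row_normalize(m2)["D", c("C", "D")], c(C = 0.5, D = 0.5))
  withr::with_seed(2, {
    r <- matrix(rpois(36, 4), 6, 6)
    expect_equal(rowSums(row_normalize(r)), rep(1, 6), ignore_attr = TRUE)
  })
})

test_that("overall accuracy is trace over total", {
  m <- matrix(1L, 6, 6)
  diag(m) <- 0L
  expect_equal(overall_accuracy(m), 0)
  expect_equal(overall_accuracy(diag(3L, 6)), 1)
  # trace 77 of 100
  m <- diag(0L, 6)
  diag(m) <- c(13L, 13L, 13L, 13L, 13L, 12L)
  m[1, 2] <- 23L
  expect_equal(overall_accuracy(m), 0.77)
  expect_error(overall_accuracy(matrix(0L, 6, 6)), "empty")
})

test_that("Cohen's kappa follows its closed form and edge cases", {
  expect_equal(cohen_kappa(diag(5L, 6)), 1)
  # outer-product margins: chance-level agreement, kappa 0
  r <- c(10, 20, 5, 8, 12, 6)
  m <- outer(r, r)
  expect_equal(cohen_kappa(m), 0, tolerance = 1e-12)
  # hand-computed 2x2 example
  expect_equal(cohen_kappa(matrix(c(20, 10, 5, 15), 2, 2)), 0.4)
  # degenerate: all mass in one diagonal cell
  one <- matrix(0L, 6, 6); one[2, 2] <- 9L
  expect_equal(cohen_kappa(one), 1)
  expect_equal(cohen_kappa(matrix(c(5, 0, 0, 0), 2, 2)), 1)
  expect_error(cohen_kappa(matrix(0L, 6, 6)), "empty")
})

test_that("kappa agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  withr::with_seed(5, {
    for (t in 1:10) {
      m <- matrix(rpois(36, 5), 6, 6)
      expect_equal(cohen_kappa(m),
                   e1071::classAgreement(m)$kappa, tolerance = 1e-12)
      k <- cohen_kappa(m)
      expect_true(k >= -1 && k <= 1)
    }
  })
})

test_that("accuracy equals the count-weighted mean of per-stage recalls", {
  withr::with_seed(6, {
    m <- matrix(rpois(36, 3), 6, 6,
                dimnames = list(stage_levels(), stage_levels()))
    rec <- per_stage_recall(m)
    w <- rowSums(m) / sum(m)
    expect_equal(overall_accuracy(m), sum(w * rec))
  })
})

test_that("agreement_report bundles the battery consistently", {
  t <- rep(stage_levels(), each = 4)
  p <- t; p[c(2, 7, 12)] <- c("D", "C", "F")
  rep <- agreement_report(t, p)
  expect_equal(rep$n, 24L)
  expect_equal(rep$overall_accuracy, 21 / 24)
  expect_equal(rep$kappa, cohen_kappa(rep$counts))
  expect_equal(rowSums(rep$proportions), rep(1, 6), ignore_attr = TRUE)
  td <- tidy(rep)
  expect_equal(sum(td$n), 24L)
  gl <- glance(rep)
  expect_named(gl, c("n", "overall_accuracy", "kappa"))
})

test_that("learning-curve summary finds the overfitting onset", {
  h <- tibble::tibble(epoch = 1:4, val_loss = c(1.0, 0.8, 0.9, 1.1))
  s <- summarize_history(h)
  expect_equal(s$best_epoch, 2L)
  expect_equal(s$min_val_loss, 0.8)
  expect_equal(s$overfit_onset, 3L)

  mono <- tibble::tibble(epoch = 1:5, val_loss = c(2, 1.5, 1.2, 1.1, 1.0))
  expect_true(is.na(summarize_history(mono)$overfit_onset))
  expect_equal(summarize_history(mono)$best_epoch, 5L)
})
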
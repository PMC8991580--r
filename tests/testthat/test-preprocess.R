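test_that("crop_roi copies interior pixels and replicates the border", {
  img <- ramp_image(300)
  # identity case: box covering the whole image
  full <- crop_roi(img[1:250, 1:250], c(125.5, 125.5), 250)
  expect_identical(dim(full), c(250L, 250L))
  expect_equal(full, img[1:250, 1:250])

  # corner crop near (10, 10): hand-indexed oracle with clamped indices
  got <- crop_roi(img, c(10, 10), 20)
  rows <- pmin(pmax(0:19, 1), 300) # 10 - 10 .. 10 + 9
  cols <- pmin(pmax(0:19, 1), 300)
  expect_equal(got, img[rows, cols])
  # first row/col replicated from the edge
  expect_equal(got[1, ], got[2, ])
  expect_equal(got[, 1], got[, 2])
})

test_that("crop_roi rejects out-of-image centers naming the coordinate", {
  img <- rand_image(50)
  expect_error(crop_roi(img, c(60, 10), 20), "60")
  expect_error(crop_roi(img, c(10, -3), 20), "-3")
})

test_that("crop_roi with the same centered box is idempotent", {
  img <- rand_image(101)
  ctr <- c(51, 51)
  once <- crop_roi(img, ctr, 41)
  twice <- crop_roi(once, c(21, 21), 41)
  expect_identical(once, twice)
})

test_that("adjust_intensity maps the percentile span onto [0, 1]", {
  expect_equal(adjust_intensity(matrix(0.4, 5, 5)), matrix(0.4, 5, 5))

  img <- rand_image(10, seed = 2) * 0.4 + 0.2 # range inside (0.2, 0.6)
  out <- adjust_intensity(img, 0, 100)
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)

  # clipped rescale against the closed-form affine map
  img <- ramp_image(10)
  q <- quantile(img, c(0.1, 0.9), names = FALSE)
  expected <- pmin(pmax((img - q[1]) / (q[2] - q[1]), 0), 1)
  expect_equal(adjust_intensity(img, 10, 90), expected)
  expect_error(adjust_intensity(img, 50, 40))
})

test_that("median_filter matches a brute-force windowed-sort oracle", {
  img <- rand_image(9, seed = 3)
  got <- median_filter(img, 3)
  expected <- img
  for (r in 1:9) for (c in 1:9) {
    win <- img[pmin(pmax((r - 1):(r + 1), 1), 9),
               pmin(pmax((c - 1):(c + 1), 1), 9)]
    expected[r, c] <- sort(as.numeric(win))[5]
  }
  expect_equal(got, expected)
})

test_that("median_filter removes isolated impulses and keeps constants", {
  expect_equal(median_filter(matrix(0.7, 15, 15), 7), matrix(0.7, 15, 15))
  img <- matrix(0, 21, 21); img[11, 11] <- 1
  expect_equal(median_filter(img, 7), matrix(0, 21, 21))
  expect_error(median_filter(img, 4), "odd")
})

test_that("median_filter output values come from the input value set", {
  img <- withr::with_seed(9,
    matrix(sample(c(0, 0.25, 0.5, 1), 100, replace = TRUE), 10, 10))
  out <- median_filter(img, 5)
  expect_true(all(out %in% c(0, 0.25, 0.5, 1)))
})

test_that("CLAHE keeps constants constant and output within [0, 1]", {
  cst <- matrix(0.37, 32, 32)
  expect_equal(enhance_clahe(cst), cst)
  out <- enhance_clahe(rand_image(64, seed = 4), clip_limit = 0.02)
  expect_true(all(out >= 0 & out <= 1))
  expect_error(enhance_clahe(rand_image(4), tile_grid = c(8, 8)), "tile")
})

test_that("single-tile CLAHE with a large clip reduces to global equalization", {
  # two-level checkerboard: equalization maps the lower level to its cdf
  img <- matrix(rep(c(0.3, 0.6), length.out = 64 * 64), 64, 64)
  out <- enhance_clahe(img, clip_limit = 100, tile_grid = c(1, 1))
  # hand oracle: 50/50 two-level histogram -> cdf 0.5 and 1.0
  expect_equal(sort(unique(as.numeric(out))), c(0.5, 1.0), tolerance = 1e-8)
})

test_that("all preprocessing operations preserve the [0,1] intensity range", {
  for (s in 1:3) {
    img <- rand_image(40, seed = s)
    for (out in list(crop_roi(img, c(20, 20), 30),
                     adjust_intensity(img, 5, 95),
                     median_filter(img, 3),
                     enhance_clahe(img, tile_grid = c(2, 2)))) {
      expect_true(all(out >= 0 & out <= 1))
    }
  }
})
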
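test_that("polygon rasterization is pixel-center even-odd, boundary inclusive", {
  sq <- cbind(c(10, 10, 20, 20), c(10, 20, 20, 10))
  mask <- contour_to_mask(sq, c(30, 30))
  expect_equal(sum(mask), 121L) # 11 x 11 inclusive of the boundary
  expect_equal(which(mask == 1L, arr.ind = TRUE)[, 1] |> range(), c(10, 20))

  # orientation invariance
  tri <- cbind(c(5, 25, 15), c(5, 8, 25))
  expect_identical(contour_to_mask(tri, c(30, 30)),
                   contour_to_mask(tri[3:1, ], c(30, 30)))

  # 360-gon circle area within 2% of pi r^2
  th <- 2 * pi * (0:359) / 360
  circ <- cbind(40 + 30 * sin(th), 40 + 30 * cos(th))
  area <- sum(contour_to_mask(circ, c(80, 80)))
  expect_lt(abs(area - pi * 900) / (pi * 900), 0.02)

  # degenerate polygon rejected
  expect_error(contour_to_mask(cbind(c(1, 2, 3), c(1, 2, 3)), c(10, 10)),
               "degenerate")
})

test_that("apply_mask keeps the interior and zeroes the background", {
  img <- ramp_image(20)
  expect_equal(apply_mask(img, matrix(1L, 20, 20)), img)
  expect_equal(apply_mask(img, matrix(0L, 20, 20)), matrix(0, 20, 20))
  half <- matrix(0L, 20, 20); half[, 1:10] <- 1L
  expect_equal(apply_mask(img, half), img * half)
})

test_that("dice and jaccard follow their closed forms", {
  a <- matrix(0L, 20, 20); a[1:10, 1:10] <- 1L # 100 px
  expect_equal(dice(a, a), 1)
  expect_equal(jaccard(a, a), 1)
  b <- matrix(0L, 20, 20); b[6:15, 1:10] <- 1L # 100 px, 50 overlap
  expect_equal(dice(a, b), 0.5)
  expect_equal(jaccard(a, b), 1 / 3)
  disj <- matrix(0L, 20, 20); disj[15:20, 15:20] <- 1L
  expect_equal(dice(a, disj), 0)
  expect_equal(dice(matrix(0L, 5, 5), matrix(0L, 5, 5)), 1)
})

test_that("jaccard equals dice / (2 - dice) on random mask pairs", {
  withr::with_seed(8, {
    for (t in 1:50) {
      a <- matrix(rbinom(400, 1, runif(1)), 20, 20)
      b <- matrix(rbinom(400, 1, runif(1)), 20, 20)
      d <- dice(a, b)
      expect_equal(jaccard(a, b), d / (2 - d), tolerance = 1e-12)
    }
  })
})

test_that("segmentation grading separates under, well and over", {
  truth <- disk_mask(101, 30)
  expect_equal(grade_segmentation(truth, truth), "well")
  eroded <- disk_mask(101, 30 / sqrt(2)) # about half the area
  expect_equal(grade_segmentation(eroded, truth, tol = 0.2), "under")
  dilated <- disk_mask(101, 30 * sqrt(2)) # about double the area
  expect_equal(grade_segmentation(dilated, truth, tol = 0.2), "over")
  expect_error(grade_segmentation(truth, matrix(0L, 101, 101)), "empty")
})

test_that("parameter sweep emits one scored row per setting", {
  cases <- generate_phantom_set(1, seed = 21, clutter_level = 0,
                                impulse_noise_fraction = 0)[1:2, ]
  cases$truth <- cases$mask
  tab <- sweep_parameters(cases, radius_lengths = c(60, 90),
                          line_counts = c(180, 240))
  expect_equal(nrow(tab), 4L)
  expect_named(tab, c("radius_length", "n_lines", "time_s", "dice",
                      "jaccard", "grade"))
  expect_true(all(tab$dice >= tab$jaccard))

  # single case, single setting: row reproduces a direct dice() call
  one <- sweep_parameters(cases[1, ], radius_lengths = 90, line_counts = 240)
  seg <- segment_tooth(cases$image[[1]], n_lines = 240, radius_length = 90)
  expect_equal(one$dice, dice(seg$mask, cases$truth[[1]]))
  expect_error(sweep_parameters(cases[0, ], 90, 240), "nonempty")
})

test_that("a radius shorter than the object forces under-segmentation", {
  # disk-like phantoms of boundary radius 45, probed with radius 30 rays
  specs <- lapply(1:3, function(i)
    phantom_spec("C", crown_width = 90, crown_height = 90,
                 root_length_fraction = 0, apex_gap = 0, clutter_level = 0,
                 impulse_noise_fraction = 0, seed = i))
  cases <- tibble::tibble(
    image = lapply(specs, function(s) generate_phantom(s)$image),
    truth = lapply(specs, function(s) generate_phantom(s)$mask)
  )
  tab <- sweep_parameters(cases, radius_lengths = 30, line_counts = 240)
  expect_equal(tab$grade, "under")
})
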
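test_that("radial grid geometry follows the polar closed form", {
  # 4 axis-aligned lines, radius 2, spacing 1: center +/- {1, 2} on both axes
  g <- radial_grid(c(0, 0), 4, 2, 1)
  expect_equal(g$n_graduations, 2L)
  pts <- round(g$points, 10)
  expect_setequal(
    paste(pts[, 1], pts[, 2]),
    c("0 1", "0 2", "1 0", "2 0", "0 -1", "0 -2", "-1 0", "-2 0")
  )

  # point (i = 3, j = 9) of a 12-line, spacing-2 grid, closed form
  g12 <- radial_grid(c(5, 7), 12, 24, 2)
  ang <- 2 * pi * 2 / 12
  idx <- (3 - 1) * g12$n_graduations + 9
  expect_equal(unname(g12$points[idx, 1]), 5 + 18 * sin(ang))
  expect_equal(unname(g12$points[idx, 2]), 7 + 18 * cos(ang))

  # recommended setting
  grec <- radial_grid(c(125, 125), 1200, 100, 1)
  expect_equal(c(grec$n_lines, grec$n_graduations), c(1200L, 100L))

  expect_error(radial_grid(c(0, 0), 2, 10, 1), "n_lines")
  expect_error(radial_grid(c(0, 0), 8, 1, 1), "radius_length")
})

test_that("directional gradient is the analytic projection on ramps", {
  g <- radial_grid(c(13, 13), 16, 8, 1)
  expect_equal(directional_gradient(matrix(0.5, 25, 25), g),
               matrix(0, 16, 8))
  # I(r, c) = c scaled: outward derivative = cos(angle) / (nc - 1)
  img <- ramp_image(25)
  got <- directional_gradient(img, g, bright_object = FALSE)
  expected <- matrix(cos(g$angles) / 24, 16, 8)
  # graduations away from the frame edge follow the closed form
  expect_equal(got[, 1:6], expected[, 1:6], tolerance = 1e-9)
})

test_that("gradient magnitude peaks at the disk boundary", {
  img <- disk_image(101, 30, low = 0.2, high = 0.9)
  g <- radial_grid(c(51, 51), 36, 45, 1)
  gd <- directional_gradient(img, g, bright_object = FALSE)
  peaks <- apply(abs(gd), 1, which.max)
  expect_true(all(abs(peaks - 30) <= 1))
})

test_that("stage cost is -g within delta and the sentinel beyond", {
  expect_equal(stage_cost(2.5, c(0, 0), c(0, 3), delta = 3), -2.5)
  expect_equal(stage_cost(2.5, c(0, 0), c(0, 3.01), delta = 3,
                          infeasible_cost = 99), 99)
  expect_equal(stage_cost(0, c(0, 0), c(1, 1), delta = 3), 0)
})

test_that("exact DP attains the brute-force minimum on random instances", {
  withr::with_seed(42, {
    for (t in 1:20) {
      M <- sample(3:5, 1); N <- sample(2:4, 1)
      spacing <- runif(1, 0.5, 2)
      g <- matrix(rnorm(M * N), M, N)
      grid <- radial_grid(c(0, 0), M, N * spacing, spacing)
      delta <- runif(1, 0.5, 4)
      sol <- solve_closed_contour(g, grid,
                                  dp_config(delta = delta, closure = "exact"))
      bf <- brute_force_contour(g, grid$radii, 2 * pi / M, delta)
      expect_equal(sol$energy, bf$energy, tolerance = 1e-9)
    }
  })
})

test_that("a unique feasible tuple is returned with energy -sum(g)", {
  # 4 lines 90 degrees apart, radii {1.45, 2.9}; delta = 2.1 admits only
  # transitions between first graduations (d = 1.45 * sqrt(2) ~ 2.05)
  grid <- radial_grid(c(0, 0), 4, 2.9, 1.45)
  g <- cbind(c(1, 2, 3, 4), c(10, 10, 10, 10)) # outer ring tempting but cut off
  sol <- solve_closed_contour(g, grid, dp_config(delta = 2.1,
                                                 closure = "exact"))
  expect_true(sol$feasible)
  expect_equal(sol$selection, rep(1L, 4))
  expect_equal(sol$energy, -10)
})

test_that("feasible contours respect the wrap-inclusive distance bound", {
  withr::with_seed(7, {
    img <- disk_image(81, 25, low = 0.9, high = 0.2) # bright disk
    grid <- radial_grid(c(41, 41), 90, 38, 1)
    gd <- directional_gradient(img, grid)
    sol <- solve_closed_contour(gd, grid, dp_config(delta = 3))
    expect_true(sol$feasible)
    p <- sol$points
    dists <- sqrt(rowSums((p - p[c(2:nrow(p), 1), ])^2))
    expect_true(all(dists <= 3 + 1e-9))
    # energy equals the recomputed sum of stage costs
    gsel <- gd[cbind(seq_len(grid$n_lines), sol$selection)]
    expect_equal(sol$energy, -sum(gsel), tolerance = 1e-6)
  })
})

test_that("DP recovers a known disk boundary within one graduation", {
  img <- disk_image(101, 30, low = 0.9, high = 0.2) # bright disk on dark
  grid <- radial_grid(c(51, 51), 360, 45, 1)
  gd <- directional_gradient(img, grid)
  sol <- solve_closed_contour(gd, grid, dp_config(delta = 3))
  expect_true(sol$feasible)
  expect_true(all(abs(sol$selection - 30) <= 1))
})

test_that("enlarging delta never increases the optimal energy", {
  withr::with_seed(11, {
    for (t in 1:5) {
      M <- 8; N <- 6
      g <- matrix(rnorm(M * N), M, N)
      grid <- radial_grid(c(0, 0), M, N, 1)
      energies <- sapply(c(1, 2, 4, 8), function(d)
        solve_closed_contour(g, grid,
                             dp_config(delta = d, closure = "exact"))$energy)
      expect_true(all(diff(energies) <= 1e-9))
    }
  })
})

test_that("intensity scaling scales the energy without moving the contour", {
  img <- disk_image(81, 22, low = 0.85, high = 0.15)
  grid <- radial_grid(c(41, 41), 72, 35, 1)
  s1 <- solve_closed_contour(directional_gradient(img, grid), grid,
                             dp_config(delta = 3))
  s2 <- solve_closed_contour(directional_gradient(img * 0.4, grid), grid,
                             dp_config(delta = 3))
  expect_identical(s1$selection, s2$selection)
  expect_equal(s2$energy, 0.4 * s1$energy, tolerance = 1e-6)
})

test_that("two-pass closure is used for very fine grids and stays close", {
  img <- disk_image(101, 30, low = 0.9, high = 0.2)
  grid <- radial_grid(c(51, 51), 120, 45, 0.5) # N = 90 graduations
  gd <- directional_gradient(img, grid)
  exact <- solve_closed_contour(gd, grid, dp_config(closure = "exact"))
  twop <- solve_closed_contour(gd, grid, dp_config(closure = "two_pass"))
  expect_gte(twop$energy, exact$energy - 1e-9)
  # auto switches to two-pass past 256 graduations
  grid_fine <- radial_grid(c(51, 51), 90, 45, 0.125) # N = 360
  sol <- solve_closed_contour(directional_gradient(img, grid_fine),
                              grid_fine, dp_config())
  expect_equal(sol$closure, "two_pass")
})

test_that("infeasible instances are flagged and report the least-bad tuple", {
  g <- matrix(1, 6, 4)
  grid <- radial_grid(c(0, 0), 6, 4, 1)
  sol <- solve_closed_contour(g, grid, dp_config(delta = 1e-6,
                                                 closure = "exact"))
  expect_false(sol$feasible)
  expect_length(sol$selection, 6)
})
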
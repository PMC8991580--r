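# Small programmatic fixtures shared across tests.

# deterministic pseudo-random image in [0, 1]
rand_image <- function(nr, nc = nr, seed = 1) {
  withr::with_seed(seed, matrix(runif(nr * nc), nr, nc))
}

# linear column ramp I(r, c) = (c - 1) / (nc - 1)
ramp_image <- function(nr, nc = nr) {
  matrix(rep((seq_len(nc) - 1) / (nc - 1), each = nr), nr, nc)
}

# centered dark disk on bright ground
disk_image <- function(side, radius, low = 0.2, high = 0.9) {
  ctr <- (side + 1) / 2
  d <- sqrt(outer((seq_len(side) - ctr)^2, (seq_len(side) - ctr)^2, "+"))
  ifelse(d <= radius, low, high)
}

# centered disk mask
disk_mask <- function(side, radius) {
  ctr <- (side + 1) / 2
  d <- sqrt(outer((seq_len(side) - ctr)^2, (seq_len(side) - ctr)^2, "+"))
  matrix(as.integer(d <= radius), side, side)
}

# independent brute-force minimizer of the cyclic contour energy
brute_force_contour <- function(g, radii, dtheta, delta) {
  M <- nrow(g); N <- ncol(g)
  maxg <- max(abs(g))
  sentinel <- 2 * (M + 1) * (maxg + 1)
  dfun <- function(j, k)
    sqrt(radii[j]^2 + radii[k]^2 - 2 * radii[j] * radii[k] * cos(dtheta))
  combs <- as.matrix(expand.grid(rep(list(seq_len(N)), M)))
  best <- Inf; bsel <- NULL
  for (row in seq_len(nrow(combs))) {
    v <- combs[row, ]
    e <- 0
    for (i in seq_len(M)) {
      nxt <- v[if (i == M) 1L else i + 1L]
      e <- e + if (dfun(v[i], nxt) <= delta) -g[i, v[i]] else sentinel
    }
    if (e < best) { best <- e; bsel <- v }
  }
  list(energy = best, selection = bsel)
}

# a tiny labeled phantom tibble for classifier tests
small_phantom_data <- function(n = 2, seed = 5, ...) {
  generate_phantom_set(n, seed = seed, ...)
}

# fast low-capacity architecture for classifier mechanics tests
tiny_spec <- function(input_side = 30L, dropout = NULL) {
  architecture_spec(input_side = input_side, conv_filters = c(8L, 8L),
                    conv_strides = c(1L, 1L), pool_after = c(1L, 2L),
                    dense_widths = 16L, dropout = dropout)
}
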
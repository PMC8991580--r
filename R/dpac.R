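#' Radial candidate grid
#'
#' Builds the polar lattice the active contour is optimized over: `n_lines`
#' rays leave the seed point at uniformly spaced angles (angle 0 along
#' +col, increasing towards +row), each carrying
#' `n_graduations = floor(radius_length / spacing)` candidate boundary
#' positions at radii `spacing, 2*spacing, ...`. Each ray is assumed to
#' cross the object boundary exactly once (star-convex objects).
#'
#' @param center `(row, col)` seed point, in pixels.
#' @param n_lines Number of radial lines M (>= 3).
#' @param radius_length Ray length in pixels (>= 2 * spacing).
#' @param spacing Pixels per graduation (default 1, so N = radius_length).
#' @return A `radial_grid` object (list with `center`, `n_lines`, `angles`,
#'   `radii`, `units`, `points`).
#' @export
radial_grid <- function(center, n_lines, radius_length, spacing = 1) {
  n_lines <- as.integer(n_lines)
  if (n_lines < 3L) stop("n_lines must be >= 3")
  if (radius_length < 2 * spacing) stop("radius_length must be >= 2 * spacing")
  n_grad <- as.integer(floor(radius_length / spacing))
  angles <- 2 * pi * (seq_len(n_lines) - 1L) / n_lines
  units <- cbind(row = sin(angles), col = cos(angles))
  radii <- spacing * seq_len(n_grad)
  # line-major point list: graduation index varies fastest
  pts <- cbind(
    row = center[1] + rep(units[, 1], each = n_grad) * rep(radii, n_lines),
    col = center[2] + rep(units[, 2], each = n_grad) * rep(radii, n_lines)
  )
  structure(
    list(center = as.numeric(center), n_lines = n_lines,
         radius_length = radius_length, spacing = spacing,
         n_graduations = n_grad, angles = angles, units = units,
         radii = radii, points = pts),
    class = "radial_grid"
  )
}

#' @export
print.radial_grid <- function(x, ...) {
  cat(sprintf("<radial_grid> %d lines x %d graduations, spacing %g px, center (%g, %g)\n",
              x$n_lines, x$n_graduations, x$spacing, x$center[1], x$center[2]))
  invisible(x)
}

#' Dynamic-programming configuration
#'
#' @param delta Maximum Euclidean distance allowed between consecutive
#'   contour points, wrap pair included. Default `3 * spacing` (permits
#'   one-graduation jumps between neighboring lines at typical geometries).
#' @param closure `"auto"` (exact when `n_graduations <= 256`, two-pass
#'   otherwise), `"exact"` (open-chain DP repeated per candidate first
#'   point; globally optimal) or `"two_pass"` (fix the open-chain optimum's
#'   first point, re-solve that cycle; a documented approximation).
#' @param bright_object The boundary of a bright object on darker surround
#'   has a negative outward derivative; when `TRUE` (default) the gradient
#'   field is negated so that boundary attracts the contour.
#' @return A `dp_config` list.
#' @export
dp_config <- function(delta = NULL, closure = c("auto", "exact", "two_pass"),
                      bright_object = TRUE) {
  closure <- match.arg(closure)
  if (!is.null(delta) && delta <= 0) stop("delta must be positive")
  structure(list(delta = delta, closure = closure,
                 bright_object = bright_object),
            class = "dp_config")
}

#' Outward directional gradient over a radial grid
#'
#' Samples the image gradient (central differences on the bilinearly
#' interpolated image, edge-replicated outside the frame) at every grid
#' point and projects it on the ray's outward unit vector. With
#' `bright_object = TRUE` the sign is flipped so the falling edge of a
#' bright object yields positive values.
#'
#' @param image Grayscale matrix in `[0, 1]`.
#' @param grid A [radial_grid()].
#' @param bright_object See [dp_config()].
#' @return An `n_lines` x `n_graduations` matrix of gradient values.
#' @export
directional_gradient <- function(image, grid, bright_object = TRUE) {
  image <- as_gray_image(image)
  stopifnot(inherits(grid, "radial_grid"))
  g <- .cpp_directional_gradient(image, grid$points, grid$units,
                                 grid$n_lines, grid$n_graduations)
  if (bright_object) -g else g
}

#' Single stage cost of the contour energy
#'
#' The additive term for consecutive picks: minus the directional gradient
#' at the current point when the two points are within `delta`, else a
#' large finite sentinel standing for infinity.
#'
#' @param g_value Directional gradient at the current point.
#' @param point_i,point_next `(row, col)` coordinates of consecutive picks.
#' @param delta Distance bound.
#' @param infeasible_cost Sentinel returned when the bound is violated.
#' @return The stage cost.
#' @export
stage_cost <- function(g_value, point_i, point_next, delta,
                       infeasible_cost = 1e9) {
  d <- sqrt(sum((point_i - point_next)^2))
  if (d <= delta) -g_value else infeasible_cost
}

#' Globally optimal closed contour by dynamic programming
#'
#' Minimizes the cyclic energy `sum_i E_i(v_i, v_{i+1})` (wrap pair
#' included) where each `E_i` is [stage_cost()]: the contour of greatest
#' directional gradient strength whose consecutive points all lie within
#' `delta`. Exact closure repeats the open-chain DP once per candidate
#' first point; the two-pass variant is an approximation for very fine
#' grids. Ties are broken deterministically towards smaller candidate
#' indices.
#'
#' @param g Gradient matrix from [directional_gradient()] (`n_lines` x
#'   `n_graduations`).
#' @param grid The [radial_grid()] the field was sampled on.
#' @param config A [dp_config()].
#' @return A `dp_contour` object: list with `selection` (graduation index
#'   per line), `points` (M x 2 contour coordinates), `energy`, `feasible`
#'   (`FALSE` when every cycle violates the distance bound; the least-bad
#'   selection is still reported), `delta` and `sentinel`.
#' @export
solve_closed_contour <- function(g, grid, config = dp_config()) {
  stopifnot(inherits(grid, "radial_grid"))
  if (!all(dim(g) == c(grid$n_lines, grid$n_graduations)))
    stop("gradient field shape does not match the grid")
  delta <- config$delta %||% (3 * grid$spacing)
  closure <- config$closure
  if (closure == "auto")
    closure <- if (grid$n_graduations <= 256L) "exact" else "two_pass"
  sol <- .cpp_dp_contour(g, grid$radii, 2 * pi / grid$n_lines, delta,
                         if (closure == "exact") 0L else 1L)
  sel <- sol$selection
  idx <- (seq_len(grid$n_lines) - 1L) * grid$n_graduations + sel
  structure(
    list(selection = sel, points = grid$points[idx, , drop = FALSE],
         energy = sol$energy, feasible = sol$feasible, delta = delta,
         closure = closure, sentinel = sol$sentinel, grid = grid),
    class = "dp_contour"
  )
}

#' @export
print.dp_contour <- function(x, ...) {
  cat(sprintf("<dp_contour> %d points, energy %.4f, %s (delta = %g, %s closure)\n",
              length(x$selection), x$energy,
              if (x$feasible) "feasible" else "INFEASIBLE",
              x$delta, x$closure))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rasterize a closed contour to a binary region mask
#'
#' Pixels whose centers lie inside or on the closed polygon become 1
#' (even-odd rule, boundary-inclusive).
#'
#' @param contour A `dp_contour` or an `n x 2` matrix of `(row, col)`
#'   vertices in order.
#' @param shape `(nrow, ncol)` of the output mask.
#' @return An integer 0/1 matrix.
#' @export
contour_to_mask <- function(contour, shape) {
  verts <- if (inherits(contour, "dp_contour")) contour$points else contour
  if (!is.matrix(verts) || ncol(verts) != 2 || nrow(verts) < 3)
    stop("contour must provide at least 3 (row, col) vertices")
  # degenerate (zero-area) polygons are rejected
  r <- verts[, 1]; c <- verts[, 2]
  area2 <- abs(sum(r * c[c(2:nrow(verts), 1)] - c * r[c(2:nrow(verts), 1)]))
  if (area2 < .Machine$double.eps^0.5) stop("degenerate polygon with zero area")
  .cpp_polygon_mask(verts, as.integer(shape[1]), as.integer(shape[2]))
}

#' Superimpose a mask on an image
#'
#' Keeps the original intensity inside the mask and zeroes the background,
#' isolating the region of interest.
#'
#' @param image Grayscale matrix.
#' @param mask 0/1 matrix of the same shape.
#' @return Masked image.
#' @export
apply_mask <- function(image, mask) {
  image <- as_gray_image(image)
  mask <- as_binary_mask(mask)
  if (!all(dim(image) == dim(mask))) stop("image and mask shapes differ")
  image * mask
}
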
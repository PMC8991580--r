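#' Stage geometry table for tooth phantoms
#'
#' Maps each Demirjian stage C-H to the geometry of the synthetic tooth:
#' the root length as a fraction of crown height (non-decreasing with
#' maturity: the root grows C through H) and the apex gap in pixels (the
#' open-apex notch shrinks with maturity and closes exactly at H).
#'
#' @return Tibble with `stage`, `root_length_fraction`, `apex_gap`.
#' @export
phantom_stage_geometry <- function() {
  tibble(
    stage = stage_levels(),
    root_length_fraction = c(0.10, 0.30, 0.55, 0.80, 1.00, 1.10),
    apex_gap = c(12, 10, 8, 6, 4, 0)
  )
}

#' Specify a star-convex tooth phantom
#'
#' A phantom is a bright star-convex tooth silhouette (elliptical crown
#' plus a stage-dependent root prong with an open-apex notch) over a
#' textured background with impulse noise, together with its ground-truth
#' mask. The silhouette is radially parameterized about the image center,
#' so every ray from the center crosses the boundary exactly once — the
#' shape family the radial active contour represents exactly.
#'
#' @param stage Demirjian stage `"C"`..`"H"`.
#' @param image_side Image side in pixels (default 250, the crop size).
#' @param crown_width,crown_height Crown ellipse axes in pixels.
#' @param root_length_fraction Root length as a fraction of crown height;
#'   default from [phantom_stage_geometry()].
#' @param apex_gap Open-apex notch depth in pixels; default from
#'   [phantom_stage_geometry()] (0 at stage H).
#' @param contrast Tooth-minus-background intensity gap (default 0.45).
#' @param clutter_level Amplitude of the smooth background texture
#'   (default 0.08); 0 disables it.
#' @param impulse_noise_fraction Fraction of pixels hit by salt-and-pepper
#'   impulses (default 0.02); 0 disables them.
#' @param scale Global geometric scale factor (cohort effect).
#' @param seed Integer seed; every random draw is derived from it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(stage, image_side = 250L, crown_width = 64,
                         crown_height = 48, root_length_fraction = NULL,
                         apex_gap = NULL, contrast = 0.45,
                         clutter_level = 0.08,
                         impulse_noise_fraction = 0.02, scale = 1,
                         seed = 1L) {
  stage <- as.character(as_stage(stage))
  geom <- phantom_stage_geometry()
  row <- geom[geom$stage == stage, ]
  spec <- structure(
    list(stage = stage, image_side = as.integer(image_side),
         crown_width = crown_width, crown_height = crown_height,
         root_length_fraction = root_length_fraction %||% row$root_length_fraction,
         apex_gap = apex_gap %||% row$apex_gap, contrast = contrast,
         clutter_level = clutter_level,
         impulse_noise_fraction = impulse_noise_fraction, scale = scale,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
  if (spec$root_length_fraction < 0 || spec$apex_gap < 0 || spec$scale <= 0)
    stop("invalid phantom geometry")
  spec
}

# Boundary radius r(theta) of the tooth silhouette about the image center.
# theta = 0 points along +col; +row (theta = pi/2) is "down", towards the
# root. Crown: ellipse. Root: a Gaussian angular bump of the stated length
# about straight-down, minus a narrow apex notch while the apex is open.
phantom_radius <- function(theta, spec) {
  a <- spec$crown_width / 2 * spec$scale
  b <- spec$crown_height / 2 * spec$scale
  r <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  phi <- theta - pi / 2                       # angle from straight down
  phi <- atan2(sin(phi), cos(phi))            # wrap to (-pi, pi]
  root_len <- spec$root_length_fraction * 2 * b
  bump <- root_len * exp(-(phi / 0.55)^2)
  gap <- spec$apex_gap * spec$scale
  # the open-apex notch carves the root, never the crown: the boundary
  # stays at or above the crown ellipse
  if (gap > 0) bump <- pmax(bump - gap * exp(-(phi / 0.12)^2), 0)
  pmax(r + bump, 2)
}

#' Generate one tooth phantom
#'
#' @param spec A [phantom_spec()].
#' @param n_vertices Number of polygon vertices used to trace the
#'   silhouette (default 720).
#' @return A `phantom_case` list: `image`, `mask` (rasterized generating
#'   polygon), `stage`, `spec`.
#' @export
generate_phantom <- function(spec, n_vertices = 720L) {
  stopifnot(inherits(spec, "phantom_spec"))
  side <- spec$image_side
  ctr <- (side + 1) / 2
  theta <- 2 * pi * (seq_len(n_vertices) - 1L) / n_vertices
  r <- phantom_radius(theta, spec)
  if (any(r >= side / 2))
    stop("phantom geometry exceeds the image bounds; reduce scale or root length")
  verts <- cbind(row = ctr + r * sin(theta), col = ctr + r * cos(theta))
  mask <- .cpp_polygon_mask(verts, side, side)

  withr::with_seed(spec$seed, {
    bg <- 0.25
    img <- matrix(bg, side, side)
    if (spec$clutter_level > 0) {
      # smooth low-frequency clutter: a few random 2-D cosine waves
      rr <- matrix(seq_len(side), side, side)
      cc <- t(rr)
      for (k in 1:4) {
        fr <- runif(2, -0.5, 0.5) * 2 * pi / 40
        ph <- runif(1, 0, 2 * pi)
        img <- img + spec$clutter_level / 2 * cos(fr[1] * rr + fr[2] * cc + ph)
      }
    }
    img[mask == 1L] <- bg + spec$contrast
    if (spec$clutter_level > 0) {
      # faint interior shading so the tooth is not perfectly flat
      img[mask == 1L] <- img[mask == 1L] +
        spec$clutter_level / 4 * sin(2 * pi * which(mask == 1L) / side^2)
    }
    if (spec$impulse_noise_fraction > 0) {
      n_imp <- round(spec$impulse_noise_fraction * side^2)
      at <- sample.int(side^2, n_imp)
      img[at] <- rep_len(c(0, 1), n_imp)
    }
  })
  structure(
    list(image = clamp01(img), mask = mask, stage = spec$stage, spec = spec),
    class = "phantom_case"
  )
}

#' Generate a phantom dataset
#'
#' Produces `n_per_stage_per_cohort` phantoms for each stage C-H in each of
#' two geometry-scale cohorts (emulating the two-sex design: cohort A at
#' scale 0.90, cohort B at 1.00). All geometric fields carry seeded jitter
#' so cases within a stage vary. `n_per_stage_per_cohort = 20` reproduces
#' the reference design of 240 cases.
#'
#' @param n_per_stage_per_cohort Cases per (stage, cohort) cell.
#' @param seed Integer seed.
#' @param jitter Relative s.d. of the geometric jitter (default 0.03).
#' @param ... Passed to [phantom_spec()] (e.g. `clutter_level = 0` for
#'   noise-free phantoms).
#' @return Tibble with `case_id`, `stage` (factor C-H), `cohort`, `seed`
#'   and list-columns `image`, `mask`.
#' @export
generate_phantom_set <- function(n_per_stage_per_cohort = 20L, seed = 1L,
                                 jitter = 0.03, ...) {
  cohorts <- c(A = 0.90, B = 1.00)
  grid <- expand.grid(rep = seq_len(n_per_stage_per_cohort),
                      cohort = names(cohorts), stage = stage_levels(),
                      stringsAsFactors = FALSE)
  cases <- purrr::pmap(grid, function(rep, cohort, stage) {
    stage_i <- match(stage, stage_levels())
    cohort_i <- match(cohort, names(cohorts))
    case_seed <- as.integer((seed + 7919 * stage_i + 104729 * cohort_i +
                               15485863 * rep) %% 2147483647)
    jit <- withr::with_seed(case_seed, rnorm(4, 1, jitter))
    jit <- pmin(pmax(jit, 1 - 3 * jitter), 1 + 3 * jitter)
    geom <- phantom_stage_geometry()
    row <- geom[geom$stage == stage, ]
    spec <- phantom_spec(
      stage = stage,
      crown_width = 64 * jit[1], crown_height = 48 * jit[2],
      root_length_fraction = row$root_length_fraction * jit[3],
      apex_gap = if (stage == "H") 0 else row$apex_gap * jit[4],
      scale = cohorts[[cohort]],
      seed = case_seed, ...
    )
    generate_phantom(spec)
  })
  tibble(
    case_id = sprintf("%s_%s_%03d", grid$stage, grid$cohort, grid$rep),
    stage = as_stage(grid$stage), cohort = grid$cohort,
    image = purrr::map(cases, "image"), mask = purrr::map(cases, "mask")
  )
}
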
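# Synthetic phantom embryos: geometries, stained images, view pairs and
# volumes with analytically known ground truth. Phantoms emulate what the
# real inputs provide -- a two-layer cross-section with a painted expression
# function, background shading, annotation artefacts -- so every measurement
# operation can be validated against a known answer.

#' Parametric phantom embryo geometry
#'
#' Builds an idealized two-ring geometry: a blastula is a pair of concentric
#' circles; a gastrula adds a Gaussian-profile inward dimple of depth
#' `invagination_depth` at the oral pole (angle 0, to the right of `center`),
#' with the endoderm-ectoderm boundary markers placed at the dimple rim. The
#' aboral anchor sits opposite the dimple, so decomposition starts at the
#' aboral pole as in real embryos.
#'
#' @param stage `"blastula"`, `"early_gastrula"` or `"late_gastrula"`; sets
#'   the default `invagination_depth` (0, 0.25, 0.5 times `outer_radius`).
#' @param outer_radius outer cell-layer radius, pixels. Default 100.
#' @param thickness cell-layer thickness, pixels; must stay below the
#'   smallest outer radius. Default 20.
#' @param invagination_depth dimple depth, pixels; 0 reproduces the blastula.
#' @param n_nodes nodes per ring. Default 16.
#' @param center embryo center `(x, y)` in pixels. Default `c(200, 200)`.
#' @param dimple_width angular half-width (radians) of the dimple. Default 0.6.
#' @return An [embryo_geometry()]; markers are present only when
#'   `invagination_depth > 0`. The parametric model is attached as attribute
#'   `"phantom_params"` for the renderer.
#' @export
make_phantom_geometry <- function(stage = c("blastula", "early_gastrula", "late_gastrula"),
                                  outer_radius = 100, thickness = 20,
                                  invagination_depth = NULL, n_nodes = 16L,
                                  center = c(200, 200), dimple_width = 0.6) {
  stage <- match.arg(stage)
  if (is.null(invagination_depth)) {
    invagination_depth <- switch(stage, blastula = 0,
                                 early_gastrula = 0.25 * outer_radius,
                                 late_gastrula = 0.5 * outer_radius)
  }
  if (stage == "blastula" && invagination_depth != 0) {
    lq_abort("lq_invalid_parameters", "a blastula has no invagination")
  }
  if (thickness <= 0 || thickness >= outer_radius - invagination_depth) {
    lq_abort("lq_invalid_parameters",
             "thickness must be positive and leave a positive inner radius everywhere")
  }
  if (invagination_depth < 0 || invagination_depth >= outer_radius) {
    lq_abort("lq_invalid_parameters", "invagination_depth must lie in [0, outer_radius)")
  }
  r_out <- function(theta) {
    outer_radius - invagination_depth * exp(-(ang_diff(theta, 0) / dimple_width)^2)
  }
  r_in <- function(theta) r_out(theta) - thickness

  # nodes start at the aboral pole (angle pi) and run with increasing angle
  th <- pi + 2 * pi * (seq_len(n_nodes) - 1L) / n_nodes
  outer_nodes <- cbind(center[1] + r_out(th) * cos(th),
                       center[2] + r_out(th) * sin(th))
  inner_nodes <- cbind(center[1] + r_in(th) * cos(th),
                       center[2] + r_in(th) * sin(th))

  markers <- NULL
  if (invagination_depth > 0) {
    # rim angles of the dimple, converted to arc fractions along the
    # mid-curve (numerically, so the dimple's arc-length distortion counts)
    rim <- c(-dimple_width, dimple_width)
    markers <- sort(vapply(rim, function(a) angle_to_arc_fraction(a, r_out, r_in),
                           numeric(1)))
  }
  geom <- embryo_geometry(outer_nodes, inner_nodes, boundary_markers = markers,
                          aboral_anchor = 0, stage_hpf = stage)
  attr(geom, "phantom_params") <- list(center = center, r_out = r_out,
                                       r_in = r_in, outer_radius = outer_radius,
                                       thickness = thickness,
                                       invagination_depth = invagination_depth,
                                       dimple_width = dimple_width)
  geom
}

ang_diff <- function(a, b) {
  d <- (a - b + pi) %% (2 * pi) - pi
  d
}

# Arc fraction (from the aboral pole, increasing angle) of a given polar
# angle on the phantom mid-curve, by dense numeric integration.
angle_to_arc_fraction <- function(angle, r_out, r_in, n = 8192L) {
  th <- pi + 2 * pi * (seq_len(n) - 1L) / n
  rm <- (r_out(th) + r_in(th)) / 2
  x <- rm * cos(th); y <- rm * sin(th)
  d <- sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2)
  cum <- c(0, cumsum(d))
  L <- cum[n + 1L]
  frac_angle <- ((angle - pi) %% (2 * pi)) / (2 * pi)
  idx <- frac_angle * n
  i0 <- floor(idx)
  w <- idx - i0
  ((1 - w) * cum[i0 + 1L] + w * cum[min(i0 + 2L, n + 1L)]) / L
}

#' Render a stained phantom embryo image
#'
#' Paints a known expression function onto a phantom geometry the way an in
#' situ hybridization looks under the microscope: a light background
#' (optionally with a linear lighting gradient), the cell-layer ribbon
#' darkened proportionally to `expression_fn` evaluated at the nearest
#' mid-curve arc position, dark annotation glyph boxes, and Gaussian pixel
#' noise under a fixed seed.
#'
#' @param geometry an [embryo_geometry()] fitting the canvas.
#' @param expression_fn function mapping arc-length fraction (from the
#'   aboral anchor, in `[0, 1)`) to expression in `[0, 1]`.
#' @param width,height canvas size in pixels.
#' @param background_level background intensity in `[0, 1]`. Default 0.95.
#' @param lighting_gradient intensity difference across the image width
#'   (left-to-right linear shading). Default 0.
#' @param stain_strength intensity drop at full expression. Default 0.7.
#' @param annotations list of glyphs, each
#'   `list(shape = "rect"|"disc", x=, y=, w=, h=)` or
#'   `list(shape = "disc", x=, y=, r=)`, with optional `level` (default 0.2).
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param seed RNG seed for the noise.
#' @param n_curve_points curve sampling used for ribbon membership and
#'   nearest-arc lookup.
#' @return List with `image` (an [rgb_image()], all channels equal) and
#'   `truth` (a `phantom_truth`: geometry, the painted profile sampled at
#'   1000 arc fractions, and all parameters).
#' @export
render_profile_image <- function(geometry, expression_fn, width = 400L,
                                 height = 400L, background_level = 0.95,
                                 lighting_gradient = 0, stain_strength = 0.7,
                                 annotations = list(), noise_sd = 0, seed = 1L,
                                 n_curve_points = 4000L) {
  width <- as.integer(width); height <- as.integer(height)
  # the whole render runs under the caller's seed (noise draws and any
  # internal tie-breaking), then the session RNG state is restored
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  outer <- build_spline_curve(geometry$outer_nodes, n_points = n_curve_points,
                              closed = TRUE)
  inner <- build_spline_curve(geometry$inner_nodes, n_points = n_curve_points,
                              closed = TRUE)
  if (min(outer$points[, 1]) < 0 || max(outer$points[, 1]) > width ||
      min(outer$points[, 2]) < 0 || max(outer$points[, 2]) > height) {
    lq_abort("lq_argument_error", "geometry does not fit the canvas")
  }
  mid_nodes <- (geometry$outer_nodes + geometry$inner_nodes) / 2
  mid <- build_spline_curve(mid_nodes, n_points = n_curve_points, closed = TRUE)
  anchor_arc <- geometry$aboral_anchor * mid$total_length

  px <- rep(seq_len(width) - 0.5, times = height)
  py <- rep(seq_len(height) - 0.5, each = width)
  base <- background_level + lighting_gradient * (px / width - 0.5)
  v <- base

  # ribbon membership: inside the outer curve but not inside the inner one
  bb <- c(min(outer$points[, 1]), max(outer$points[, 1]),
          min(outer$points[, 2]), max(outer$points[, 2]))
  cand <- which(px >= bb[1] & px <= bb[2] & py >= bb[3] & py <= bb[4])
  in_out <- points_in_polygon(px[cand], py[cand],
                              outer$points[, 1], outer$points[, 2])
  cand <- cand[in_out]
  in_in <- points_in_polygon(px[cand], py[cand],
                             inner$points[, 1], inner$points[, 2])
  ribbon <- cand[!in_in]

  if (length(ribbon)) {
    # exact nearest mid-curve sample per ribbon pixel (1-NN)
    nearest <- as.integer(as.character(class::knn1(
      mid$points, cbind(px[ribbon], py[ribbon]),
      factor(seq_len(nrow(mid$points))))))
    arcs <- mid$arclength[nearest]
    s_frac <- ((arcs - anchor_arc) %% mid$total_length) / mid$total_length
    g <- expression_fn(s_frac)
    v[ribbon] <- base[ribbon] - stain_strength * g
  }

  for (ann in annotations) {
    level <- if (is.null(ann$level)) 0.2 else ann$level
    hit <- if (identical(ann$shape, "disc")) {
      (px - ann$x)^2 + (py - ann$y)^2 <= ann$r^2
    } else {
      px >= ann$x & px <= ann$x + ann$w & py >= ann$y & py <= ann$y + ann$h
    }
    v[hit] <- level
  }

  if (noise_sd > 0) {
    v <- v + stats::rnorm(length(v), sd = noise_sd)
  }
  v <- pmin(pmax(v, 0), 1)
  img <- rgb_image(matrix(round(v * 255), nrow = height, ncol = width,
                          byrow = TRUE))

  s_truth <- (seq_len(1000L) - 1L) / 1000
  truth <- structure(list(geometry = geometry,
                          arc_fraction = s_truth,
                          expression = expression_fn(s_truth),
                          background_level = background_level,
                          lighting_gradient = lighting_gradient,
                          stain_strength = stain_strength,
                          noise_sd = noise_sd, seed = seed),
                     class = "phantom_truth")
  list(image = img, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> painted profile peak %.2f, noise sd %.3g, seed %d\n",
              max(x$expression), x$noise_sd, x$seed))
  invisible(x)
}

#' Analytic phantom volumes
#'
#' Ground-truth 3D expression arrays: an axis-aligned box of uniform
#' expression, a spherical shell (the voxel analogue of the two-layer body
#' wall) optionally modulated around the primary axis, or a uniform block.
#'
#' @param kind `"box"`, `"shell"` or `"uniform"`.
#' @param dims integer triple, voxels `(x, y, z)`.
#' @param value expression level inside the support. Default 1.
#' @param box for `kind = "box"`: list of index ranges
#'   `list(x = c(lo, hi), y = ..., z = ...)`.
#' @param center,r_inner,r_outer for `kind = "shell"`: sphere center (voxel
#'   index coordinates) and shell radii.
#' @param edge_width for `kind = "shell"`: width (voxels) of the linear
#'   intensity ramp at the shell edges; 0 gives a hard binary shell, larger
#'   values emulate the soft falloff of real stain and reduce voxel
#'   aliasing. Default 2.
#' @param modulation for `kind = "shell"`: optional function of the azimuth
#'   about the x axis (radians, in `(-pi, pi]`) multiplying the shell value.
#' @return An `expression_volume`.
#' @export
make_phantom_volume <- function(kind = c("box", "shell", "uniform"), dims,
                                value = 1, box = NULL, center = NULL,
                                r_inner = NULL, r_outer = NULL,
                                edge_width = 2, modulation = NULL) {
  kind <- match.arg(kind)
  dims <- as.integer(dims)
  P <- array(0, dims)
  if (kind == "uniform") {
    P[] <- value
  } else if (kind == "box") {
    P[box$x[1]:box$x[2], box$y[1]:box$y[2], box$z[1]:box$z[2]] <- value
  } else {
    ix <- rep(seq_len(dims[1]), times = dims[2] * dims[3])
    iy <- rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3])
    iz <- rep(seq_len(dims[3]), each = dims[1] * dims[2])
    r <- sqrt((ix - center[1])^2 + (iy - center[2])^2 + (iz - center[3])^2)
    if (edge_width > 0) {
      ramp <- pmin(pmax(pmin(r - r_inner, r_outer - r) / edge_width + 0.5, 0), 1)
    } else {
      ramp <- as.numeric(r >= r_inner & r <= r_outer)
    }
    vals <- value * ramp
    if (!is.null(modulation)) {
      phi <- atan2(iy - center[2], iz - center[3])
      pos <- vals > 0
      vals[pos] <- vals[pos] * modulation(phi[pos])
    }
    P[] <- vals
  }
  new_expression_volume(pmin(pmax(P, 0), 1))
}

#' Project a phantom volume into a perpendicular view pair
#'
#' The optical model for fully transparent embryos with dark stain: each
#' view pixel records the maximum expression (darkest raw intensity) along
#' its viewing ray. The lateral view projects along y, the oral view along
#' x. Reference points at two shared-z corners are emitted on both views so
#' the pair feeds straight into [align_views()].
#'
#' @param truth_volume an `expression_volume`.
#' @return List with elements `lateral` and `oral` ([view_image()]s).
#' @export
render_view_pair <- function(truth_volume) {
  d <- dim(truth_volume)
  S1 <- t(apply(truth_volume, c(1, 3), max))  # [z, x]
  S2 <- t(apply(truth_volume, c(2, 3), max))  # [z, y]
  refs_z <- c(0.5, d[3] - 0.5)
  lateral <- view_image(S1, plane = "lateral",
                        reference_points = cbind(c(0.5, 0.5), refs_z))
  oral <- view_image(S2, plane = "oral",
                     reference_points = cbind(c(0.5, 0.5), refs_z))
  list(lateral = lateral, oral = oral)
}
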
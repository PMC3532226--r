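#' Single-view images for 3D reconstruction
#'
#' A `view_image` holds one projection of the embryo in expression units
#' (`[0, 1]`, inverted-intensity convention: high value = strong stain).
#' The matrix is indexed `[z, u]` where `z` runs down image rows along the
#' shared vertical axis and `u` along image columns — `x` for the lateral
#' view (the `(x, z)` plane) and `y` for the oral view (the `(y, z)` plane).
#'
#' @param expression numeric matrix in `[0, 1]`, rows = z, columns = x or y.
#' @param plane `"lateral"` or `"oral"`.
#' @param reference_points optional n-by-2 matrix of `(u, z)` crosshair
#'   coordinates used by [align_views()]; rows matched across views by order.
#' @return A `view_image`.
#' @export
view_image <- function(expression, plane = c("lateral", "oral"),
                       reference_points = NULL) {
  plane <- match.arg(plane)
  expression <- as.matrix(expression)
  if (min(expression) < 0 || max(expression) > 1) {
    lq_abort("lq_argument_error", "view expression values must lie in [0, 1]")
  }
  if (!is.null(reference_points)) {
    reference_points <- as_point_matrix(reference_points, "reference_points")
  }
  structure(list(expression = expression, plane = plane,
                 reference_points = reference_points),
            class = "view_image")
}

#' @export
print.view_image <- function(x, ...) {
  cat(sprintf("<view_image> %s, %d x %d px, %d reference point(s)\n",
              x$plane, nrow(x$expression), ncol(x$expression),
              if (is.null(x$reference_points)) 0L else nrow(x$reference_points)))
  invisible(x)
}

#' Convert a stained micrograph to an expression view
#'
#' Greyscale conversion plus intensity inversion: dark stain on a light
#' background becomes expression in `[0, 1]`.
#'
#' @param image an [rgb_image()].
#' @inheritParams view_image
#' @return A `view_image`.
#' @export
as_view_image <- function(image, plane = c("lateral", "oral"),
                          reference_points = NULL) {
  if (!inherits(image, "rgb_image")) image <- rgb_image(image)
  grey <- (unclass(image)[, , 1] + unclass(image)[, , 2] + unclass(image)[, , 3]) / 3
  view_image(1 - grey / 255, plane = plane, reference_points = reference_points)
}

#' Align the oral view to the lateral view along z
#'
#' Fits the 1D affine map (scale + shift on the z axis) that best matches the
#' oral reference-point z coordinates to the lateral ones in least squares,
#' then resamples the oral image height accordingly (linear interpolation
#' along rows; regions mapping outside the source get 0). Column coordinates
#' are untouched: the two views share only the z axis.
#'
#' @param lateral,oral [view_image()]s with at least 2 reference points each
#'   (matched by order).
#' @return The resampled oral `view_image`, with the same number of rows as
#'   `lateral` and the fitted map attached as attribute `"zmap"` (list with
#'   `scale`, `shift`; `z_lat = scale * z_oral + shift`).
#' @export
align_views <- function(lateral, oral) {
  for (v in list(lateral, oral)) {
    if (is.null(v$reference_points) || nrow(v$reference_points) < 2L) {
      lq_abort("lq_underdetermined", "need at least 2 reference points per view")
    }
  }
  if (nrow(lateral$reference_points) != nrow(oral$reference_points)) {
    lq_abort("lq_argument_error", "reference point counts differ between views")
  }
  zl <- lateral$reference_points[, 2]
  zo <- oral$reference_points[, 2]
  if (stats::var(zo) < .Machine$double.eps || stats::var(zl) < .Machine$double.eps) {
    lq_abort("lq_degenerate", "reference points have no spread along z")
  }
  # least squares for z_lat = a * z_oral + b
  a <- stats::cov(zo, zl) / stats::var(zo)
  b <- mean(zl) - a * mean(zo)

  src <- oral$expression
  n_out <- nrow(lateral$expression)
  z_out <- seq_len(n_out) - 0.5
  z_src <- (z_out - b) / a           # back to oral pixel coordinates
  r <- z_src + 0.5                   # fractional source row index
  r0 <- floor(r); w <- r - r0
  ok0 <- r0 >= 1 & r0 <= nrow(src)
  ok1 <- (r0 + 1) >= 1 & (r0 + 1) <= nrow(src)
  out <- matrix(0, n_out, ncol(src))
  for (i in seq_len(n_out)) {
    v0 <- if (ok0[i]) src[r0[i], ] else 0
    v1 <- if (ok1[i]) src[r0[i] + 1, ] else 0
    out[i, ] <- (1 - w[i]) * v0 + w[i] * v1
  }
  res <- view_image(out, plane = "oral",
                    reference_points = cbind(oral$reference_points[, 1],
                                             a * zo + b))
  attr(res, "zmap") <- list(scale = a, shift = b)
  res
}

new_expression_volume <- function(P, voxel_size = 1, axis = "x", ...) {
  if (min(P) < -1e-9 || max(P) > 1 + 1e-9) {
    lq_abort("lq_argument_error", "volume values must lie in [0, 1]")
  }
  structure(P, class = "expression_volume", voxel_size = voxel_size,
            axis = axis, ...)
}

#' @export
print.expression_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<expression_volume> %d x %d x %d voxels (primary axis: %s)\n",
              d[1], d[2], d[3], attr(x, "axis")))
  invisible(x)
}

#' Reconstruct a 3D expression array from two perpendicular views
#'
#' Mixes a lateral view S1 (the `(x, z)` plane) and an aligned oral view S2
#' (the `(y, z)` plane) into a 3D array by taking, for every voxel, the
#' minimum expression of the associated pixel pair:
#' `P[x, y, z] = min(S1[z, x], S2[z, y])`. Since stain is dark, the minimal
#' expression corresponds to the maximal raw pixel intensity — a voxel is
#' only as stained as both views allow.
#'
#' @param lateral a lateral [view_image()].
#' @param oral_aligned an oral [view_image()] already resampled by
#'   [align_views()] (same row count as `lateral`).
#' @return An `expression_volume` with dimensions
#'   `ncol(lateral) x ncol(oral) x nrow(lateral)` (x, y, z); values in
#'   `[0, 1]`; primary (oral-aboral) axis = x.
#' @export
reconstruct_two_views <- function(lateral, oral_aligned) {
  S1 <- lateral$expression
  S2 <- oral_aligned$expression
  if (nrow(S1) != nrow(S2)) {
    lq_abort("lq_dimension_error",
             sprintf("z extents differ after alignment (%d vs %d rows)",
                     nrow(S1), nrow(S2)))
  }
  X <- ncol(S1); Y <- ncol(S2); Z <- nrow(S1)
  P <- array(0, c(X, Y, Z))
  for (z in seq_len(Z)) {
    P[, , z] <- outer(S1[z, ], S2[z, ], pmin)
  }
  new_expression_volume(P)
}

# Bilinear sample of an image matrix (rows = y-ish, cols = x-ish) at
# continuous pixel coordinates (x, y) with pixel centers at half-integers.
# Out-of-image samples return 0.
bilinear_sample <- function(img, x, y) {
  H <- nrow(img); W <- ncol(img)
  cj <- x + 0.5; ri <- y + 0.5   # fractional col / row indices
  j0 <- floor(cj); i0 <- floor(ri)
  fx <- cj - j0; fy <- ri - i0
  val <- function(i, j) {
    ok <- i >= 1 & i <= H & j >= 1 & j <= W
    out <- numeric(length(i))
    if (any(ok)) out[ok] <- img[cbind(i[ok], j[ok])]
    out
  }
  (1 - fx) * (1 - fy) * val(i0, j0) +
    fx * (1 - fy) * val(i0, j0 + 1) +
    (1 - fx) * fy * val(i0 + 1, j0) +
    fx * fy * val(i0 + 1, j0 + 1)
}

#' Reconstruct a 3D expression array from one view under radial symmetry
#'
#' For expression patterns roughly symmetric about a drawn axis, fills a 3D
#' array from a single image by smoothly averaging pairs of image points
#' along circular arcs about the axis. For each voxel at azimuthal angle
#' `theta` (0..pi, measured from the image half-plane containing the first
#' base point) and radius `r` from the axis, the two base points S1 and S2
#' are the intersections of that circle with the image plane; the voxel value
#' is the angle-weighted average
#' `(1 - theta/pi) * I(S1) + (theta/pi) * I(S2)`, sampled bilinearly. Base
#' points outside the image contribute 0.
#'
#' The output volume is axis-aligned: dimension 1 (x) runs along the drawn
#' axis from its first endpoint, dimensions 2 (y, out of the image plane) and
#' 3 (z, the in-plane normal) are centered offsets of extent `out_depth`.
#' The central y plane reproduces the input image along the axis strip.
#'
#' @param image a [view_image()] or plain expression matrix in `[0, 1]`.
#' @param axis_line 2-by-2 matrix: rows are the two axis endpoints `(x, y)`
#'   in image pixel coordinates.
#' @param out_depth extent (voxels) of the two cross-axis dimensions; odd
#'   values put a voxel sheet exactly on the image plane.
#' @return An `expression_volume` with attributes `axis_origin`, `axis_dir`,
#'   `axis_normal` (image-plane frame) and `offsets` (cross-axis voxel
#'   offsets).
#' @export
reconstruct_radial <- function(image, axis_line, out_depth = 61L) {
  img <- if (inherits(image, "view_image")) image$expression else as.matrix(image)
  axis_line <- as_point_matrix(axis_line, "axis_line")
  if (nrow(axis_line) != 2L) {
    lq_abort("lq_argument_error", "axis_line must be two (x, y) endpoints")
  }
  A <- axis_line[1, ]; B <- axis_line[2, ]
  len <- sqrt(sum((B - A)^2))
  if (len < .Machine$double.eps) {
    lq_abort("lq_argument_error", "axis endpoints coincide")
  }
  ahat <- (B - A) / len
  nhat <- c(-ahat[2], ahat[1])       # in-plane normal; the S1 side
  out_depth <- as.integer(out_depth)
  X <- max(2L, round(len))
  t_ax <- (seq_len(X) - 0.5) * (len / X)
  offs <- seq_len(out_depth) - (out_depth + 1) / 2

  P <- array(0, c(X, out_depth, out_depth))
  # axial sample positions along the axis (image coordinates)
  ax_x <- A[1] + t_ax * ahat[1]
  ax_y <- A[2] + t_ax * ahat[2]
  for (jy in seq_len(out_depth)) {
    w <- offs[jy]                    # out-of-plane offset
    d <- rep(offs, each = X)         # in-plane offset (z), X x depth grid
    r <- sqrt(d^2 + w^2)
    theta <- atan2(abs(w), d)        # 0 on the S1 half-plane, pi on S2's
    s1x <- rep(ax_x, out_depth) + r * nhat[1]
    s1y <- rep(ax_y, out_depth) + r * nhat[2]
    s2x <- rep(ax_x, out_depth) - r * nhat[1]
    s2y <- rep(ax_y, out_depth) - r * nhat[2]
    v1 <- bilinear_sample(img, s1x, s1y)
    v2 <- bilinear_sample(img, s2x, s2y)
    P[, jy, ] <- (1 - theta / pi) * v1 + (theta / pi) * v2
  }
  new_expression_volume(pmin(pmax(P, 0), 1),
                        axis_origin = A, axis_dir = ahat, axis_normal = nhat,
                        offsets = offs)
}

# Trilinear interpolation in an expression_volume at continuous index
# coordinates (voxel centers at integer indices). Out of range -> 0.
trilinear_sample <- function(P, x, y, z) {
  d <- dim(P)
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  val <- function(i, j, k) {
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2] & k >= 1 & k <= d[3]
    out <- numeric(length(i))
    if (any(ok)) out[ok] <- P[cbind(i[ok], j[ok], k[ok])]
    out
  }
  (1 - fx) * (1 - fy) * (1 - fz) * val(x0, y0, z0) +
    fx * (1 - fy) * (1 - fz) * val(x0 + 1, y0, z0) +
    (1 - fx) * fy * (1 - fz) * val(x0, y0 + 1, z0) +
    (1 - fx) * (1 - fy) * fz * val(x0, y0, z0 + 1) +
    fx * fy * (1 - fz) * val(x0 + 1, y0 + 1, z0) +
    fx * (1 - fy) * fz * val(x0 + 1, y0, z0 + 1) +
    (1 - fx) * fy * fz * val(x0, y0 + 1, z0 + 1) +
    fx * fy * fz * val(x0 + 1, y0 + 1, z0 + 1)
}

#' Slice a volume through the primary body axis
#'
#' Cuts `n_slices` full planes through the primary (x) axis at equally
#' incremented angles `k * 180 / n_slices` degrees, `k = 0 .. n_slices - 1`.
#' Each slice is a 2D expression image covering both half-planes, sampled
#' trilinearly; slice 1 (angle 0) is the central `(x, z)` plane of the
#' volume. Together the slices cover the full circle, since the plane at
#' angle `a + 180` is the plane at `a`.
#'
#' @param volume an `expression_volume`.
#' @param n_slices number of slices; default 9 (every 20 degrees).
#' @return List of slice matrices indexed `[offset, x]`, with the slice
#'   angles (degrees) in attribute `"angles_deg"` and the cross-axis offsets
#'   in `"offsets"`.
#' @export
slice_volume <- function(volume, n_slices = 9L) {
  n_slices <- as.integer(n_slices)
  if (n_slices < 1L) lq_abort("lq_argument_error", "n_slices must be >= 1")
  d <- dim(volume)
  cy <- (d[2] + 1) / 2; cz <- (d[3] + 1) / 2
  q <- seq_len(d[3]) - cz            # in-slice offsets, reusing the z grid
  angles <- (seq_len(n_slices) - 1L) * 180 / n_slices
  xs <- rep(seq_len(d[1]), each = length(q))
  qs <- rep(q, times = d[1])
  slices <- lapply(angles, function(a) {
    phi <- a * pi / 180
    yy <- cy + qs * sin(phi)
    zz <- cz + qs * cos(phi)
    matrix(trilinear_sample(volume, xs, yy, zz), nrow = length(q), ncol = d[1])
  })
  attr(slices, "angles_deg") <- angles
  attr(slices, "offsets") <- q
  slices
}

#' Assemble a 2D expression landscape from a volume
#'
#' Slices the volume through the primary axis, decomposes every slice with a
#' shared embryo geometry (registered to the central slice), measures the
#' per-segment expression, replays a shared edit script, standardizes each
#' profile, and stacks the rows into the slice-by-position landscape array.
#'
#' The geometry must be expressed in slice pixel coordinates: `x` along the
#' axis (slice columns), `y` along the cross-axis offsets (slice rows).
#'
#' @param volume an `expression_volume`.
#' @param geometry an [embryo_geometry()] registered to the central slice.
#' @param n_slices number of angular slices, default 9.
#' @param segment_length decomposition segment length, pixels.
#' @param edit_script optional edit script (see [apply_edit_script()])
#'   applied to each raw profile before standardization; must not itself end
#'   in a `standardize` step.
#' @param pin,n_out standardization parameters, see [standardize()].
#' @param n_curve_points spline density for the decomposition.
#' @return An `expression_landscape`: `n_slices`-by-`n_out` matrix with
#'   attributes `slice_angles` (degrees) and `grid` (normalized positions).
#' @export
build_landscape <- function(volume, geometry, n_slices = 9L, segment_length,
                            edit_script = NULL, pin = 25, n_out = 101L,
                            n_curve_points = 2e4) {
  slices <- slice_volume(volume, n_slices)
  dec <- decompose_cell_layer(geometry, segment_length,
                              n_curve_points = n_curve_points)
  rows <- lapply(slices, function(sl) {
    prof <- measure_segments(sl, dec)
    if (!is.null(edit_script)) prof <- apply_edit_script(prof, edit_script)
    std <- standardize(prof, pin = pin, n_out = n_out, allow_zero = TRUE)
    std$value
  })
  structure(do.call(rbind, rows), class = "expression_landscape",
            slice_angles = attr(slices, "angles_deg"),
            grid = seq(-50, 50, length.out = n_out))
}

#' @export
print.expression_landscape <- function(x, ...) {
  cat(sprintf("<expression_landscape> %d slices x %d positions\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Read / write expression volumes
#'
#' Volumes are stored as little-endian float32 raw binary plus a JSON sidecar
#' (`<path>.json`) recording the dimensions, voxel size and axis convention.
#'
#' @param volume an `expression_volume`.
#' @param path path of the raw binary file; the sidecar is `<path>.json`.
#' @return `read_volume()` returns an `expression_volume`; `write_volume()`
#'   returns `path` invisibly.
#' @export
write_volume <- function(volume, path) {
  meta <- list(dims = dim(volume), voxel_size = attr(volume, "voxel_size"),
               axis = attr(volume, "axis"), dtype = "float32",
               byte_order = "little")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(volume), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- prod(meta$dims)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, numeric(), n = n, size = 4L, endian = "little")
  new_expression_volume(pmin(pmax(array(vals, meta$dims), 0), 1),
                        voxel_size = meta$voxel_size, axis = meta$axis)
}
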
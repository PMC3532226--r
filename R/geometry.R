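#' Digital embryo geometries
#'
#' An `embryo_geometry` represents the body wall of a two-layered embryo as a
#' pair of closed node rings placed on the outer and inner cell-layer
#' boundaries. Coordinates are in pixel units of the image the geometry was
#' drawn on: `x` runs along columns, `y` along rows, origin at the top-left
#' image corner. Both rings are normalized to counterclockwise orientation
#' (positive shoelace area in the stored x/y frame) on construction so that
#' arc-length fractions are comparable across geometries.
#'
#' @param outer_nodes,inner_nodes numeric n-by-2 matrices (columns x, y) or
#'   objects coercible to them; ordered closed rings, at least 4 nodes each.
#'   The last node must not repeat the first; closure is implicit.
#' @param boundary_markers optional numeric pair of arc-length fractions in
#'   `[0, 1)` along the ribbon marking the two endoderm-ectoderm boundaries.
#' @param aboral_anchor arc-length fraction in `[0, 1)` of the aboral pole,
#'   where the cell-layer decomposition starts. Default 0 (first node).
#' @param stage_hpf developmental stage, hours past fertilization (numeric) or
#'   a symbolic stage label such as `"blastula"`.
#'
#' @return An object of class `embryo_geometry`: a list with elements
#'   `outer_nodes`, `inner_nodes`, `boundary_markers`, `aboral_anchor`,
#'   `stage_hpf`.
#' @seealso [build_spline_curve()], [decompose_cell_layer()],
#'   [average_geometries()], [interpolate_stages()], [register_to_image()]
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 13)[-13]
#' g <- embryo_geometry(
#'   outer_nodes = cbind(100 + 80 * cos(th), 100 + 80 * sin(th)),
#'   inner_nodes = cbind(100 + 60 * cos(th), 100 + 60 * sin(th)),
#'   stage_hpf = 24
#' )
#' g
embryo_geometry <- function(outer_nodes, inner_nodes, boundary_markers = NULL,
                            aboral_anchor = 0, stage_hpf = NULL) {
  outer_nodes <- as_node_matrix(outer_nodes, "outer_nodes")
  inner_nodes <- as_node_matrix(inner_nodes, "inner_nodes")
  if (!is.null(boundary_markers)) {
    boundary_markers <- as.numeric(boundary_markers)
    if (length(boundary_markers) != 2L || anyNA(boundary_markers) ||
        any(boundary_markers < 0 | boundary_markers >= 1)) {
      lq_abort("lq_invalid_geometry",
               "boundary_markers must be two arc-length fractions in [0, 1)")
    }
    if (boundary_markers[1] == boundary_markers[2]) {
      lq_abort("lq_invalid_geometry", "boundary_markers must be distinct")
    }
  }
  stopifnot_scalar_number(aboral_anchor)
  if (aboral_anchor < 0 || aboral_anchor >= 1) {
    lq_abort("lq_invalid_geometry", "aboral_anchor must lie in [0, 1)")
  }

  o <- normalize_ring(outer_nodes)
  i <- normalize_ring(inner_nodes)
  if (o$reversed) {
    aboral_anchor <- (1 - aboral_anchor) %% 1
    if (!is.null(boundary_markers)) {
      boundary_markers <- sort((1 - boundary_markers) %% 1)
    }
  }

  geom <- structure(
    list(outer_nodes = o$nodes, inner_nodes = i$nodes,
         boundary_markers = boundary_markers,
         aboral_anchor = aboral_anchor, stage_hpf = stage_hpf),
    class = "embryo_geometry"
  )
  validate_geometry(geom)
  geom
}

as_node_matrix <- function(x, name) {
  if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
  if (is.list(x) && !is.matrix(x)) x <- do.call(rbind, lapply(x, as.numeric))
  x <- unname(as.matrix(x))
  storage.mode(x) <- "double"
  if (ncol(x) != 2L) {
    lq_abort("lq_invalid_geometry", sprintf("%s must have two columns (x, y)", name))
  }
  if (nrow(x) < 4L) {
    lq_abort("lq_invalid_geometry",
             sprintf("%s needs at least 4 nodes, got %d", name, nrow(x)))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    lq_abort("lq_invalid_geometry", sprintf("%s contains non-finite coordinates", name))
  }
  colnames(x) <- c("x", "y")
  x
}

# Signed shoelace area; positive = counterclockwise in the stored x/y frame.
ring_area <- function(nodes) {
  x <- nodes[, 1]; y <- nodes[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Reverse node order (keeping node 1 first) if the ring is clockwise.
normalize_ring <- function(nodes) {
  reversed <- ring_area(nodes) < 0
  if (reversed) {
    n <- nrow(nodes)
    nodes <- nodes[c(1L, n:2L), , drop = FALSE]
  }
  list(nodes = nodes, reversed = reversed)
}

segments_intersect <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
    ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
}

ring_self_intersects <- function(nodes) {
  n <- nrow(nodes)
  idx <- rbind(cbind(1:n, c(2:n, 1L)))
  for (a in seq_len(n - 2L)) {
    for (b in (a + 1L):n) {
      # skip adjacent edges (share a vertex)
      if (b == a + 1L || (a == 1L && b == n)) next
      if (segments_intersect(nodes[idx[a, 1], ], nodes[idx[a, 2], ],
                             nodes[idx[b, 1], ], nodes[idx[b, 2], ])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# Even-odd point-in-polygon for a single point against a node ring.
point_in_ring <- function(p, nodes) {
  as.logical(points_in_polygon(p[1], p[2], nodes[, 1], nodes[, 2]))
}

validate_geometry <- function(geom) {
  if (ring_self_intersects(geom$outer_nodes)) {
    lq_abort("lq_invalid_geometry", "outer ring is self-intersecting")
  }
  if (ring_self_intersects(geom$inner_nodes)) {
    lq_abort("lq_invalid_geometry", "inner ring is self-intersecting")
  }
  inside <- points_in_polygon(geom$inner_nodes[, 1], geom$inner_nodes[, 2],
                              geom$outer_nodes[, 1], geom$outer_nodes[, 2])
  if (!all(inside)) {
    lq_abort("lq_invalid_geometry",
             "inner ring must lie strictly inside the outer ring")
  }
  invisible(geom)
}

#' @export
print.embryo_geometry <- function(x, ...) {
  cat(sprintf("<embryo_geometry> %d outer / %d inner nodes",
              nrow(x$outer_nodes), nrow(x$inner_nodes)))
  if (!is.null(x$stage_hpf)) cat(sprintf(", stage %s", format(x$stage_hpf)))
  cat("\n")
  if (!is.null(x$boundary_markers)) {
    cat(sprintf("  endoderm boundaries at ribbon fractions %.3f, %.3f\n",
                x$boundary_markers[1], x$boundary_markers[2]))
  }
  cat(sprintf("  aboral anchor at fraction %.3f\n", x$aboral_anchor))
  invisible(x)
}

check_compatible <- function(a, b) {
  if (nrow(a$outer_nodes) != nrow(b$outer_nodes) ||
      nrow(a$inner_nodes) != nrow(b$inner_nodes)) {
    lq_abort("lq_incompatible_geometry",
             "geometries have different node counts per ring")
  }
  if (is.null(a$boundary_markers) != is.null(b$boundary_markers)) {
    lq_abort("lq_incompatible_geometry",
             "geometries disagree on boundary-marker presence")
  }
  invisible(TRUE)
}

#' Average several embryo geometries node-wise
#'
#' Corresponding nodes across geometries (same index on the same ring) are
#' averaged arithmetically; boundary markers and the aboral anchor are
#' averaged as arc-length fractions, and numeric stages are averaged. Node
#' correspondence is the caller's responsibility: all geometries must have
#' been digitized with the same number of nodes placed at comparable
#' anatomical positions.
#'
#' @param geometries list of [embryo_geometry()] objects (typically 2 to 5)
#'   with identical node counts per ring and the same marker presence.
#' @return A single averaged `embryo_geometry`.
#' @export
average_geometries <- function(geometries) {
  if (!is.list(geometries) || length(geometries) < 1L) {
    lq_abort("lq_argument_error", "need a non-empty list of geometries")
  }
  ref <- geometries[[1]]
  for (g in geometries[-1]) check_compatible(ref, g)

  mean_mat <- function(field) {
    Reduce(`+`, lapply(geometries, `[[`, field)) / length(geometries)
  }
  markers <- NULL
  if (!is.null(ref$boundary_markers)) {
    markers <- Reduce(`+`, lapply(geometries, `[[`, "boundary_markers")) /
      length(geometries)
  }
  stages <- lapply(geometries, `[[`, "stage_hpf")
  stage <- if (all(vapply(stages, is.numeric, logical(1))) &&
               !any(vapply(stages, is.null, logical(1)))) {
    mean(unlist(stages))
  } else {
    ref$stage_hpf
  }
  anchor <- mean(vapply(geometries, `[[`, numeric(1), "aboral_anchor"))
  embryo_geometry(mean_mat("outer_nodes"), mean_mat("inner_nodes"),
                  boundary_markers = markers, aboral_anchor = anchor,
                  stage_hpf = stage)
}

#' Interpolate between two staged geometries
#'
#' Node-wise linear interpolation `(1 - t) * a + t * b` between two
#' stage-average geometries, producing the continuous range of intermediate
#' morphologies used to match an arbitrary embryo image.
#'
#' @param geom_a,geom_b compatible [embryo_geometry()] objects.
#' @param t interpolation fraction in `[0, 1]`; 0 returns `geom_a`, 1 returns
#'   `geom_b`.
#' @return The interpolated `embryo_geometry`; numeric stages are interpolated
#'   the same way.
#' @export
interpolate_stages <- function(geom_a, geom_b, t) {
  stopifnot_scalar_number(t)
  if (t < 0 || t > 1) {
    lq_abort("lq_domain_error", sprintf("t = %g outside [0, 1]", t))
  }
  check_compatible(geom_a, geom_b)
  lerp <- function(field) (1 - t) * geom_a[[field]] + t * geom_b[[field]]
  markers <- if (!is.null(geom_a$boundary_markers)) lerp("boundary_markers")
  stage <- if (is.numeric(geom_a$stage_hpf) && is.numeric(geom_b$stage_hpf)) {
    (1 - t) * geom_a$stage_hpf + t * geom_b$stage_hpf
  } else if (t < 0.5) geom_a$stage_hpf else geom_b$stage_hpf
  embryo_geometry(lerp("outer_nodes"), lerp("inner_nodes"),
                  boundary_markers = markers, aboral_anchor = lerp("aboral_anchor"),
                  stage_hpf = stage)
}

# Closed-form least-squares similarity transform (uniform scale, rotation,
# translation) mapping src (n x 2) onto dst (n x 2).
fit_similarity <- function(src, dst) {
  sc <- colMeans(src); dc <- colMeans(dst)
  s0 <- sweep(src, 2, sc); d0 <- sweep(dst, 2, dc)
  denom <- sum(s0^2)
  if (denom < .Machine$double.eps) {
    lq_abort("lq_degenerate", "source points are coincident")
  }
  a <- sum(s0[, 1] * d0[, 1] + s0[, 2] * d0[, 2])
  b <- sum(s0[, 1] * d0[, 2] - s0[, 2] * d0[, 1])
  theta <- atan2(b, a)
  scale <- sqrt(a^2 + b^2) / denom
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  shift <- dc - as.numeric(scale * R %*% sc)
  list(scale = scale, theta = theta, shift = shift, R = R)
}

apply_similarity <- function(nodes, tf) {
  sweep(nodes %*% t(tf$scale * tf$R), 2, tf$shift, `+`)
}

#' Register a geometry onto an image by matched control points
#'
#' Fits the least-squares similarity transform (uniform scale + rotation +
#' translation) that maps `source_points` onto `target_points` and applies it
#' to every node of the geometry. This is the programmatic counterpart of
#' dragging a projected geometry over the cell-layer boundaries of a stained
#' embryo: pick a few landmark pairs (e.g. the poles and widest points),
#' register, then fine-tune single nodes with [set_node()] if needed.
#'
#' @param geometry an [embryo_geometry()].
#' @param source_points,target_points matched n-by-2 point sets (n >= 2) in
#'   geometry and image coordinates respectively.
#' @return The transformed `embryo_geometry`. The fitted transform is attached
#'   as attribute `"transform"` (list with `scale`, `theta`, `shift`).
#' @export
register_to_image <- function(geometry, source_points, target_points) {
  src <- as_point_matrix(source_points, "source_points")
  dst <- as_point_matrix(target_points, "target_points")
  if (nrow(src) != nrow(dst)) {
    lq_abort("lq_argument_error", "source and target point counts differ")
  }
  if (nrow(src) < 2L) {
    lq_abort("lq_underdetermined",
             "need at least 2 point pairs for a similarity transform")
  }
  tf <- fit_similarity(src, dst)
  out <- embryo_geometry(apply_similarity(geometry$outer_nodes, tf),
                         apply_similarity(geometry$inner_nodes, tf),
                         boundary_markers = geometry$boundary_markers,
                         aboral_anchor = geometry$aboral_anchor,
                         stage_hpf = geometry$stage_hpf)
  attr(out, "transform") <- tf[c("scale", "theta", "shift")]
  out
}

as_point_matrix <- function(x, name) {
  if (is.data.frame(x)) x <- as.matrix(x[, 1:2])
  if (is.list(x) && !is.matrix(x)) x <- do.call(rbind, lapply(x, as.numeric))
  x <- unname(as.matrix(x))
  storage.mode(x) <- "double"
  if (ncol(x) != 2L || anyNA(x)) {
    lq_abort("lq_argument_error", sprintf("%s must be finite n-by-2 (x, y)", name))
  }
  x
}

#' Replace a single geometry node
#'
#' Direct node override for local adjustments after [register_to_image()].
#'
#' @param geometry an [embryo_geometry()].
#' @param ring `"outer"` or `"inner"`.
#' @param index node index (1-based, in stored counterclockwise order).
#' @param point length-2 numeric `(x, y)`.
#' @return The modified `embryo_geometry` (revalidated).
#' @export
set_node <- function(geometry, ring = c("outer", "inner"), index, point) {
  ring <- match.arg(ring)
  field <- paste0(ring, "_nodes")
  nodes <- geometry[[field]]
  if (index < 1L || index > nrow(nodes)) {
    lq_abort("lq_argument_error", "node index out of range")
  }
  nodes[index, ] <- as.numeric(point)
  geometry[[field]] <- nodes
  validate_geometry(geometry)
  geometry
}

#' Read / write geometry JSON files
#'
#' Geometries are stored as JSON with keys `outer_nodes`, `inner_nodes`
#' (arrays of `[x, y]` pairs), `boundary_markers`, `aboral_anchor` and
#' `stage_hpf`, matching the on-disk stage-library format.
#'
#' @param path file path.
#' @return `read_geometry()` returns an [embryo_geometry()];
#'   `write_geometry()` returns `path` invisibly.
#' @export
read_geometry <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  embryo_geometry(j$outer_nodes, j$inner_nodes,
                  boundary_markers = j$boundary_markers,
                  aboral_anchor = if (is.null(j$aboral_anchor)) 0 else j$aboral_anchor,
                  stage_hpf = j$stage_hpf)
}

#' @rdname read_geometry
#' @param geometry an [embryo_geometry()] to serialize.
#' @export
write_geometry <- function(geometry, path) {
  jsonlite::write_json(
    list(outer_nodes = unname(geometry$outer_nodes),
         inner_nodes = unname(geometry$inner_nodes),
         boundary_markers = geometry$boundary_markers,
         aboral_anchor = geometry$aboral_anchor,
         stage_hpf = geometry$stage_hpf),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
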
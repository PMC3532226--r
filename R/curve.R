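#' Build a dense cubic-spline curve through geometry nodes
#'
#' Connects an ordered node list by a cubic spline sampled densely (about
#' 1e5 points by default), the working representation of a cell-layer
#' boundary. The spline is parameterized by cumulative chord length; closed
#' rings use periodic end conditions, open chains natural end conditions.
#'
#' @param nodes n-by-2 matrix of `(x, y)` node coordinates, n >= 4, no two
#'   consecutive nodes identical (for closed curves this includes the
#'   last-to-first closure).
#' @param n_points number of sampled points, uniform in the chord-length
#'   parameter. Default `1e5`.
#' @param closed logical; `TRUE` for a closed ring (the sampling covers one
#'   full period without duplicating the start point).
#' @return An object of class `layer_curve`: list with `points` (n_points-by-2),
#'   `arclength` (cumulative polyline arc length, starting at 0),
#'   `total_length` (closing segment included for closed curves) and `closed`.
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 9)[-9]
#' cv <- build_spline_curve(cbind(cos(th), sin(th)), n_points = 1000, closed = TRUE)
#' max(abs(sqrt(rowSums(cv$points^2)) - 1))  # spline-vs-circle deviation
build_spline_curve <- function(nodes, n_points = 1e5, closed = TRUE) {
  nodes <- as_point_matrix(nodes, "nodes")
  if (nrow(nodes) < 4L) {
    lq_abort("lq_invalid_geometry",
             sprintf("need at least 4 nodes, got %d", nrow(nodes)))
  }
  n_points <- as.integer(n_points)
  if (n_points < nrow(nodes)) {
    lq_abort("lq_argument_error", "n_points must be at least the node count")
  }
  pts <- if (closed) rbind(nodes, nodes[1, ]) else nodes
  seg <- sqrt(rowSums(diff(pts)^2))
  if (any(seg < .Machine$double.eps)) {
    lq_abort("lq_invalid_geometry", "duplicate consecutive nodes")
  }
  tt <- c(0, cumsum(seg))
  tmax <- tt[length(tt)]
  method <- if (closed) "periodic" else "natural"
  tout <- if (closed) {
    seq(0, tmax, length.out = n_points + 1L)[seq_len(n_points)]
  } else {
    seq(0, tmax, length.out = n_points)
  }
  sx <- stats::spline(tt, pts[, 1], method = method, xout = tout)$y
  sy <- stats::spline(tt, pts[, 2], method = method, xout = tout)$y
  points <- cbind(x = sx, y = sy)
  d <- sqrt(rowSums(diff(points)^2))
  arclength <- c(0, cumsum(d))
  total <- if (closed) {
    arclength[n_points] + sqrt(sum((points[n_points, ] - points[1, ])^2))
  } else {
    arclength[n_points]
  }
  structure(list(points = points, arclength = arclength,
                 total_length = total, closed = closed),
            class = "layer_curve")
}

#' @export
print.layer_curve <- function(x, ...) {
  cat(sprintf("<layer_curve> %d points, length %.2f px, %s\n",
              nrow(x$points), x$total_length,
              if (x$closed) "closed" else "open"))
  invisible(x)
}

# Point on the (piecewise-linear view of the) curve at arc length s,
# wrapping for closed curves. Vectorized over s.
curve_point_at <- function(curve, s) {
  n <- nrow(curve$points)
  if (curve$closed) s <- s %% curve$total_length
  s <- pmin(pmax(s, 0), curve$total_length)
  pts <- curve$points
  arc <- curve$arclength
  if (curve$closed) {
    pts <- rbind(pts, pts[1, ])
    arc <- c(arc, curve$total_length)
  }
  idx <- findInterval(s, arc, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(arc) - 1L)
  seg_len <- arc[idx + 1L] - arc[idx]
  w <- ifelse(seg_len > 0, (s - arc[idx]) / seg_len, 0)
  cbind(x = pts[idx, 1] + w * (pts[idx + 1L, 1] - pts[idx, 1]),
        y = pts[idx, 2] + w * (pts[idx + 1L, 2] - pts[idx, 2]))
}

#' Nearest sampled point on a curve
#'
#' Finds the sampled curve point closest (Euclidean) to a query point; ties
#' are broken toward the lowest index. Used to match each outer-boundary
#' point to the inner spline during cell-layer decomposition.
#'
#' @param p length-2 numeric `(x, y)`.
#' @param curve a [build_spline_curve()] result.
#' @return List with `index` (into `curve$points`), `point` (the coordinates),
#'   `distance`, and `arc` (arc-length position of that point).
#' @export
nearest_point_on_curve <- function(p, curve) {
  if (!inherits(curve, "layer_curve") || nrow(curve$points) == 0L) {
    lq_abort("lq_argument_error", "curve must be a non-empty layer_curve")
  }
  p <- as.numeric(p)
  d2 <- (curve$points[, 1] - p[1])^2 + (curve$points[, 2] - p[2])^2
  i <- which.min(d2)  # which.min returns the first (lowest-index) minimum
  list(index = i, point = curve$points[i, ], distance = sqrt(d2[i]),
       arc = curve$arclength[i])
}
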
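#' Decompose the cell layer into parallel segments
#'
#' Partitions the ribbon between the outer and inner cell-layer splines into
#' quadrilateral segments of roughly uniform width, proceeding
#' counterclockwise from the aboral anchor. The outer curve is split at equal
#' arc-length intervals (the requested `segment_length`, with the division
#' remainder spread evenly so the closed curve is tiled exactly); each outer
#' boundary point is matched to its nearest point on the inner spline; inner
#' arcs left with large gaps (longer than `gap_factor * segment_length`) are
#' subdivided and matched back to the outer curve; finally the boundary
#' positions on both curves are smoothed by a circular moving average so the
#' segments are more uniformly spaced.
#'
#' @param geometry an [embryo_geometry()].
#' @param segment_length target outer-curve arc length per segment, pixels.
#'   Must be positive and less than half the outer perimeter.
#' @param smoothing_span odd integer width of the circular moving average
#'   applied to boundary arc positions. Default 3. `1` disables smoothing.
#' @param gap_factor inner-arc gaps longer than `gap_factor * segment_length`
#'   trigger subdivision. Default 1.5.
#' @param smoothing_passes number of smoothing passes. Default 1.
#' @param n_curve_points spline sampling density for both boundary curves.
#' @return An object of class `segment_decomposition`: list with `quads`
#'   (n-by-4-by-2 array; corners ordered outer_i, outer_i+1, inner_i+1,
#'   inner_i), `centers` (n-by-2 segment center points), `arc_positions`
#'   (strictly increasing mid-curve arc positions of the centers, measured
#'   from the aboral anchor), `total_arclength` (mid-curve perimeter),
#'   `boundary_indices` (segment indices at the endoderm-ectoderm boundaries,
#'   if the geometry carries markers), plus the matched `outer_points` /
#'   `inner_points` boundary rings.
#' @export
decompose_cell_layer <- function(geometry, segment_length, smoothing_span = 3L,
                                 gap_factor = 1.5, smoothing_passes = 1L,
                                 n_curve_points = 1e5) {
  stopifnot_scalar_number(segment_length)
  smoothing_span <- as.integer(smoothing_span)
  if (smoothing_span < 1L || smoothing_span %% 2L == 0L) {
    lq_abort("lq_argument_error", "smoothing_span must be a positive odd integer")
  }
  outer <- build_spline_curve(geometry$outer_nodes, n_points = n_curve_points,
                              closed = TRUE)
  inner <- build_spline_curve(geometry$inner_nodes, n_points = n_curve_points,
                              closed = TRUE)
  L <- outer$total_length
  if (segment_length <= 0 || segment_length >= L / 2) {
    lq_abort("lq_argument_error",
             "segment_length must be positive and below half the outer perimeter")
  }
  n_seg <- max(4L, round(L / segment_length))
  spacing <- L / n_seg
  anchor_s <- geometry$aboral_anchor * L

  s_outer <- (anchor_s + (seq_len(n_seg) - 1L) * spacing) %% L
  outer_pts <- curve_point_at(outer, s_outer)
  inner_match <- lapply(seq_len(n_seg), function(k) {
    nearest_point_on_curve(outer_pts[k, ], inner)
  })
  s_inner <- vapply(inner_match, `[[`, numeric(1), "arc")

  # Subdivide inner arcs with large gaps and match the new points back to the
  # outer curve, inserting the extra boundary pairs in order.
  Li <- inner$total_length
  thresh <- gap_factor * segment_length
  extra_outer <- numeric(0)
  extra_inner <- numeric(0)
  for (k in seq_len(n_seg)) {
    k2 <- if (k == n_seg) 1L else k + 1L
    gap <- (s_inner[k2] - s_inner[k]) %% Li
    if (gap > thresh && gap < Li / 2) {
      m <- ceiling(gap / segment_length) - 1L
      if (m > 0L) {
        s_new <- (s_inner[k] + gap * seq_len(m) / (m + 1L)) %% Li
        for (sn in s_new) {
          pin <- curve_point_at(inner, sn)
          back <- nearest_point_on_curve(pin[1, ], outer)
          extra_outer <- c(extra_outer, back$arc)
          extra_inner <- c(extra_inner, sn)
        }
      }
    }
  }
  if (length(extra_outer)) {
    s_outer <- c(s_outer, extra_outer)
    s_inner <- c(s_inner, extra_inner)
    ord <- order((s_outer - anchor_s) %% L)
    s_outer <- s_outer[ord]
    s_inner <- s_inner[ord]
  }

  # Circular moving-average smoothing of the boundary arc positions on each
  # curve; wrap-aware so positions near the seam average correctly.
  for (p in seq_len(smoothing_passes)) {
    if (smoothing_span > 1L) {
      s_outer <- smooth_circular_positions(s_outer, L, smoothing_span)
      s_inner <- smooth_circular_positions(s_inner, Li, smoothing_span)
    }
  }

  outer_pts <- curve_point_at(outer, s_outer)
  inner_pts <- curve_point_at(inner, s_inner)
  n <- nrow(outer_pts)
  nxt <- c(2:n, 1L)

  # Crossing check: the side edges of consecutive boundaries must not intersect.
  for (k in seq_len(n)) {
    if (segments_intersect(outer_pts[k, ], inner_pts[k, ],
                           outer_pts[nxt[k], ], inner_pts[nxt[k], ])) {
      lq_abort("lq_decomposition_failed",
               sprintf("segment edges cross at boundary %d; use a larger segment_length or fix the geometry", k),
               index = k)
    }
  }

  quads <- array(NA_real_, c(n, 4L, 2L),
                 dimnames = list(NULL, c("outer_a", "outer_b", "inner_b", "inner_a"),
                                 c("x", "y")))
  quads[, 1L, ] <- outer_pts
  quads[, 2L, ] <- outer_pts[nxt, ]
  quads[, 3L, ] <- inner_pts[nxt, ]
  quads[, 4L, ] <- inner_pts

  # Mid-curve: pointwise average of matched outer/inner boundary pairs; arc
  # positions of segment centers run along this polyline from the anchor.
  mid <- (outer_pts + inner_pts) / 2
  dmid <- sqrt(rowSums((mid[nxt, , drop = FALSE] - mid)^2))
  cum_mid <- c(0, cumsum(dmid))
  total_mid <- cum_mid[n + 1L]
  arc_positions <- cum_mid[seq_len(n)] + dmid / 2
  centers <- (mid + mid[nxt, , drop = FALSE]) / 2

  boundary_indices <- NULL
  if (!is.null(geometry$boundary_markers)) {
    target <- geometry$boundary_markers * total_mid
    boundary_indices <- vapply(target, function(s) {
      which.min(pmin(abs(arc_positions - s),
                     total_mid - abs(arc_positions - s)))
    }, integer(1))
  }

  structure(list(quads = quads, centers = centers,
                 arc_positions = arc_positions, total_arclength = total_mid,
                 boundary_indices = boundary_indices,
                 outer_points = outer_pts, inner_points = inner_pts),
            class = "segment_decomposition")
}

# Wrap-aware circular moving average of arc positions on a closed curve of
# length L. Each position is replaced by the mean of its span-wide window,
# neighbours unwrapped into the same branch first.
smooth_circular_positions <- function(s, L, span) {
  n <- length(s)
  half <- (span - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- ((i - half - 1L):(i + half - 1L)) %% n + 1L
    d <- (s[idx] - s[i] + L / 2) %% L - L / 2  # signed wrap difference
    out[i] <- (s[i] + mean(d)) %% L
  }
  out
}

#' @export
print.segment_decomposition <- function(x, ...) {
  cat(sprintf("<segment_decomposition> %d segments, mid-curve length %.1f px\n",
              dim(x$quads)[1], x$total_arclength))
  if (!is.null(x$boundary_indices)) {
    cat(sprintf("  endoderm-ectoderm boundaries at segments %d, %d\n",
                x$boundary_indices[1], x$boundary_indices[2]))
  }
  invisible(x)
}

#' Measure per-segment color intensities
#'
#' Averages the red, green and blue values of all pixels whose centers fall
#' inside each segment quadrilateral (even-odd rule, pixel centers at
#' half-integer coordinates) and converts them to expression units in
#' `[0, 1]`. With `invert = TRUE` (the default, matching the dark-stain
#' convention) expression is `(255 - value) / 255`, otherwise `value / 255`.
#' The greyscale trace is the unweighted mean of the three channel means
#' (set `grey = "luma"` for Rec.601 weights).
#'
#' Segments that catch no pixel center are filled in by circular linear
#' interpolation from their neighbours and reported in the profile's
#' `warnings` attribute. Segments partly outside the image are clipped to
#' the image with a warning.
#'
#' @param image an [rgb_image()], or a plain numeric matrix already in
#'   expression units `[0, 1]` (e.g. a volume slice), in which case `invert`
#'   is ignored and all channels carry the same values.
#' @param decomposition a [decompose_cell_layer()] result.
#' @param invert logical, default `TRUE`.
#' @param grey `"mean"` (default) or `"luma"`.
#' @return An `expression_profile`: data.frame with columns `position`,
#'   `mean_r`, `mean_g`, `mean_b`, `mean_grey`; attributes `total_length`,
#'   `boundary_positions` (arc positions of the marked boundary segments, if
#'   any), `closed = TRUE`, and `warnings`.
#' @export
measure_segments <- function(image, decomposition, invert = TRUE,
                             grey = c("mean", "luma")) {
  grey <- match.arg(grey)
  plain <- is.matrix(image) && !inherits(image, "rgb_image")
  if (plain) {
    expr_mat <- image
    H <- nrow(expr_mat); W <- ncol(expr_mat)
  } else {
    if (!inherits(image, "rgb_image")) image <- rgb_image(image)
    H <- dim(image)[1]; W <- dim(image)[2]
  }
  n <- dim(decomposition$quads)[1]
  means <- matrix(NA_real_, n, 3L)
  clipped <- FALSE

  for (k in seq_len(n)) {
    vx <- decomposition$quads[k, , 1]
    vy <- decomposition$quads[k, , 2]
    # candidate pixel centers (col - 0.5, row - 0.5) inside the bounding box
    j0 <- ceiling(min(vx) + 0.5); j1 <- floor(max(vx) + 0.5)
    i0 <- ceiling(min(vy) + 0.5); i1 <- floor(max(vy) + 0.5)
    if (j0 < 1L || j1 > W || i0 < 1L || i1 > H) clipped <- TRUE
    j0 <- max(j0, 1L); i0 <- max(i0, 1L)
    j1 <- min(j1, W); i1 <- min(i1, H)
    if (j1 < j0 || i1 < i0) next
    jj <- rep(j0:j1, times = i1 - i0 + 1L)
    ii <- rep(i0:i1, each = j1 - j0 + 1L)
    keep <- points_in_polygon(jj - 0.5, ii - 0.5, vx, vy)
    if (!any(keep)) next
    ii <- ii[keep]; jj <- jj[keep]
    if (plain) {
      means[k, ] <- mean(expr_mat[cbind(ii, jj)])
    } else {
      means[k, 1] <- mean(image[cbind(ii, jj, 1L)])
      means[k, 2] <- mean(image[cbind(ii, jj, 2L)])
      means[k, 3] <- mean(image[cbind(ii, jj, 3L)])
    }
  }

  warn <- character(0)
  if (clipped) {
    warn <- c(warn, "decomposition extends beyond the image; segments clipped")
    lq_warn("lq_clipped", warn[length(warn)])
  }
  empty <- which(is.na(means[, 1]))
  if (length(empty)) {
    if (length(empty) == n) {
      lq_abort("lq_argument_error", "no segment contains any pixel center")
    }
    for (ch in 1:3) means[, ch] <- fill_circular(means[, ch])
    warn <- c(warn, sprintf("segments without pixel centers interpolated: %s",
                            paste(empty, collapse = ", ")))
  }

  if (plain) {
    expr <- means
  } else {
    expr <- if (invert) (255 - means) / 255 else means / 255
  }
  grey_vals <- if (grey == "mean") rowMeans(expr) else {
    as.numeric(expr %*% c(0.299, 0.587, 0.114))
  }

  bpos <- NULL
  if (!is.null(decomposition$boundary_indices)) {
    bpos <- decomposition$arc_positions[decomposition$boundary_indices]
  }
  new_expression_profile(
    position = decomposition$arc_positions,
    mean_r = expr[, 1], mean_g = expr[, 2], mean_b = expr[, 3],
    mean_grey = grey_vals,
    total_length = decomposition$total_arclength,
    boundary_positions = bpos, warnings = warn)
}

# Circular linear interpolation across NA runs.
fill_circular <- function(v) {
  n <- length(v)
  ok <- which(!is.na(v))
  if (length(ok) == n) return(v)
  for (i in which(is.na(v))) {
    prev <- ok[ok < i]; nxt <- ok[ok > i]
    a <- if (length(prev)) max(prev) else max(ok)
    b <- if (length(nxt)) min(nxt) else min(ok)
    da <- (i - a) %% n
    db <- (b - i) %% n
    v[i] <- (db * v[a] + da * v[b]) / (da + db)
  }
  v
}

new_expression_profile <- function(position, mean_r, mean_g, mean_b, mean_grey,
                                   total_length, boundary_positions = NULL,
                                   warnings = character(0)) {
  df <- data.frame(position = position, mean_r = mean_r, mean_g = mean_g,
                   mean_b = mean_b, mean_grey = mean_grey)
  structure(df, class = c("expression_profile", "data.frame"),
            total_length = total_length,
            boundary_positions = boundary_positions,
            closed = TRUE, warnings = warnings)
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("<expression_profile> %d segments over %.1f px\n",
              nrow(x), attr(x, "total_length")))
  w <- attr(x, "warnings")
  if (length(w)) cat("  warnings:", paste(w, collapse = "; "), "\n")
  NextMethod()
}

profile_channels <- c("mean_r", "mean_g", "mean_b", "mean_grey")

#' Read / write expression-profile CSV files
#'
#' Profiles are stored as CSV with columns `position_px`, `mean_r`, `mean_g`,
#' `mean_b`, `mean_grey`; header comment lines (`#`) carry the mid-curve
#' total length and the endoderm-ectoderm boundary positions.
#'
#' @param path file path.
#' @return `read_profile()` returns an `expression_profile`;
#'   `write_profile()` returns `path` invisibly.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# total_length: %.10g", attr(profile, "total_length")), con)
  bp <- attr(profile, "boundary_positions")
  if (!is.null(bp)) {
    writeLines(sprintf("# boundary_positions: %.10g %.10g", bp[1], bp[2]), con)
  }
  df <- as.data.frame(profile)
  names(df)[names(df) == "position"] <- "position_px"
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @param profile an `expression_profile` to serialize.
#' @export
read_profile <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  get_num <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    as.numeric(strsplit(sub(paste0("^# ", key, ": *"), "", ln[1]), " +")[[1]])
  }
  df <- utils::read.csv(path, comment.char = "#")
  new_expression_profile(df$position_px, df$mean_r, df$mean_g, df$mean_b,
                         df$mean_grey,
                         total_length = get_num("total_length"),
                         boundary_positions = get_num("boundary_positions"))
}
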
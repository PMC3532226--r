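# Editing operations on raw expression profiles. All editors preserve the
# profile's positions and length; only intensity values change. The profile
# is treated as a closed loop (the ribbon is a closed curve), so smoothing
# and interpolation wrap around the aboral seam.

resolve_channels <- function(channel) {
  if (identical(channel, "all")) return(profile_channels)
  bad <- setdiff(channel, profile_channels)
  if (length(bad)) {
    lq_abort("lq_argument_error",
             sprintf("unknown channel(s): %s", paste(bad, collapse = ", ")))
  }
  channel
}

# Linear interpolation of a closed-loop signal (positions in [0, L)) at
# arbitrary arc positions s, wrapping across the seam.
circular_interp <- function(positions, values, s, total_length) {
  n <- length(positions)
  s <- s %% total_length
  xs <- c(positions[n] - total_length, positions, positions[1] + total_length)
  ys <- c(values[n], values, values[1])
  stats::approx(xs, ys, xout = s, rule = 2)$y
}

check_interval <- function(interval, n, spline_method = FALSE) {
  interval <- as.integer(interval)
  if (length(interval) != 2L || interval[1] > interval[2]) {
    lq_abort("lq_argument_error", "interval must be an index pair lo <= hi")
  }
  ctx <- if (spline_method) 2L else 1L
  if (interval[1] - ctx < 1L || interval[2] + ctx > n) {
    lq_abort("lq_context_error",
             sprintf("interval %d..%d leaves fewer than %d context point(s) at a profile end",
                     interval[1], interval[2], ctx))
  }
  interval
}

#' Repair an artefact interval in a profile
#'
#' Replaces the values inside an index interval — typically a trough or ridge
#' caused by an annotation overlapping the cell layer — by an interpolant
#' fitted to the flanking context, or by a constant. Available methods:
#' `"linear"` (straight interpolation across the flanks, 2 context points per
#' side), `"cubic_spline"` (natural cubic spline, 4 per side), `"pchip"`
#' (monotonicity-preserving piecewise cubic Hermite, 4 per side) and
#' `"constant"`.
#'
#' @param profile an `expression_profile`.
#' @param channel one of `"mean_r"`, `"mean_g"`, `"mean_b"`, `"mean_grey"`,
#'   or `"all"` (default) to repair every channel.
#' @param interval integer pair `c(lo, hi)` of segment indices to replace;
#'   must leave at least one context point on each side (two for the spline
#'   methods).
#' @param method interpolation method, see above.
#' @param constant_value required when `method = "constant"`.
#' @return The repaired `expression_profile`.
#' @export
repair_interval <- function(profile, channel = "all", interval,
                            method = c("linear", "cubic_spline", "pchip", "constant"),
                            constant_value = NULL) {
  method <- match.arg(method)
  channels <- resolve_channels(channel)
  n <- nrow(profile)
  spline_like <- method %in% c("cubic_spline", "pchip")
  interval <- check_interval(interval, n, spline_method = spline_like)
  lo <- interval[1]; hi <- interval[2]

  if (method == "constant") {
    if (is.null(constant_value)) {
      lq_abort("lq_argument_error", "constant method needs constant_value")
    }
    for (ch in channels) profile[[ch]][lo:hi] <- constant_value
    return(profile)
  }

  n_ctx <- if (spline_like) 4L else 2L
  left <- max(1L, lo - n_ctx):(lo - 1L)
  right <- (hi + 1L):min(n, hi + n_ctx)
  ctx <- c(left, right)
  x <- profile$position
  for (ch in channels) {
    y <- profile[[ch]]
    fit <- switch(method,
      linear = stats::approxfun(x[ctx], y[ctx]),
      cubic_spline = stats::splinefun(x[ctx], y[ctx], method = "natural"),
      pchip = stats::splinefun(x[ctx], y[ctx], method = "monoH.FC")
    )
    y[lo:hi] <- fit(x[lo:hi])
    profile[[ch]] <- y
  }
  profile
}

#' Smooth a profile with a circular moving average
#'
#' Lowpass filter with all coefficients equal to `1/span`; the window wraps
#' around the aboral seam since the profile is a closed loop. Preserves the
#' circular mean of the profile exactly.
#'
#' @param profile an `expression_profile`.
#' @param span odd positive window width; `1` is the identity.
#' @param channel channel selection as in [repair_interval()].
#' @return The smoothed `expression_profile`.
#' @export
moving_average <- function(profile, span, channel = "all") {
  span <- as.integer(span)
  if (span < 1L || span %% 2L == 0L) {
    lq_abort("lq_argument_error", "span must be a positive odd integer")
  }
  if (span > nrow(profile)) {
    lq_abort("lq_argument_error", "span exceeds the profile length")
  }
  for (ch in resolve_channels(channel)) {
    profile[[ch]] <- as.numeric(
      stats::filter(profile[[ch]], rep(1 / span, span),
                    method = "convolution", sides = 2, circular = TRUE))
  }
  profile
}

#' Subtract a constant background baseline
#'
#' Lowers every value by `baseline` and clamps at zero, removing the average
#' unstained background so that zero means no detected expression.
#'
#' @param profile an `expression_profile`.
#' @param baseline non-negative expression-unit constant.
#' @param channel channel selection as in [repair_interval()].
#' @return The corrected `expression_profile`.
#' @export
subtract_baseline <- function(profile, baseline, channel = "all") {
  stopifnot_scalar_number(baseline)
  if (baseline < 0) lq_abort("lq_argument_error", "baseline must be >= 0")
  for (ch in resolve_channels(channel)) {
    profile[[ch]] <- pmax(profile[[ch]] - baseline, 0)
  }
  profile
}

#' Zero out regions without observed expression
#'
#' Sets the values in the listed index intervals to exactly zero. Overlapping
#' intervals are allowed; the operation is idempotent.
#'
#' @param profile an `expression_profile`.
#' @param intervals list of integer pairs `c(lo, hi)` (a single pair is also
#'   accepted); an empty list is the identity.
#' @param channel channel selection as in [repair_interval()].
#' @return The edited `expression_profile`.
#' @export
zero_regions <- function(profile, intervals, channel = "all") {
  if (is.numeric(intervals) && length(intervals) == 2L) intervals <- list(intervals)
  n <- nrow(profile)
  channels <- resolve_channels(channel)
  for (iv in intervals) {
    iv <- as.integer(iv)
    if (length(iv) != 2L || iv[1] < 1L || iv[2] > n || iv[1] > iv[2]) {
      lq_abort("lq_argument_error", "intervals must be index pairs inside the profile")
    }
    for (ch in channels) profile[[ch]][iv[1]:iv[2]] <- 0
  }
  profile
}

#' Symmetrize a profile about the aboral axis
#'
#' Averages the two halves of the closed-loop profile, `v'(s) = (v(s) +
#' v(L - s)) / 2`, reflecting about the decomposition start point (the aboral
#' anchor). This cancels non-symmetric influences such as uneven lighting
#' when the expression pattern itself is symmetric about the primary axis.
#' The mirrored value `v(L - s)` is obtained by circular linear interpolation
#' between segment centers.
#'
#' @param profile an `expression_profile`.
#' @param channel channel selection as in [repair_interval()].
#' @return The symmetrized `expression_profile`.
#' @export
symmetrize <- function(profile, channel = "all") {
  L <- attr(profile, "total_length")
  s <- profile$position
  for (ch in resolve_channels(channel)) {
    v <- profile[[ch]]
    mirrored <- circular_interp(s, v, L - s, L)
    profile[[ch]] <- (v + mirrored) / 2
  }
  profile
}

#' Standardize a profile to the normalized cell-layer coordinate
#'
#' Maps the arc-position axis onto the normalized coordinate running from
#' -50 to +50: the aboral pole (decomposition start) maps to both ends
#' (-50 and +50, the same physical point), the two endoderm-ectoderm
#' boundaries to `-pin` and `+pin`, and the endoderm center (midway between
#' the boundaries) to 0. The map is piecewise linear between those anchors;
#' values are resampled onto a uniform `n_out`-point grid and rescaled so the
#' maximum is 100.
#'
#' Profiles without boundary positions (e.g. blastula stages, which have no
#' endoderm yet) are mapped with the oral pole (arc position L/2) at 0 and
#' no boundary pins.
#'
#' @param profile an `expression_profile`.
#' @param boundary_positions arc positions (pixels) of the two
#'   endoderm-ectoderm boundaries; defaults to the profile's
#'   `boundary_positions` attribute. Pass `NULL` explicitly for a
#'   boundary-free (blastula) mapping when the attribute is absent.
#' @param pin normalized position the boundaries are pinned to; default 25.
#' @param n_out output grid length; default 101 so every integer position
#'   from -50 to +50 is on the grid.
#' @param channel which profile channel to standardize; default `"mean_grey"`.
#' @param allow_zero if `TRUE`, an all-zero profile yields an all-zero
#'   standard profile instead of an error.
#' @param gene,stage optional metadata labels stored on the result.
#' @return An object of class `standard_profile`: data.frame with columns
#'   `position` (-50..+50) and `value` (0..100), attributes `gene`, `stage`.
#' @export
standardize <- function(profile, boundary_positions = attr(profile, "boundary_positions"),
                        pin = 25, n_out = 101L, channel = "mean_grey",
                        allow_zero = FALSE, gene = NA_character_, stage = NA) {
  L <- attr(profile, "total_length")
  v <- profile[[channel]]
  if (max(v) <= 0) {
    if (!allow_zero) {
      lq_abort("lq_no_expression",
               "profile has no positive values; pass allow_zero = TRUE for an all-zero standard profile")
    }
  }
  if (!is.null(boundary_positions)) {
    b <- sort(as.numeric(boundary_positions)) %% L
    if (length(b) != 2L || b[1] == b[2]) {
      lq_abort("lq_argument_error", "boundary_positions must be two distinct arc positions")
    }
    knots_s <- c(0, b[1], mean(b), b[2], L)
    knots_u <- c(-50, -pin, 0, pin, 50)
  } else {
    knots_s <- c(0, L / 2, L)
    knots_u <- c(-50, 0, 50)
  }
  grid <- seq(-50, 50, length.out = n_out)
  s_at <- stats::approx(knots_u, knots_s, xout = grid)$y
  vals <- circular_interp(profile$position, v, s_at, L)
  vals[n_out] <- vals[1]  # -50 and +50 are the same aboral point
  if (max(vals) > 0) vals <- vals * (100 / max(vals))
  structure(data.frame(position = grid, value = vals),
            class = c("standard_profile", "data.frame"),
            gene = gene, stage = stage, pin = if (is.null(boundary_positions)) NULL else pin)
}

#' @export
print.standard_profile <- function(x, ...) {
  g <- attr(x, "gene"); st <- attr(x, "stage")
  lab <- if (!is.na(g)) sprintf(" %s:%s", g, format(st)) else ""
  cat(sprintf("<standard_profile>%s %d grid points, max %.1f\n",
              lab, nrow(x), max(x$value)))
  invisible(x)
}

#' Read / write standardized-profile CSV files
#'
#' Columns `position_norm` (-50..+50) and `value` (0..100); gene and stage
#' metadata in `#` header comments.
#'
#' @param path file path.
#' @return `read_standard_profile()` returns a `standard_profile`;
#'   `write_standard_profile()` returns `path` invisibly.
#' @export
write_standard_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# gene: %s", attr(profile, "gene")),
               sprintf("# stage: %s", format(attr(profile, "stage")))), con)
  df <- data.frame(position_norm = profile$position, value = profile$value)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_standard_profile
#' @param profile a `standard_profile` to serialize.
#' @export
read_standard_profile <- function(path) {
  hdr <- readLines(path, n = 5L)
  get_chr <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(NA_character_)
    trimws(sub(paste0("^# ", key, ": *"), "", ln[1]))
  }
  df <- utils::read.csv(path, comment.char = "#")
  structure(data.frame(position = df$position_norm, value = df$value),
            class = c("standard_profile", "data.frame"),
            gene = get_chr("gene"), stage = get_chr("stage"))
}

#' Apply a recorded edit script to a profile
#'
#' Edit scripts record the full Example-style processing chain (repair,
#' smooth, baseline, zeroing, symmetrization, standardization) as data, so an
#' analysis can be replayed exactly. A script is a list of steps, each a list
#' with an `op` field naming the operation plus its arguments, e.g.
#' `list(list(op = "moving_average", span = 5), list(op = "standardize"))`.
#' Scripts round-trip through YAML via [read_edit_script()] /
#' [write_edit_script()].
#'
#' @param profile an `expression_profile`.
#' @param script list of steps (possibly empty). Supported ops:
#'   `repair_interval`, `moving_average`, `subtract_baseline`, `zero_regions`,
#'   `symmetrize`, `standardize`.
#' @return The edited profile; a `standard_profile` if the script ends in a
#'   `standardize` step, otherwise an `expression_profile`.
#' @export
apply_edit_script <- function(profile, script) {
  ops <- list(repair_interval = repair_interval, moving_average = moving_average,
              subtract_baseline = subtract_baseline, zero_regions = zero_regions,
              symmetrize = symmetrize, standardize = standardize)
  for (step in script) {
    op <- step$op
    if (is.null(op) || !op %in% names(ops)) {
      lq_abort("lq_argument_error", sprintf("unknown edit op: %s", format(op)))
    }
    args <- step[setdiff(names(step), "op")]
    # [[ ]] on purpose: $ would partially match `interval` to `intervals`
    if (!is.null(args[["interval"]])) {
      args[["interval"]] <- as.integer(unlist(args[["interval"]]))
    }
    if (!is.null(args[["intervals"]])) {
      args[["intervals"]] <- lapply(args[["intervals"]],
                                    function(x) as.integer(unlist(x)))
    }
    profile <- do.call(ops[[op]], c(list(profile), args))
  }
  profile
}

#' @rdname apply_edit_script
#' @param path YAML file path.
#' @export
read_edit_script <- function(path) yaml::read_yaml(path)

#' @rdname apply_edit_script
#' @export
write_edit_script <- function(script, path) {
  yaml::write_yaml(script, path)
  invisible(path)
}
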
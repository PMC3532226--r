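# Shared fixtures, built in code. Heavy objects (rendered phantom + dense
# decomposition) are memoized so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# nodes on a circle, counterclockwise, starting at angle `start`
circle_nodes <- function(n, r, center = c(0, 0), start = 0) {
  th <- start + 2 * pi * (seq_len(n) - 1L) / n
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

ring_geometry <- function(r_out = 100, r_in = 80, n = 16, center = c(200, 200)) {
  embryo_geometry(circle_nodes(n, r_out, center), circle_nodes(n, r_in, center))
}

gaussian_bump <- function(s, at = 0.5, width = 0.08) exp(-((s - at) / width)^2)

# the standard recovery phantom: r = 100 px ring, painted Gaussian bump,
# noise sd 0.01, seed 17, plus a 100-segment decomposition
recovery_phantom <- function() {
  memo("recovery_phantom", {
    geom <- make_phantom_geometry("blastula", outer_radius = 100,
                                  thickness = 20, center = c(200, 200))
    rendered <- render_profile_image(geom, gaussian_bump, width = 400,
                                     height = 400, noise_sd = 0.01, seed = 17)
    dec <- decompose_cell_layer(geom, segment_length = 2 * pi * 100 / 100,
                                n_curve_points = 2e4)
    list(geom = geom, image = rendered$image, truth = rendered$truth, dec = dec)
  })
}

# painted profile sampled at the decomposition's segment centers
truth_at_segments <- function(truth, profile) {
  L <- attr(profile, "total_length")
  stats::approx(truth$arc_fraction * L, truth$expression,
                xout = profile$position, rule = 2)$y
}

# a small raw profile with hand-set values, for the editing-operator tests
toy_profile <- function(values, total_length = length(values)) {
  n <- length(values)
  layerquant:::new_expression_profile(
    position = (seq_len(n) - 0.5) * total_length / n,
    mean_r = values, mean_g = values, mean_b = values, mean_grey = values,
    total_length = total_length)
}

# standard_profile from a value vector on the -50..+50 grid
toy_standard <- function(values, gene = NA_character_, stage = NA) {
  structure(data.frame(position = seq(-50, 50, length.out = length(values)),
                       value = values),
            class = c("standard_profile", "data.frame"),
            gene = gene, stage = stage)
}

# planted two-group profile set: 3 near-duplicates of a bump at -20 and
# 3 of a bump at +30, fixed seed
planted_profiles <- function(seed = 7) {
  set.seed(seed)
  grid <- seq(-50, 50, length.out = 101)
  mk <- function(at, width, label_prefix, k) {
    lapply(seq_len(k), function(i) {
      v <- 100 * exp(-((grid - at) / width)^2) + stats::rnorm(101, sd = 2)
      v <- pmax(v, 0); v[101] <- v[1]
      v <- v * (100 / max(v))
      toy_standard(v, gene = sprintf("%s%d", label_prefix, i), stage = 24)
    })
  }
  c(stats::setNames(mk(-20, 8, "geneA", 3), paste0("A", 1:3)),
    stats::setNames(mk(30, 6, "geneB", 3), paste0("B", 1:3)))
}
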
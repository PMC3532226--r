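test_that("image inversion is the 255-complement and an involution", {
  arr <- array(0L, c(2, 2, 3))
  arr[1, 1, ] <- c(255L, 255L, 255L)
  arr[1, 2, ] <- c(10L, 20L, 30L)
  img <- rgb_image(arr)
  inv <- invert_image(img)
  expect_equal(as.integer(inv[1, 1, ]), c(0L, 0L, 0L))
  expect_equal(as.integer(inv[1, 2, ]), c(245L, 235L, 225L))
  expect_identical(unclass(invert_image(inv)), unclass(img))
})

test_that("interval repair follows the chosen interpolant", {
  p <- toy_profile(c(0, 0, 5, 9, 4, 0, 10, 10))
  pc <- repair_interval(p, interval = c(3, 5), method = "constant",
                        constant_value = 0.3)
  expect_equal(pc$mean_grey[3:5], rep(0.3, 3))
  expect_equal(pc$mean_grey[-(3:5)], p$mean_grey[-(3:5)])
  expect_equal(pc$position, p$position)

  # linear: flanks 0 and 10, four equally spaced interior points -> 2,4,6,8
  p2 <- toy_profile(c(5, 0, 99, 99, 99, 99, 10, 12))
  pl <- repair_interval(p2, interval = c(3, 6), method = "linear")
  expect_equal(pl$mean_grey[3:6], c(2, 4, 6, 8))

  # pchip keeps monotone context monotone across the repair
  p3 <- toy_profile(c(0, 1, 2, 3, 50, -7, 80, 6, 7, 8, 9, 10))
  pp <- repair_interval(p3, interval = c(5, 7), method = "pchip")
  expect_true(all(diff(pp$mean_grey) >= 0))

  # cubic spline repair equals the natural spline through the 4 + 4 context
  x <- toy_profile(((1:12) - 0.5)^3 / 100)
  x$mean_grey[5:7] <- -1
  xr <- repair_interval(x, channel = "mean_grey", interval = c(5, 7),
                        method = "cubic_spline")
  ctx <- c(1:4, 8:11)
  want <- stats::splinefun(x$position[ctx], x$mean_grey[ctx],
                           method = "natural")(x$position[5:7])
  expect_equal(xr$mean_grey[5:7], want, tolerance = 1e-12)

  expect_error(repair_interval(p, interval = c(1, 2), method = "linear"),
               class = "lq_context_error")
  expect_error(repair_interval(p, interval = c(3, 5), method = "constant"),
               class = "lq_argument_error")
})

test_that("circular moving average smooths with wraparound and preserves the mean", {
  p <- toy_profile(c(1, 2, 3, 4, 5))
  expect_equal(moving_average(p, 1)$mean_grey, p$mean_grey)
  sm <- moving_average(p, 3)
  expect_equal(sm$mean_grey, c(8 / 3, 2, 3, 4, 10 / 3))
  expect_equal(mean(sm$mean_grey), mean(p$mean_grey), tolerance = 1e-12)

  const <- toy_profile(rep(0.4, 9))
  expect_equal(moving_average(const, 5)$mean_grey, rep(0.4, 9))

  set.seed(8)
  r <- toy_profile(runif(21))
  expect_equal(mean(moving_average(r, 7)$mean_grey), mean(r$mean_grey),
               tolerance = 1e-12)
  expect_error(moving_average(p, 4), class = "lq_argument_error")
})

test_that("baseline subtraction lowers and clamps at zero", {
  p <- toy_profile(c(0.05, 0.10, 0.05))
  expect_equal(subtract_baseline(p, 0.05)$mean_grey, c(0, 0.05, 0))
  expect_equal(subtract_baseline(p, 0)$mean_grey, p$mean_grey)
  p2 <- toy_profile(c(0.03, 0.10, 0.2, 0.4))
  expect_equal(subtract_baseline(p2, 0.05)$mean_grey, c(0, 0.05, 0.15, 0.35))
  expect_error(subtract_baseline(p, -1), class = "lq_argument_error")
})

test_that("zeroing regions is exact and idempotent", {
  p <- toy_profile(runif(10, 0.2, 0.8))
  expect_equal(zero_regions(p, list())$mean_grey, p$mean_grey)
  all0 <- zero_regions(p, list(c(1, 10)))
  expect_equal(all0$mean_grey, rep(0, 10))
  z1 <- zero_regions(p, list(c(2, 4), c(3, 6)))
  expect_equal(zero_regions(z1, list(c(2, 4), c(3, 6)))$mean_grey, z1$mean_grey)
  expect_equal(z1$mean_grey[2:6], rep(0, 5))
  expect_equal(z1$mean_grey[c(1, 7:10)], p$mean_grey[c(1, 7:10)])
})

test_that("symmetrization averages mirror positions and is idempotent", {
  # uniform centers on a closed loop are a mirror-symmetric grid
  sym_vals <- c(1, 2, 3, 4, 4, 3, 2, 1)  # symmetric under s <-> L - s
  ps <- toy_profile(sym_vals)
  expect_equal(symmetrize(ps)$mean_grey, sym_vals, tolerance = 1e-12)

  p <- toy_profile(c(1, 5, 2, 8, 0, 3, 9, 7))
  s1 <- symmetrize(p)
  # values 1 and 3 at mirror positions +-d average to 2
  # positions 1.5 and 6.5 mirror about the loop seam (L = 8)
  pm <- toy_profile(c(0, 1, 0, 0, 0, 0, 3, 0))
  expect_equal(symmetrize(pm)$mean_grey[2], 2)
  expect_equal(symmetrize(pm)$mean_grey[7], 2)
  expect_equal(symmetrize(s1)$mean_grey, s1$mean_grey, tolerance = 1e-12)
})

test_that("standardization pins the aboral pole and the endoderm center", {
  ph <- recovery_phantom()
  prof <- measure_segments(ph$image, ph$dec)
  L <- attr(prof, "total_length")

  std <- standardize(prof, boundary_positions = NULL)
  expect_equal(max(std$value), 100)
  expect_equal(std$value[1], std$value[101])
  expect_equal(std$position, seq(-50, 50))
  # the painted bump sits at the oral pole (arc fraction 0.5) -> grid 0
  expect_equal(std$position[which.max(std$value)], 0)

  # with boundaries: the endoderm arc-center maps to grid 0 and the
  # boundaries to +-pin — a spike painted at the arc-center must peak at 0
  n <- 200
  spike <- numeric(n)
  spike[100] <- 1  # center position = (100 - 0.5) / 200 of the loop
  sp <- toy_profile(spike, total_length = 100)
  ctr_arc <- sp$position[100]
  stdb <- standardize(sp, boundary_positions = c(ctr_arc - 20, ctr_arc + 20),
                      pin = 25)
  expect_equal(stdb$position[which.max(stdb$value)], 0)
  expect_equal(max(stdb$value), 100)
  # and the boundary positions land at -25/+25, far from the spike -> zero
  expect_equal(stdb$value[stdb$position == -25], 0)

  const <- toy_profile(rep(0.25, 12))
  stdc <- standardize(const, boundary_positions = NULL)
  expect_equal(stdc$value, rep(100, 101))

  zero <- toy_profile(rep(0, 12))
  expect_error(standardize(zero, boundary_positions = NULL),
               class = "lq_no_expression")
  stdz <- standardize(zero, boundary_positions = NULL, allow_zero = TRUE)
  expect_equal(stdz$value, rep(0, 101))
})

test_that("the full editing chain recovers a painted profile despite artefacts", {
  geom <- make_phantom_geometry("blastula", outer_radius = 100, thickness = 20,
                                center = c(200, 200))
  g <- function(s) gaussian_bump(s, at = 0.5, width = 0.1)
  # dark annotation glyph overlapping the ribbon at arc fraction ~0.25,
  # plus uneven lighting and noise
  ann <- list(list(shape = "disc", x = 200, y = 110, r = 10, level = 0.15))
  ph <- render_profile_image(geom, g, width = 400, height = 400,
                             lighting_gradient = 0.04, annotations = ann,
                             noise_sd = 0.01, seed = 23)
  dec <- decompose_cell_layer(geom, segment_length = 2 * pi,
                              n_curve_points = 2e4)
  prof <- measure_segments(ph$image, dec)

  edited <- prof |>
    repair_interval(interval = c(21, 30), method = "linear") |>
    moving_average(span = 3) |>
    subtract_baseline(0.06) |>
    zero_regions(list(c(1, 30), c(71, 100))) |>
    symmetrize()
  std <- standardize(edited, boundary_positions = NULL)

  truth_std <- g((std$position + 50) / 100)
  truth_std <- truth_std * 100 / max(truth_std)
  expect_gte(cor(std$value, truth_std), 0.95)
})

test_that("edit scripts replay the operation chain from YAML", {
  p <- toy_profile(c(0.2, 0.9, 0.4, 0.8, 0.1, 0.3, 0.7, 0.2))
  script <- list(
    list(op = "moving_average", span = 3),
    list(op = "subtract_baseline", baseline = 0.1),
    list(op = "zero_regions", intervals = list(c(1, 2)))
  )
  path <- withr::local_tempfile(fileext = ".yaml")
  write_edit_script(script, path)
  replayed <- apply_edit_script(p, read_edit_script(path))
  manual <- zero_regions(subtract_baseline(moving_average(p, 3), 0.1),
                         list(c(1, 2)))
  expect_equal(replayed$mean_grey, manual$mean_grey)
  expect_error(apply_edit_script(p, list(list(op = "nope"))),
               class = "lq_argument_error")
})

test_that("standard profile CSV files round-trip", {
  std <- toy_standard(pmax(0, 100 * gaussian_bump(seq(0, 1, length.out = 101),
                                                  0.5, 0.2)),
                      gene = "nos2", stage = 24)
  path <- withr::local_tempfile(fileext = ".csv")
  write_standard_profile(std, path)
  back <- read_standard_profile(path)
  expect_equal(back$value, std$value)
  expect_equal(attr(back, "gene"), "nos2")
})
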
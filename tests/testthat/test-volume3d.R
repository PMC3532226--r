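test_that("view alignment recovers the z shift and scale by least squares", {
  lat <- view_image(matrix(0.5, 40, 30), "lateral",
                    reference_points = rbind(c(1, 5), c(1, 35)))
  # already matched -> identity map
  oral_same <- view_image(matrix(0.2, 40, 20), "oral",
                          reference_points = rbind(c(1, 5), c(1, 35)))
  al <- align_views(lat, oral_same)
  expect_equal(attr(al, "zmap")$scale, 1)
  expect_equal(attr(al, "zmap")$shift, 0)
  expect_equal(al$expression, oral_same$expression)

  # lateral z-span 10, oral z-span 20 -> scale 0.5
  lat2 <- view_image(matrix(0.5, 40, 30), "lateral",
                     reference_points = rbind(c(1, 10), c(1, 20)))
  oral2 <- view_image(matrix(0.2, 60, 20), "oral",
                      reference_points = rbind(c(1, 10), c(1, 30)))
  expect_equal(attr(align_views(lat2, oral2), "zmap")$scale, 0.5)

  # noisy reference pairs match the closed-form normal equations
  set.seed(9)
  zo <- c(4, 18, 33); zl <- 0.8 * zo + 3 + rnorm(3, sd = 0.3)
  lat3 <- view_image(matrix(0, 40, 10), "lateral",
                     reference_points = cbind(1, zl))
  oral3 <- view_image(matrix(0, 40, 10), "oral",
                      reference_points = cbind(1, zo))
  zm <- attr(align_views(lat3, oral3), "zmap")
  # oracle: solve the 2x2 normal equations directly
  A <- rbind(c(sum(zo^2), sum(zo)), c(sum(zo), 3))
  ab <- solve(A, c(sum(zo * zl), sum(zl)))
  expect_equal(zm$scale, ab[1], tolerance = 1e-12)
  expect_equal(zm$shift, ab[2], tolerance = 1e-12)

  expect_error(align_views(view_image(matrix(0, 4, 4), "lateral"), oral_same),
               class = "lq_underdetermined")
  flat <- view_image(matrix(0, 40, 20), "oral",
                     reference_points = rbind(c(1, 5), c(3, 5)))
  expect_error(align_views(lat, flat), class = "lq_degenerate")
})

test_that("two-view reconstruction is the voxelwise minimum of the views", {
  lat <- view_image(matrix(0.8, 10, 12), "lateral")
  oral <- view_image(matrix(0.5, 10, 9), "oral")
  P <- reconstruct_two_views(lat, oral)
  expect_equal(dim(P), c(12L, 9L, 10L))
  expect_true(all(abs(P - 0.5) < 1e-12))

  # a zero in one view zeroes the whole back-projected line
  oz <- matrix(0.5, 10, 9); oz[4, 6] <- 0
  Pz <- reconstruct_two_views(lat, view_image(oz, "oral"))
  expect_true(all(Pz[, 6, 4] == 0))

  expect_error(reconstruct_two_views(lat, view_image(matrix(0, 7, 9), "oral")),
               class = "lq_dimension_error")
})

test_that("two-blob reconstruction equals a brute-force triple-loop sweep", {
  set.seed(2)
  S1 <- matrix(0, 20, 15); S2 <- matrix(0, 20, 12)
  S1[3:8, 2:6] <- runif(30); S1[14:18, 9:14] <- runif(30)
  S2[3:8, 4:9] <- runif(36); S2[14:18, 2:5] <- runif(20)
  P <- reconstruct_two_views(view_image(S1, "lateral"), view_image(S2, "oral"))
  for (x in seq_len(15)) for (y in seq_len(12)) for (z in seq_len(20)) {
    expect_identical(P[x, y, z], min(S1[z, x], S2[z, y]))
  }
  # support is the intersection of the two back-projected prisms
  sup <- array(FALSE, c(15, 12, 20))
  for (z in 1:20) sup[, , z] <- outer(S1[z, ] > 0, S2[z, ] > 0, `&`)
  expect_identical(unclass(P) > 0, sup)
})

test_that("radial reconstruction weights the two arc base points by azimuth", {
  # ramp image: intensity depends only on the signed distance from the axis
  H <- 41; W <- 60
  py <- matrix(rep(1:H - 0.5, each = W), H, W, byrow = TRUE)
  img <- (py / H) * 0.9
  axis_line <- rbind(c(5, 20.5), c(55, 20.5))
  vol <- reconstruct_radial(img, axis_line, out_depth = 31)
  offs <- attr(vol, "offsets")
  cy <- which(offs == 0); X <- dim(vol)[1]

  # theta = 0 (image plane, S1 side) reproduces I(S1) exactly
  i_s1 <- function(d) (20.5 + d + 0.5 - 0.5) / H * 0.9  # bilinear = exact on a ramp
  for (d in c(3, 7, 12)) {
    jz <- which(offs == d)
    expect_equal(vol[10, cy, jz], i_s1(d), tolerance = 1e-9)
    # theta = pi (opposite in-plane side) reproduces I(S2)
    jzm <- which(offs == -d)
    expect_equal(vol[10, cy, jzm], i_s1(-d), tolerance = 1e-9)
    # theta = pi/2 (straight out of plane) averages the two base points
    jy <- which(offs == d)
    expect_equal(vol[10, jy, which(offs == 0)],
                 (i_s1(d) + i_s1(-d)) / 2, tolerance = 1e-9)
  }
  expect_error(reconstruct_radial(img, rbind(c(5, 5), c(5, 5))),
               class = "lq_argument_error")
})

test_that("mirror-symmetric images give rotationally invariant volumes", {
  H <- 120; W <- 120
  px <- matrix(rep(1:W - 0.5, H), H, W, byrow = TRUE)
  py <- matrix(rep(1:H - 0.5, each = W), H, W, byrow = TRUE)
  img <- exp(-((px - 60)^2 + (py - 60)^2) / (2 * 15^2))
  vol <- reconstruct_radial(img, rbind(c(10, 60), c(110, 60)), out_depth = 61)
  sl <- slice_volume(vol, 9)
  devs <- vapply(2:9, function(k) max(abs(sl[[k]] - sl[[1]])), numeric(1))
  expect_lt(max(devs), 0.02)
})

test_that("slices through the primary axis behave like planes of the volume", {
  set.seed(4)
  vol <- layerquant:::new_expression_volume(array(runif(30 * 21 * 21), c(30, 21, 21)))
  sl <- slice_volume(vol, 9)
  expect_equal(attr(sl, "angles_deg"), seq(0, 160, by = 20))

  # slice 1 is the central (x, z) plane exactly
  expect_equal(sl[[1]], t(vol[, 11, ]))

  # every sampled pixel equals an independent trilinear interpolation
  tri_oracle <- function(P, x, y, z) {
    d <- dim(P)
    if (x < 1 || x > d[1] || y < 1 || y > d[2] || z < 1 || z > d[3]) {
      # replicate edge handling: mix in 0 for out-of-range corners
    }
    x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
    acc <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      i <- x0 + dx; j <- y0 + dy; k <- z0 + dz
      w <- (1 - abs(x - i)) * (1 - abs(y - j)) * (1 - abs(z - k))
      v <- if (i >= 1 && i <= d[1] && j >= 1 && j <= d[2] && k >= 1 && k <= d[3])
        P[i, j, k] else 0
      acc <- acc + w * v
    }
    acc
  }
  q <- attr(sl, "offsets")
  phi <- 40 * pi / 180
  for (probe in list(c(3, 5), c(12, 17), c(20, 2))) {
    i_q <- probe[2]; i_x <- probe[1]
    want <- tri_oracle(vol, i_x, 11 + q[i_q] * sin(phi), 11 + q[i_q] * cos(phi))
    expect_equal(sl[[3]][i_q, i_x], want, tolerance = 1e-12)
  }
})

test_that("radial volumes satisfy the angular mirror property of slices", {
  H <- 100; W <- 100
  px <- matrix(rep(1:W - 0.5, H), H, W, byrow = TRUE)
  py <- matrix(rep(1:H - 0.5, each = W), H, W, byrow = TRUE)
  # asymmetric about the axis on purpose: the property must still hold
  img <- exp(-((px - 50)^2 + (py - 38)^2) / 150) +
    0.6 * exp(-((px - 60)^2 + (py - 70)^2) / 300)
  img <- img / max(img)
  vol <- reconstruct_radial(img, rbind(c(8, 50), c(92, 50)), out_depth = 51)
  sl <- slice_volume(vol, 9)
  # the mirror of the plane at angle a is the plane at 180 - a with the
  # in-slice coordinate flipped: slices 2..5 pair with 9..6
  nq <- length(attr(sl, "offsets"))
  for (k in 2:5) {
    mirrored <- sl[[11 - k]][nq:1, ]
    expect_lt(max(abs(mirrored - sl[[k]])), 0.02)
  }
})

test_that("round-tripping a ball phantom preserves its support", {
  ball <- make_phantom_volume("shell", dims = c(50, 40, 40),
                              center = c(25, 20.5, 20.5),
                              r_inner = 0, r_outer = 14, edge_width = 0)
  # forward projection along y (max along viewing rays) in image coordinates
  img <- t(apply(ball, c(1, 3), max))   # [z, x]
  rec <- reconstruct_radial(img, rbind(c(0, 20), c(50, 20)), out_depth = 40)
  a <- rec > 0.5
  b <- ball > 0.5
  expect_equal(dim(a), dim(b))
  jaccard <- sum(a & b) / sum(a | b)
  expect_gte(jaccard, 0.9)
})

test_that("landscapes standardize uniform and symmetric volumes correctly", {
  u <- make_phantom_volume("uniform", dims = c(41, 41, 41))
  geom_u <- make_phantom_geometry("blastula", outer_radius = 14, thickness = 5,
                                  center = c(20.5, 20.5), n_nodes = 12)
  land_u <- build_landscape(u, geom_u, n_slices = 5, segment_length = 3,
                            n_curve_points = 1e4)
  expect_true(all(abs(land_u - 100) < 1e-9))
  expect_equal(dim(land_u), c(5L, 101L))

  shell <- make_phantom_volume("shell", dims = c(81, 81, 81), center = c(41, 41, 41),
                               r_inner = 22, r_outer = 32, edge_width = 3)
  geom_s <- make_phantom_geometry("blastula", outer_radius = 32, thickness = 10,
                                  center = c(40.5, 40.5), n_nodes = 12)
  land_s <- build_landscape(shell, geom_s, n_slices = 9, segment_length = 5,
                            n_curve_points = 1e4)
  expect_lt(max(abs(sweep(land_s, 2, land_s[1, ]))), 2)
})

test_that("painted angular modulation is recovered across landscape rows", {
  shellm <- make_phantom_volume("shell", dims = c(61, 61, 61), center = c(31, 31, 31),
                                r_inner = 17, r_outer = 25,
                                modulation = function(phi) cos(phi)^2)
  geom <- make_phantom_geometry("blastula", outer_radius = 25, thickness = 8,
                                center = c(30.5, 30.5), n_nodes = 12)
  dec <- decompose_cell_layer(geom, 4, n_curve_points = 1e4)
  sl <- slice_volume(shellm, 9)
  amp <- vapply(sl, function(s) max(measure_segments(s, dec)$mean_grey), numeric(1))
  painted <- cos(attr(sl, "angles_deg") * pi / 180)^2
  expect_gte(cor(amp, painted), 0.95)
})

test_that("volumes round-trip through the raw + JSON sidecar format", {
  set.seed(6)
  vol <- layerquant:::new_expression_volume(array(runif(5 * 6 * 7), c(5, 6, 7)))
  path <- withr::local_tempfile(fileext = ".raw")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(dim(back), dim(vol))
  expect_equal(unclass(back), unclass(vol), tolerance = 1e-7, ignore_attr = TRUE)
})
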
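flat_curve <- function(label, z_opl, x = seq(0, 300, by = 50)) {
  fit_interface(sampling_points(0L, label, x, rep(z_opl, length(x))), label)
}

test_that("rasterization converts OPL to geometric before any distance", {
  r <- rasterize_curves(flat_curve("i1", 133), flat_curve("i2", 266),
                        n_medium = 1.33, spacing_x = 5)
  expect_equal(unique(r$P1[, "z"]), 100)
  expect_equal(unique(r$P2[, "z"]), 200)
  expect_equal(r$m, 61L)            # one i1 point per voxel column
  expect_identical(r$frame, "geometric")
  # i2 raster at least 4x denser than the voxel pitch
  expect_lte(max(diff(r$P2[, "x"])), 5 / 4)
})

test_that("rasterization needs overlapping domains", {
  i1 <- flat_curve("i1", 133, x = c(0, 50, 100))
  i2 <- flat_curve("i2", 266, x = c(200, 250, 300))
  expect_error(rasterize_curves(i1, i2, 1.33, 5), "no common support")
})

test_that("the dense i2 polyline tracks an analytic linear curve", {
  x <- seq(0, 600, by = 100)
  i2 <- fit_interface(sampling_points(0L, "i2", x, 100 + 0.5 * x), "i2")
  r <- rasterize_curves(flat_curve("i1", 0, x), i2, n_medium = 1,
                        spacing_x = 5)
  expect_lt(max(abs(r$P2[, "z"] - (100 + 0.5 * r$P2[, "x"]))), 1e-3)
})

test_that("parallel horizontal interfaces give the exact separation", {
  P1 <- cbind(x = seq(0, 500, by = 5), z = 0)
  P2 <- cbind(x = seq(0, 500, by = 1), z = 50)
  prof <- thickness_profile(P1, P2)
  expect_equal(unique(prof$t_um), 50)
})

test_that("a single i1 point finds its perpendicular foot", {
  P1 <- cbind(x = 0, z = 0)
  P2 <- cbind(x = seq(-500, 500, by = 1), z = 100)
  expect_equal(thickness_profile(P1, P2)$t_um, 100)
})

test_that("tilted interfaces match the exhaustive oracle and the vertical bound", {
  P1 <- cbind(x = seq(0, 600, by = 30), z = 0)
  P2 <- cbind(x = seq(0, 600, by = 2), z = 100 + 0.5 * seq(0, 600, by = 2))
  prof <- thickness_profile(P1, P2)
  expect_equal(prof$t_um, brute_min_dist(P1, P2), tolerance = 1e-12)
  expect_lt(max(abs(prof$t_um - brute_min_dist(P1, P2))), 1e-9)
  expect_true(all(prof$t_um <= 100 + 0.5 * P1[, "x"] + 1e-12))
})

test_that("concentric arcs recover the annulus width", {
  th1 <- seq(60, 120, by = 1) * pi / 180
  th2 <- seq(60, 120, by = 0.05) * pi / 180
  P1 <- cbind(x = 300 * cos(th1), z = 300 * sin(th1))
  P2 <- cbind(x = 360 * cos(th2), z = 360 * sin(th2))
  t <- thickness_profile(P1, P2)$t_um
  expect_lt(max(abs(t - 60)), 0.1)
})

test_that("mixed coordinate frames are rejected", {
  P1 <- cbind(x = 0:10, z = 0)
  P2 <- cbind(x = 0:10, z = 50)
  attr(P1, "frame") <- "geometric"
  attr(P2, "frame") <- "opl"
  expect_error(thickness_profile(P1, P2), "frame mismatch")
})

test_that("thickness is invariant under rigid translation and the OPL scaling law", {
  pts <- random_curve_points(11L)
  i1 <- fit_interface(pts, "i1"); i2 <- fit_interface(pts, "i2")
  r <- rasterize_curves(i1, i2, n_medium = 1.33, spacing_x = 5)
  t0 <- thickness_profile(r)$t_um
  # translation of both point sets in (x, z)
  shift <- c(37.5, -12.25)
  P1 <- sweep(r$P1, 2, shift, "+"); P2 <- sweep(r$P2, 2, shift, "+")
  expect_equal(thickness_profile(P1, P2)$t_um, t0, tolerance = 1e-12)
  # scaling all OPL z by c while scaling n by c leaves geometric t unchanged
  cc <- 1.2
  pts_s <- pts; pts_s$z_opl_um <- pts_s$z_opl_um * cc
  rs <- rasterize_curves(fit_interface(pts_s, "i1"),
                         fit_interface(pts_s, "i2"),
                         n_medium = 1.33 * cc, spacing_x = 5)
  expect_equal(thickness_profile(rs)$t_um, t0, tolerance = 1e-12)
})

test_that("the windowed minimum-distance search equals the exhaustive oracle", {
  for (seed in 1:10) {
    pts <- random_curve_points(seed)
    r <- rasterize_curves(fit_interface(pts, "i1"),
                          fit_interface(pts, "i2"),
                          n_medium = 1.33, spacing_x = 10)
    expect_lt(max(abs(thickness_profile(r)$t_um -
                        brute_min_dist(r$P1, r$P2))), 1e-9)
  }
})

test_that("profile reductions are plain means and are permutation-invariant", {
  p <- structure(list(t_um = c(50, 50, 50), m = 3L), class = "thickness_profile")
  s <- bscan_mean_thickness(p)
  expect_equal(s$t_b, 50); expect_equal(s$sd_b, 0)
  p$t_um <- c(40, 60)
  expect_equal(bscan_mean_thickness(p)$t_b, 50)
  withr::with_seed(2, {
    t <- runif(50, 80, 120)
    a <- bscan_mean_thickness(structure(list(t_um = t), class = "thickness_profile"))
    b <- bscan_mean_thickness(structure(list(t_um = sample(t)), class = "thickness_profile"))
    expect_equal(a$t_b, b$t_b)
    expect_equal(a$sd_b, b$sd_b)
  })
})

test_that("sample thickness averages the per-B-scan means", {
  s <- sample_thickness(c(100, 110, 120))
  expect_equal(s$t_urcl, 110)
  expect_equal(s$sd_urcl, sd(c(100, 110, 120)))
  one <- sample_thickness(105)
  expect_equal(one$t_urcl, 105)
  expect_equal(one$sd_urcl, 0)
  expect_true(one$single_bscan)
  # equals a one-shot mean over independently recomputed per-group means
  withr::with_seed(4, {
    groups <- split(runif(60, 60, 140), rep(1:6, each = 10))
    tb <- vapply(groups, mean, numeric(1))
    expect_equal(sample_thickness(tb)$t_urcl, mean(tb))
  })
})

test_that("dispersion sensitivity follows t * dn / (n + dn)", {
  expect_equal(dispersion_sensitivity(126, 1.33, 0), 0)
  dt <- dispersion_sensitivity(126, 1.33, 0.02)
  expect_equal(dt, 126 * 0.02 / 1.35)
  expect_lt(abs(dt - 1.87), 0.01)
  expect_lt(dt / 126, 0.02)
  # |dt| strictly increasing in |dn| at fixed t and n
  dts <- abs(dispersion_sensitivity(126, 1.33, c(-0.02, -0.01, 0.01, 0.02)))
  expect_true(all(dts > 0))
  expect_true(all(diff(abs(dispersion_sensitivity(126, 1.33,
                                                  c(0.005, 0.01, 0.02)))) > 0))
  expect_error(dispersion_sensitivity(126, 1.33, 0.5), "dn")
})
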
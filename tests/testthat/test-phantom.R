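test_that("spec validation rejects invalid fields by name", {
  bad <- test_layers(); bad$thickness_um[1] <- -1
  expect_error(phantom_spec(layers = bad), "thickness")
  bad <- test_layers(); bad$reflectivity[2] <- 1.5
  expect_error(phantom_spec(layers = bad), "reflectivit")
  expect_error(phantom_spec(n_medium = 0.9), "n_medium")
  expect_error(phantom_spec(speckle_contrast = 1.5), "speckle_contrast")
  expect_error(phantom_spec(top_depth_um = -5), "top_depth_um")
  expect_error(phantom_spec(i2_after_layer = "nope"), "i2_after_layer")
  expect_error(small_spec(shape = c(100L, 60L, 4L)), "shape")
})

test_that("noise-free phantom regions are exactly constant at their reflectivity", {
  spec <- small_spec()
  ph <- generate_phantom(spec)
  a <- ph$volume$intensity
  z_i1 <- ph$truth$z_i1_opl[1, 1]
  # medium above the tissue
  med_rows <- seq_len(floor(z_i1) - 2L)
  expect_identical(unique(as.vector(a[med_rows, , ])),
                   spec$medium_reflectivity)
  # middle of the first layer (NFL)
  r_nfl <- floor(z_i1 + spec$n_medium * spec$layers$thickness_um[1] / 2) + 1L
  expect_identical(unique(as.vector(a[r_nfl, , ])),
                   spec$layers$reflectivity[1])
})

test_that("ground-truth interface separation equals URCL thickness times n", {
  ph <- generate_phantom(small_spec())
  sep <- ph$truth$z_i2_opl - ph$truth$z_i1_opl
  expect_equal(as.vector(sep), rep(120 * 1.33, length(sep)))
  expect_equal(ph$truth$urcl_design_um, 120)
  expect_true(all(ph$truth$z_i2_opl > ph$truth$z_i1_opl))
})

test_that("speckle realizes the designed contrast and mean (moment check)", {
  spec <- slab_spec(speckle_contrast = 0.5, seed = 7L)
  ph <- generate_phantom(spec)
  v <- as.vector(ph$volume$intensity[slab_rows(spec), , ])
  expect_gte(length(v), 1e5)
  # 3 sigma Monte-Carlo bounds on the sample mean of 0.5 * Gamma(k, k)
  se_mean <- 0.5 * 0.5 / sqrt(length(v))
  expect_lt(abs(mean(v) - 0.5), 3 * se_mean)
  expect_lt(abs(sd(v) / mean(v) - 0.5), 0.01)
})

test_that("generation is bit-reproducible given the spec and seed", {
  spec <- slab_spec(speckle_contrast = 0.3, seed = 99L)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$volume$intensity, b$volume$intensity)
  expect_identical(a$truth, b$truth)
  c <- generate_phantom(slab_spec(speckle_contrast = 0.3, seed = 100L))
  expect_false(identical(a$volume$intensity, c$volume$intensity))
})

test_that("flat phantoms have horizontal truth interfaces, curved ones stay rigid", {
  flat <- generate_phantom(small_spec())
  expect_equal(diff(range(flat$truth$z_i1_opl)), 0)
  curved <- generate_phantom(small_spec(curvature_um = 30))
  # peak sagitta reached at the lateral edge columns, in OPL units
  z1 <- curved$truth$z_i1_opl[, 1]
  base <- 1.33 * 40
  expect_equal(max(z1) - base, 30 * 1.33)
  expect_equal(z1[1], z1[length(z1)])
  expect_gte(min(z1), base)
  # rigid bowing: the geometric thickness map is constant in x
  expect_equal(diff(range(curved$truth$thickness_map_um)), 0)
})

test_that("zero-amplitude distortion is the identity and empty ranges warn", {
  ph <- generate_phantom(small_spec(speckle_contrast = 0.3))
  out <- apply_distortion(ph$volume, ph$truth, y_indices = 3:4,
                          amplitude_um = 0)
  expect_identical(out$volume$intensity, ph$volume$intensity)
  expect_identical(out$truth, ph$truth)
  expect_warning(apply_distortion(ph$volume, ph$truth, integer(), 30),
                 "empty y-range")
  expect_error(apply_distortion(ph$volume, ph$truth, 50L, 30), "outside")
})

test_that("fold distortion warps truth by its amplitude only on affected planes", {
  ph <- generate_phantom(small_spec(speckle_contrast = 0.3))
  out <- apply_distortion(ph$volume, ph$truth, y_indices = c(3L, 4L),
                          amplitude_um = 30)
  dev <- abs(out$truth$z_i1_opl - ph$truth$z_i1_opl)
  expect_equal(max(dev[, 4:5]), 30)
  expect_equal(max(dev[, -(4:5)]), 0)
  # identical warp on both interfaces
  expect_equal(out$truth$z_i2_opl - ph$truth$z_i2_opl,
               out$truth$z_i1_opl - ph$truth$z_i1_opl)
  # unaffected intensity planes are bit-identical
  expect_identical(out$volume$intensity[, , -(4:5)],
                   ph$volume$intensity[, , -(4:5)])
  expect_false(identical(out$volume$intensity[, , 4],
                         ph$volume$intensity[, , 4]))
})

test_that("volume and ground-truth round-trip through TIFF/CSV", {
  ph <- generate_phantom(small_spec(speckle_contrast = 0.3,
                                    shape = c(300L, 40L, 4L)))
  dir <- withr::local_tempdir()
  write_oct_volume(ph$volume, dir)
  back <- read_oct_volume(dir)
  expect_equal(back$intensity, ph$volume$intensity, tolerance = 1e-6)
  expect_equal(back$spacing, ph$volume$spacing)
  expect_equal(back$n_medium, ph$volume$n_medium)
  expect_equal(back$meta$seed, ph$volume$meta$seed)

  write_ground_truth(ph$truth, dir)
  gt <- read.csv(file.path(dir, "ground_truth.csv"))
  expect_named(gt, c("y_index", "x_um", "z_i1_oplum", "z_i2_oplum"))
  expect_equal(nrow(gt), 40 * 4)
  expect_equal(gt$z_i1_oplum[gt$y_index == 2],
               ph$truth$z_i1_opl[, 3])
})
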
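test_that("preprocess config enforces its invariants", {
  expect_error(preprocess_config(sigma_xz = -1), "sigma")
  expect_error(preprocess_config(stretch_low = 0.5, stretch_high = 0.2),
               "low")
  expect_error(preprocess_config(n_average = 2), "odd")
  expect_error(preprocess_config(n_average = 0), "odd")
})

test_that("unit-sum kernels leave a constant volume untouched", {
  vol <- oct_volume(array(3.7, c(12, 10, 8)), c(1, 5, 4))
  out <- gaussian_filter_3d(vol, preprocess_config())
  expect_lt(max(abs(out$intensity - 3.7)), 1e-9)
  expect_equal(dim(out$intensity), dim(vol$intensity))
  expect_message(gaussian_filter_3d(vol, preprocess_config(sigma_xz = 0,
                                                           sigma_y = 0)),
                 "unchanged")
})

test_that("filter response matches an independent separable 1D convolution", {
  # unit impulse at the centre of a 9x9x9 volume, sigma (1, 1, 2)
  a <- array(0, c(9, 9, 9)); a[5, 5, 5] <- 1
  out <- gaussian_filter_3d(oct_volume(a, c(1, 1, 1)),
                            preprocess_config(sigma_xz = 1, sigma_y = 2))
  e <- numeric(9); e[5] <- 1
  rz <- conv1_sym(e, 1); rx <- conv1_sym(e, 1); ry <- conv1_sym(e, 2)
  expect_equal(out$intensity[5, 5, 5], rz[5] * rx[5] * ry[5],
               tolerance = 1e-12)
  expected <- outer(outer(rz, rx), ry)
  expect_equal(out$intensity, array(expected, c(9, 9, 9)), tolerance = 1e-12)
})

test_that("filtering reduces speckle SD in a homogeneous background patch", {
  spec <- slab_spec(speckle_contrast = 0.3, seed = 5L)
  ph <- generate_phantom(spec)
  filt <- gaussian_filter_3d(ph$volume, preprocess_config())
  rows <- slab_rows(spec, pad = 10L)[1:20]
  raw_sd <- sd(ph$volume$intensity[rows, 6:25, 13])
  filt_sd <- sd(filt$intensity[rows, 6:25, 13])
  expect_lt(filt_sd, raw_sd)
})

test_that("histogram stretching maps the quantile range onto [0, 1] monotonically", {
  v <- array(c(0, 10), c(2, 1, 1))
  out <- stretch_contrast(oct_volume(v, c(1, 1, 1)),
                          preprocess_config(stretch_low = 0,
                                            stretch_high = 1))
  expect_equal(as.vector(out$intensity), c(0, 1))

  set.seed(1)
  v <- array(rexp(500), c(20, 5, 5))
  out <- stretch_contrast(oct_volume(v, c(1, 1, 1)), preprocess_config())
  s <- as.vector(out$intensity)
  expect_true(all(s >= 0 & s <= 1))
  expect_true(all(diff(s[order(as.vector(v))]) >= 0))

  expect_error(stretch_contrast(oct_volume(array(2, c(3, 3, 3)), c(1, 1, 1))),
               "degenerate histogram")
})

test_that("quantile stretching clips the expected tail fractions on an enumerated grid", {
  v <- array(0:99, c(100, 1, 1))
  cfg <- preprocess_config(stretch_low = 0.10, stretch_high = 0.90)
  out <- as.vector(stretch_contrast(oct_volume(v, c(1, 1, 1)), cfg)$intensity)
  # brute-force oracle: the documented rule applied to the enumerated grid
  q <- quantile(0:99, c(0.10, 0.90), names = FALSE, type = 7)
  oracle <- pmin(1, pmax(0, ((0:99) - q[1]) / (q[2] - q[1])))
  expect_equal(out, oracle)
  expect_equal(mean(out == 0), 0.10)
  expect_equal(mean(out == 1), 0.10)
})

test_that("adjacent B-scan averaging takes truncated-window means", {
  a <- array(0, c(4, 3, 3))
  for (j in 1:3) a[, , j] <- j
  vol <- oct_volume(a, c(1, 5, 4))
  expect_identical(average_adjacent_bscans(vol, 1L)$intensity, a)
  out <- average_adjacent_bscans(vol, 3L)
  expect_equal(unique(as.vector(out$intensity[, , 2])), 2)
  expect_equal(unique(as.vector(out$intensity[, , 1])), 1.5)
  expect_equal(unique(as.vector(out$intensity[, , 3])), 2.5)
  expect_equal(out$spacing, vol$spacing)
  expect_error(average_adjacent_bscans(vol, 2L), "odd")
  expect_error(average_adjacent_bscans(vol, 5L), "exceeds")
})

test_that("5-plane averaging reduces background SD by about sqrt(5)", {
  spec <- slab_spec(speckle_contrast = 0.3, seed = 17L,
                    shape = c(280L, 60L, 25L))
  ph <- generate_phantom(spec)
  avg <- average_adjacent_bscans(ph$volume, 5L)
  rows <- slab_rows(spec, pad = 5L)
  raw_sd <- sd(ph$volume$intensity[rows, 11:50, 13])
  avg_sd <- sd(avg$intensity[rows, 11:50, 13])
  expect_gt(raw_sd / avg_sd, 1.8)
  expect_lt(raw_sd / avg_sd, 2.6)
})

test_that("OPL to geometric conversion divides by the refractive index", {
  expect_equal(opl_to_geometric(133.0, 1.33), 100.0)
  expect_equal(opl_to_geometric(0, 1.49), 0)
  withr::with_seed(3, {
    t <- runif(200, 0, 300)
    n <- runif(200, 1, 1.6)
    expect_equal(opl_to_geometric(t * n, n), t)
  })
  # strictly decreasing in n at fixed OPL
  g <- opl_to_geometric(150, c(1.2, 1.33, 1.49))
  expect_true(all(diff(g) < 0))
  expect_error(opl_to_geometric(100, 0.99), "n_medium")
  expect_error(opl_to_geometric(-1, 1.33), "opl")
})
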
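test_that("fields are slice-constant with the couch-interplay boundary rules", {
  g <- gaussian_blob_grid(n = 33)
  p <- delivery_parameters(couch_start_y = 8)  # travel extends past the grid
  set.seed(3)
  n <- 30
  tt <- seq(0, 187.3, length.out = n)
  disp <- rbind(0, matrix(rnorm(3 * (n - 1), sd = 2), ncol = 3))
  tr <- motion_trace(1, tt, disp)
  fld <- build_dvf(tr, p, g)

  # within-slice variance is exactly zero
  for (j in c(1, 10, 33)) {
    for (k in 1:3) {
      sl <- fld$vectors[, j, , k]
      expect_identical(max(sl) - min(sl), 0)
    }
  }
  # slices superior to couch start carry the zero vector exactly
  ys <- grid_axes(g)$y
  sup <- which(ys > p$couch_start_y)
  expect_true(all(fld$vectors[, sup, , ] == 0))
  # slices inferior to the end of travel carry exactly -m(end)
  m_end <- motion_at_travel_fraction(tr, 1)
  inf <- which(ys < p$couch_start_y - couch_travel_length(p))
  if (length(inf)) {
    for (k in 1:3)
      expect_true(all(fld$vectors[, inf, , k] == -m_end[k]))
  }
})

test_that("a mid-travel slice of a linear drift carries half the reversed end vector", {
  g <- gaussian_blob_grid(n = 33)
  # short delivery so the 18.9 mm couch travel fits inside the 32 mm grid
  p <- delivery_parameters(couch_start_y = 8, delivery_time = 47)
  tr <- linear_drift_trace(c(0, -6, 0), n = 30, duration = 47)
  fld <- build_dvf(tr, p, g)
  ys <- grid_axes(g)$y
  y_mid <- p$couch_start_y - couch_travel_length(p) / 2
  j <- which.min(abs(ys - y_mid))
  f <- slice_travel_fraction(ys[j], p)
  expect_equal(fld$vectors[1, j, 1, ], c(0, 6 * f, 0), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(fld$vectors[1, j, 1, 2], 3, tolerance = 0.2 / 3)
})

test_that("zero fields reproduce the input bit-exactly", {
  g <- gaussian_blob_grid(n = 24)
  fld <- uniform_field(g, c(0, 0, 0))
  out <- apply_dvf(g, fld)
  expect_identical(out$values, g$values)
})

test_that("integer-voxel uniform shifts translate the array exactly", {
  g <- gaussian_blob_grid(n = 24)
  fld <- uniform_field(g, c(0, 2, 0))  # +2 mm = +2 voxels superior
  out <- apply_dvf(g, fld)
  expected <- array(0, dim(g$values))
  expected[, 3:24, ] <- g$values[, 1:22, ]
  expect_lt(max(abs(out$values - expected)), 1e-13)
})

test_that("apply_dvf matches the brute-force trilinear oracle", {
  set.seed(101)
  for (case in 1:3) {
    g <- gaussian_blob_grid(n = 20, sigma = runif(1, 3, 6),
                            centre = runif(3, -2, 2))
    fld <- if (case == 1) uniform_field(g, runif(3, -3, 3)) else
      random_smooth_field(g, max_mm = 3)
    out <- apply_dvf(g, fld)
    expect_lt(max(abs(out$values - oracle_resample(g, fld))), 1e-12)
  }
})

test_that("geometry mismatches are rejected", {
  g <- gaussian_blob_grid(n = 16)
  g2 <- gaussian_blob_grid(n = 17)
  expect_error(apply_dvf(g, uniform_field(g2, c(1, 0, 0))), "geometr")
})

test_that("uniform (rigid) fields conserve total dose of an interior blob", {
  g <- gaussian_blob_grid(n = 41, sigma = 4)
  for (d in list(c(0, 6, 2), c(-3, -5, 1), c(0.5, -7.3, 0))) {
    out <- apply_dvf(g, uniform_field(g, d))
    expect_equal(sum(out$values), sum(g$values),
                 tolerance = 0.01)
  }
})

test_that("dose centroid measures symmetric and shifted blobs", {
  g <- gaussian_blob_grid(n = 41, sigma = 4)
  expect_equal(dose_centroid(g), c(0, 0, 0), tolerance = 0.5,
               ignore_attr = TRUE)
  g2 <- gaussian_blob_grid(n = 41, sigma = 4, centre = c(0, 5, 0))
  expect_equal(dose_centroid(g2)[["y"]], 5, tolerance = 0.1)
  # two equal blobs at +/-10 mm in X balance to zero
  ga <- gaussian_blob_grid(n = 41, sigma = 3, centre = c(10, 0, 0))
  gb <- gaussian_blob_grid(n = 41, sigma = 3, centre = c(-10, 0, 0))
  gsum <- dose_grid(ga$values + gb$values, spacing = ga$spacing,
                    origin = ga$origin)
  expect_equal(dose_centroid(gsum)[["x"]], 0, tolerance = 1e-6)
  expect_error(dose_centroid(dose_grid(array(0, c(4, 4, 4)))), "zero")
})

test_that("inferior+posterior drift shifts dose superiorly and anteriorly", {
  plan <- small_plan()
  p <- delivery_for(plan)
  tr <- make_motion_trace(synthetic_motion_spec(
    drift_amplitude = c(0, -6, -2), noise_sd = 0))
  fld <- build_dvf(tr, p, plan$dose)
  moved <- apply_dvf(plan$dose, fld)
  delta <- dose_centroid(moved) - dose_centroid(plan$dose)
  expect_gt(delta[["y"]], 0)  # superior
  expect_gt(delta[["z"]], 0)  # anterior
  expect_equal(delta[["x"]], 0, tolerance = 1e-6)
})
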
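test_that("RGB synthesis is an 8-bit per-channel stretch of nearest bands", {
  wl <- make_wavelength_grid(400, 700, 31)
  set.seed(3)
  cube <- hypercube(array(runif(6 * 7 * 31), c(6, 7, 31)), wl, "reflectance")
  rgb <- synthesize_rgb(cube)
  expect_true(all(rgb %in% 0:255))
  # channel 2 is the stretched nearest-550nm slice
  band <- which.min(abs(wl - 550))
  plane <- cube$values[, , band]
  manual <- as.integer(round((plane - min(plane)) /
                               (max(plane) - min(plane)) * 255))
  expect_equal(as.vector(rgb[, , 2]), manual)

  # constant cube maps to a constant image
  flat <- hypercube(array(0.4, c(4, 4, 31)), wl, "reflectance")
  expect_true(all(synthesize_rgb(flat) == 0))

  nir_only <- hypercube(array(0.4, c(4, 4, 3)),
                        make_wavelength_grid(800, 900, 3), "reflectance")
  expect_error(synthesize_rgb(nir_only), "visible")
})

test_that("otsu threshold equals the exhaustive brute-force search", {
  set.seed(21)
  for (i in 1:10) {
    v <- sample(0:255, 100, replace = TRUE)
    expect_equal(otsu_threshold(v), brute_otsu(v), tolerance = 1e-12)
  }
  # continuous data too
  v <- c(rnorm(60, 0.2, 0.03), rnorm(40, 0.7, 0.05))
  expect_equal(otsu_threshold(v), brute_otsu(v), tolerance = 1e-12)

  # perfectly bimodal: the cut separates the two groups
  thr <- otsu_threshold(c(0, 0, 0, 255, 255, 255))
  expect_gt(thr, 0)
  expect_lt(thr, 255)

  # translation equivariance
  expect_equal(otsu_threshold(v + 0.8), otsu_threshold(v) + 0.8,
               tolerance = 1e-12)

  expect_error(otsu_threshold(rep(3, 10)), "distinct")
})

test_that("foreground segmentation recovers the synthetic truth mask", {
  wl <- vnir_grid()
  for (s in c(1, 2)) {
    scene <- generate_cube(35, 64, 64, wl, seed = s)
    refl <- calibrate_reflectance(scene$cube, scene$refs)
    fg <- segment_foreground(refl)
    expect_gte(jaccard(fg$mask, scene$truth_mask), 0.95)

    # invariant to a global positive gain on the cube
    gained <- hypercube(refl$values * 3.1, wl, "reflectance")
    expect_identical(segment_foreground(gained)$mask, fg$mask)
  }

  # an all-background scene has no segmentable plant
  dark_scene <- hypercube(
    array(abs(rnorm(32 * 32 * 180, 0, 1e-3)), c(32, 32, 180)),
    wl, "reflectance")
  expect_error(segment_foreground(dark_scene), "empty")
})

test_that("morphological opening removes injected speckles", {
  wl <- vnir_grid()
  scene <- generate_cube(35, 64, 64, wl, leaf_spectrum_model(noise_sd = 0),
                         seed = 3)
  refl <- calibrate_reflectance(scene$cube, scene$refs)
  # paint isolated single-pixel foreground speckles into the background
  clean <- generate_spectrum(35, wl, leaf_spectrum_model(noise_sd = 0))
  speckles <- rbind(c(3, 3), c(3, 60), c(60, 3), c(60, 60))
  for (i in seq_len(nrow(speckles)))
    refl$values[speckles[i, 1], speckles[i, 2], ] <- clean
  fg <- segment_foreground(refl)
  expect_false(any(fg$mask[speckles]))
  expect_gte(jaccard(fg$mask, scene$truth_mask), 0.95)
})

test_that("ROI mean spectrum averages foreground pixels only", {
  wl <- make_wavelength_grid(400, 700, 4)
  vals <- array(0.7, c(3, 3, 4))
  cube <- hypercube(vals, wl, "reflectance")
  mask <- matrix(FALSE, 3, 3)
  mask[1, 1] <- mask[2, 2] <- TRUE
  expect_equal(unname(mean_roi_spectrum(cube, mask)), rep(0.7, 4))

  # two foreground pixels at 0.2 and 0.4 average to 0.3
  vals[1, 1, ] <- 0.2
  vals[2, 2, ] <- 0.4
  cube <- hypercube(vals, wl, "reflectance")
  expect_equal(unname(mean_roi_spectrum(cube, mask)), rep(0.3, 4))

  # background values are irrelevant
  vals[3, 3, ] <- 99
  cube2 <- hypercube(vals, wl, "reflectance")
  expect_equal(mean_roi_spectrum(cube2, mask), mean_roi_spectrum(cube, mask))

  expect_error(mean_roi_spectrum(cube, matrix(FALSE, 3, 3)), "no foreground")
})

test_that("ROI extraction commutes with band trimming", {
  wl <- vnir_grid(trimmed = FALSE)
  scene <- generate_cube(30, 32, 32, wl, seed = 6)
  refl <- calibrate_reflectance(scene$cube, scene$refs)
  mask <- scene$truth_mask

  extract_then_trim <- trim_to_range(mean_roi_spectrum(refl, mask), wl,
                                     437, 919)$values
  trim_then_extract <- mean_roi_spectrum(trim_to_range(refl, 437, 919), mask)
  expect_equal(extract_then_trim, trim_then_extract, tolerance = 1e-12)
})

test_that("min-max scaling spans [0,1] and is affine invariant", {
  expect_equal(minmax_scale(c(1, 3)), c(0, 1))
  x <- c(0, 0.25, 0.6, 1)
  expect_equal(minmax_scale(x), x)
  expect_equal(minmax_scale(2.5 * x + 7), minmax_scale(x))
  expect_error(minmax_scale(rep(2, 5)), "constant")

  m <- rbind(c(1, 2, 3), c(10, 30, 20))
  sm <- minmax_scale(m)
  expect_equal(unname(apply(sm, 1, range)), matrix(c(0, 1, 0, 1), 2))
  sb <- minmax_scale(m, scope = "band")
  expect_equal(unname(apply(sb, 2, range)), matrix(rep(c(0, 1), 3), 2))
})

test_that("first derivative is exact for polynomials of low degree", {
  wl <- seq(437, 919, length.out = 100)
  expect_equal(first_derivative(rep(0.5, 100), wl), rep(0, 100))
  expect_equal(first_derivative(0.002 * wl + 1, wl), rep(0.002, 100),
               tolerance = 1e-12)
  # central differences are exact for quadratics at interior points
  quad <- 1e-5 * wl^2
  d <- first_derivative(quad, wl)
  expect_equal(d[2:99], 2e-5 * wl[2:99], tolerance = 1e-9)
  expect_error(first_derivative(rep(1, 5), wl), "length")
})

test_that("augmentation draws stay inside the configured jitter bounds", {
  wl <- vnir_grid()
  x <- generate_spectrum(35, wl, leaf_spectrum_model(noise_sd = 0))
  cfg <- augmentation_config()

  # identity configuration
  id <- augmentation_config(offset_factor = 0, slope_low = 1, slope_high = 1)
  expect_equal(augment_spectrum(x, id, seed = 1), x)

  # recover (a, b) of each draw by least squares against the input
  n_draws <- 10000
  sdx <- sd(x)
  ones <- rep(1, length(x))
  A <- cbind(unname(x), ones)
  AtA_inv <- solve(crossprod(A))
  ok_a <- ok_b <- TRUE
  set.seed(123)
  for (i in seq_len(n_draws)) {
    z <- augment_spectrum(x, cfg)
    ab <- AtA_inv %*% crossprod(A, z)
    if (ab[1] < 0.95 - 1e-9 || ab[1] > 1.05 + 1e-9) ok_a <- FALSE
    if (abs(ab[2]) > 0.10 * sdx + 1e-9) ok_b <- FALSE
  }
  expect_true(ok_a)
  expect_true(ok_b)

  # determinism and extremum preservation
  expect_identical(augment_spectrum(x, cfg, seed = 42),
                   augment_spectrum(x, cfg, seed = 42))
  z <- augment_spectrum(x, cfg, seed = 7)
  expect_identical(which.max(z), which.max(x))
  expect_identical(which.min(z), which.min(x))

  expect_error(augment_spectrum(rep(1, 10), cfg), "constant")
  expect_error(augmentation_config(slope_low = 1.2, slope_high = 1.1),
               "slope")
})
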
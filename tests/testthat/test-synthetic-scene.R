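test_that("endmember generation honors the band grid, shapes and determinism", {
  lib <- generate_endmember_spectra(426, default_class_specs(), seed = 1)
  expect_equal(ncol(lib$spectra), 426)
  expect_equal(nrow(lib$spectra), 3)
  expect_true(all(diff(lib$wavelengths_nm) > 0))
  expect_true(all(lib$spectra >= 0))

  lib2 <- generate_endmember_spectra(426, default_class_specs(), seed = 1)
  expect_identical(lib$spectra, lib2$spectra)

  # vegetation classes rise from red to near-infrared; soil does not
  wl <- lib$wavelengths_nm
  red <- wl >= 620 & wl <= 690
  nir <- wl >= 760 & wl <= 900
  for (cl in c("herbaceous", "mixed_forbs")) {
    s <- lib$spectra[cl, ]
    expect_gt(mean(s[nir]) - mean(s[red]), 0.1)
  }
  soil <- lib$spectra["bare_soil", ]
  expect_lt(mean(soil[nir]) - mean(soil[red]), 0.1)
  expect_gt(stats::cor(wl, soil), 0.8)  # monotone-trending brightening
})

test_that("generated classes are pairwise separable by the direct angle formula", {
  lib <- generate_endmember_spectra(200, default_class_specs(), seed = 5,
                                    min_angle = 0.05)
  S <- lib$spectra
  for (i in 1:2) for (j in (i + 1):3) {
    oracle <- acos(sum(S[i, ] * S[j, ]) /
                     sqrt(sum(S[i, ]^2) * sum(S[j, ]^2)))
    expect_gte(oracle, 0.05)
    expect_equal(spectral_angle(S[i, ], S[j, ]), oracle, tolerance = 1e-12)
  }
})

test_that("endmember generation rejects degenerate inputs", {
  expect_error(generate_endmember_spectra(1, default_class_specs(), seed = 1),
               "n_bands")
  expect_error(
    generate_endmember_spectra(50, default_class_specs()[1], seed = 1),
    "2 classes")
  same <- list(list(name = "a", shape = "soil", low = 0.1, high = 0.3),
               list(name = "b", shape = "soil", low = 0.1, high = 0.3))
  expect_error(
    generate_endmember_spectra(50, same, seed = 1, min_angle = 0.2),
    "separable")
})

test_that("fraction fields live on the unit simplex", {
  f1 <- generate_fraction_field(6, 9, c(one = 2), seed = 3)
  expect_true(all(f1$fractions == 1))

  f <- generate_fraction_field(25, 30, c(a = 0.3, b = 0.5, c = 0.2),
                               smoothness_px = 1.5, seed = 3)
  sums <- apply(f$fractions, c(1, 2), sum)
  expect_true(all(abs(sums - 1) <= 1e-9))
  expect_true(all(f$fractions >= 0 & f$fractions <= 1))

  expect_error(generate_fraction_field(5, 5, c(1, -1), seed = 1),
               "concentration")
  expect_error(generate_fraction_field(5, 5, c(1, 1), smoothness_px = -1,
                                       seed = 1), "smoothness")
})

test_that("unsmoothed symmetric field has Dirichlet marginal means", {
  f <- generate_fraction_field(200, 200, c(1, 1, 1), smoothness_px = 0,
                               seed = 11)
  # marginal variance of a flat Dirichlet(1,1,1) component is 1/18
  se <- sqrt((1 / 18) / (200 * 200))
  for (k in 1:3)
    expect_lt(abs(mean(f$fractions[, , k]) - 1 / 3), 3 * se)
})

test_that("rendering is the exact linear mixing model at zero noise", {
  lib <- tiny_library(60)
  one_hot <- array(0, c(3, 3, 3))
  for (k in 1:3) one_hot[k, , k] <- 1
  one_hot[, 2:3, ] <- 1 / 3
  fs <- fraction_stack(one_hot, lib$class_names)
  truth <- scene_truth(fs, lib, noise_sd = 0, seed = 2)
  cube <- render_cube(truth)
  for (k in 1:3)
    expect_equal(cube$reflectance[k, 1, ], unname(lib$spectra[k, ]),
                 tolerance = 1e-14)
  # identical truth renders identically
  expect_identical(cube$reflectance, render_cube(truth)$reflectance)
})

test_that("noiseless cubes are exactly invertible by constrained unmixing", {
  scn <- tiny_scene(15, 15, 70, noise_sd = 0)
  st <- unmix_cube(scn$cube, scn$truth$library, mode = "fcls")
  expect_lt(max(abs(st$fractions - scn$truth$fractions$fractions)), 1e-6)
})

test_that("rendered noise level matches the known-truth reconstruction residual", {
  scn <- tiny_scene(30, 30, 120, noise_sd = 0.01, seed = 9)
  fs <- scn$truth$fractions
  F <- matrix(fs$fractions, 900, 3)
  recon <- F %*% scn$truth$library$spectra
  resid <- matrix(scn$cube$reflectance, 900, 120) - recon
  rmse <- mean(sqrt(rowMeans(resid^2)))
  expect_lt(abs(rmse - 0.01) / 0.01, 0.2)
})

test_that("corrupted ranges and sentinel pixels are injected as declared", {
  scn <- simulate_scene(12, 12, 100, noise_sd = 0,
                        corrupted_band_ranges = list(c(10, 19)),
                        n_bad_pixels = 5, seed = 21, smoothness_px = 0)
  cube <- scn$cube
  flat <- matrix(cube$reflectance, 144, 100)
  sent <- rowSums(abs(flat - (-0.9999)) < 1e-12) == 100
  expect_equal(sum(sent), 5)
  # corrupted bands no longer reproduce the mixing model
  F <- matrix(scn$truth$fractions$fractions, 144, 3)
  recon <- F %*% scn$truth$library$spectra
  clean <- setdiff(seq_len(100), 10:19)
  expect_gt(mean(abs((flat - recon)[!sent, 10:19])), 0.1)
  expect_lt(max(abs((flat - recon)[!sent, clean])), 1e-9)
})

test_that("reference points respect the purity threshold and error contract", {
  scn <- tiny_scene(30, 30, 60, seed = 13)
  truth <- scn$truth
  pts <- sample_reference_points(truth, n_per_class = 5, purity = 0.7,
                                 seed = 3)
  expect_equal(nrow(pts), 15)
  expect_false(any(duplicated(pts[, c("x", "y")])))
  # direct lookup oracle
  fs <- truth$fractions
  for (i in seq_len(nrow(pts))) {
    col <- floor(pts$x[i] - fs$origin_xy[1]) + 1
    row <- floor(fs$origin_xy[2] - pts$y[i]) + 1
    k <- match(pts$label[i], fs$class_names)
    expect_gte(fs$fractions[row, col, k], 0.7)
  }
  expect_error(
    sample_reference_points(truth, n_per_class = 1e5, purity = 0.7,
                            seed = 3),
    "herbaceous")
  expect_error(
    sample_reference_points(truth, n_per_class = 5, purity = 1.5, seed = 3),
    "purity")
})

test_that("one-hot truth with purity 1 puts every point on a one-hot pixel", {
  lib <- tiny_library(50)
  arr <- array(0, c(10, 10, 3))
  cls <- matrix(sample(1:3, 100, replace = TRUE), 10, 10)
  for (k in 1:3) arr[, , k] <- (cls == k) * 1
  fs <- fraction_stack(arr, lib$class_names)
  truth <- scene_truth(fs, lib, seed = 1)
  pts <- sample_reference_points(truth, n_per_class = 3, purity = 1,
                                 seed = 2)
  for (i in seq_len(nrow(pts))) {
    col <- floor(pts$x[i]) + 1
    row <- floor(-pts$y[i]) + 1
    k <- match(pts$label[i], lib$class_names)
    expect_equal(unname(fs$fractions[row, col, k]), 1)
  }
})

test_that("full scene simulation is deterministic under a fixed seed", {
  a <- simulate_scene(10, 10, 60, seed = 99, n_bad_pixels = 3,
                      corrupted_band_ranges = list(c(5, 10)))
  b <- simulate_scene(10, 10, 60, seed = 99, n_bad_pixels = 3,
                      corrupted_band_ranges = list(c(5, 10)))
  expect_identical(a$cube$reflectance, b$cube$reflectance)
  expect_identical(a$truth$fractions$fractions, b$truth$fractions$fractions)
})
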
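test_that("pure and exact-mixture pixels are solved exactly in every mode", {
  lib <- tiny_library(50)
  for (mode in c("ols", "sto", "nnls", "fcls")) {
    out <- unmix_pixel(lib$spectra[2, ], lib, mode)
    expect_equal(unname(out$fractions), c(0, 1, 0), tolerance = 1e-8)
    expect_lt(out$rmse, 1e-8)
  }
  # two-endmember 50/50 mixture
  lib2 <- endmember_library(lib$spectra[1:2, ], lib$class_names[1:2],
                            lib$wavelengths_nm)
  mix <- 0.5 * lib$spectra[1, ] + 0.5 * lib$spectra[2, ]
  out <- unmix_pixel(mix, lib2, "fcls")
  expect_equal(unname(out$fractions), c(0.5, 0.5), tolerance = 1e-9)
})

test_that("the constrained solver matches the brute-force simplex grid", {
  lib <- tiny_library(50)
  set.seed(77)
  truth <- c(0.31, 0.47, 0.22)
  px <- drop(truth %*% lib$spectra) + rnorm(50, 0, 0.01)
  fc <- unmix_pixel(px, lib, "fcls")$fractions
  bf <- brute_force_unmix(px, lib, step = 0.001)
  expect_lt(max(abs(fc - bf)), 1e-3)
})

test_that("brute force enumerates the exact simplex lattice", {
  lib <- tiny_library(30)
  lib2 <- endmember_library(lib$spectra[1:2, ], lib$class_names[1:2],
                            lib$wavelengths_nm)
  out <- brute_force_unmix(lib2$spectra[1, ], lib2, step = 0.5)
  expect_equal(attr(out, "n_evaluated"), 3)
  expect_equal(unname(out[1]), 1)
  expect_error(brute_force_unmix(rep(1, 30),
                                 endmember_library(matrix(runif(150), 5),
                                                   letters[1:5],
                                                   neon_wavelengths(30)),
                                 step = 0.5),
               "K <= 4")
})

test_that("constraints cost residual: fcls >= ols objective", {
  lib <- tiny_library(40)
  set.seed(3)
  for (i in 1:10) {
    px <- runif(40, 0, 0.6)
    expect_gte(unmix_pixel(px, lib, "fcls")$rmse + 1e-12,
               unmix_pixel(px, lib, "ols")$rmse)
  }
})

test_that("permuting library rows permutes output fractions identically", {
  lib <- tiny_library(45)
  set.seed(9)
  px <- runif(45, 0, 0.5)
  perm <- c(3, 1, 2)
  libp <- endmember_library(lib$spectra[perm, ], lib$class_names[perm],
                            lib$wavelengths_nm)
  a <- unmix_pixel(px, lib, "fcls")$fractions
  b <- unmix_pixel(px, libp, "fcls")$fractions
  expect_equal(unname(b), unname(a[perm]), tolerance = 1e-10)
})

test_that("fully constrained output lies on the unit simplex for whole scenes", {
  for (sdv in c(0, 0.01)) {
    scn <- tiny_scene(15, 15, 60, noise_sd = sdv, seed = 50 + sdv * 100)
    st <- unmix_cube(scn$cube, scn$truth$library, "fcls")
    sums <- apply(st$fractions, c(1, 2), sum)
    expect_true(all(abs(sums - 1) <= 1e-6))
    expect_true(all(st$fractions >= -1e-9))
    expect_true(all(is.finite(st$residual_rmse)) &&
                  all(st$residual_rmse >= 0))
    expect_equal(attr(st, "constraint_violations"), 0L)
  }
})

test_that("invalid pixels propagate and all-invalid cubes process nothing", {
  scn <- tiny_scene(6, 6, 30, seed = 55)
  cube <- scn$cube
  cube$pixel_valid[2, 3] <- FALSE
  st <- unmix_cube(cube, scn$truth$library, "fcls")
  expect_false(st$pixel_valid[2, 3])
  expect_true(all(is.na(st$fractions[2, 3, ])))

  cube$pixel_valid[] <- FALSE
  st0 <- unmix_cube(cube, scn$truth$library, "fcls")
  expect_equal(attr(st0, "n_pixels_processed"), 0)
  expect_true(all(is.na(st0$fractions)))
})

test_that("near-collinear endmembers fail loudly with the class pair named", {
  wl <- neon_wavelengths(30)
  base <- seq(0.1, 0.4, length.out = 30)
  lib <- endmember_library(rbind(base, base * (1 + 1e-13), base + 0.2),
                           c("dup1", "dup2", "other"), wl)
  expect_error(unmix_pixel(runif(30), lib, "fcls"), "dup1.*dup2")
})

test_that("band-axis mismatches are rejected", {
  lib <- tiny_library(40)
  expect_error(unmix_pixel(runif(39), lib), "band axis")
  scn <- tiny_scene(4, 4, 41, seed = 1)
  expect_error(unmix_cube(scn$cube, lib), "wavelength axes")
})

test_that("fractions are recovered across noise levels (seeded 30x30 scenes)", {
  tolerances <- c(`0` = 1e-6, `0.005` = 0.02, `0.02` = 0.05)
  for (sdv in c(0, 0.005, 0.02)) {
    scn <- tiny_scene(30, 30, 100, noise_sd = sdv, seed = 60)
    st <- unmix_cube(scn$cube, scn$truth$library, "fcls")
    mae <- mean(abs(st$fractions - scn$truth$fractions$fractions))
    expect_lt(mae, tolerances[[as.character(sdv)]])
  }
})

test_that("the active-set solve agrees with an independent NNLS implementation", {
  skip_if_not_installed("pracma")
  lib <- tiny_library(40)
  A <- t(lib$spectra)
  set.seed(12)
  for (i in 1:20) {
    b <- runif(40, 0, 0.6)
    ours <- unmix_pixel(b, lib, "nnls")$fractions
    ref <- pracma::lsqnonneg(A, b)$x
    expect_equal(unname(ours), ref, tolerance = 1e-7)
  }
})
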
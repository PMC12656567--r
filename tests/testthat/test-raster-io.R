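make_io_cube <- function(seed = 31) {
  scn <- tiny_scene(8, 9, 40, noise_sd = 0.01, seed = seed)
  scn$cube
}

test_that("cube round-trips through every dialect within storage quantization", {
  cube <- make_io_cube()
  for (dialect in c("envi", "geotiff", "archive")) {
    path <- file.path(withr::local_tempdir(),
                      if (dialect == "archive") "cube" else "cube.bin")
    write_cube(cube, path, dialect)
    back <- read_cube(path, dialect)
    tol <- if (dialect == "archive") 1e-12 else 0.5 / 10000 + 1e-12
    expect_lt(max(abs(back$reflectance - cube$reflectance)), tol)
    expect_equal(back$wavelengths_nm, cube$wavelengths_nm)
    expect_equal(back$pixel_size_m, cube$pixel_size_m)
    expect_equal(back$origin_xy, cube$origin_xy)
  }
})

test_that("sentinel pixels read back as invalid", {
  cube <- make_io_cube()
  cube$reflectance[3, 4, ] <- -9999 / 10000
  for (dialect in c("envi", "geotiff")) {
    path <- file.path(withr::local_tempdir(), "cube.bin")
    write_cube(cube, path, dialect)
    back <- read_cube(path, dialect)
    expect_false(back$pixel_valid[3, 4])
    expect_equal(sum(!back$pixel_valid), 1)
  }
})

test_that("an ENVI header inconsistent with its payload is an error, not a repair", {
  cube <- make_io_cube()
  path <- file.path(withr::local_tempdir(), "cube.bin")
  write_cube(cube, path, "envi")
  hdr <- readLines(paste0(path, ".hdr"))
  hdr <- sub("^bands = 40", "bands = 41", hdr)
  # keep wavelength count consistent with the inflated band count so the
  # payload-size check is what fires
  wl_i <- grep("^wavelength =", hdr)
  hdr[wl_i] <- sub("\\}$", ", 999}", hdr[wl_i])
  writeLines(hdr, paste0(path, ".hdr"))
  expect_error(read_cube(path, "envi"), "size mismatch")
  expect_error(read_cube(file.path(tempdir(), "nope.bin"), "envi"),
               "missing")
})

test_that("fraction maps round-trip with class names, order and masks", {
  scn <- tiny_scene(7, 6, 30, seed = 8)
  st <- unmix_cube(scn$cube, scn$truth$library, "fcls")
  st$pixel_valid[2, 5] <- FALSE
  path <- file.path(withr::local_tempdir(), "fr.tif")
  write_fraction_maps(st, path)
  back <- read_fraction_maps(path)
  expect_identical(back$class_names, st$class_names)
  expect_false(back$pixel_valid[2, 5])
  ok <- back$pixel_valid
  for (k in 1:3)
    expect_lt(max(abs(back$fractions[, , k][ok] - st$fractions[, , k][ok])),
              1e-6)
})

test_that("points round-trip losslessly in CSV and GeoJSON", {
  classes <- c("herbaceous", "mixed_forbs", "bare_soil")
  n <- 150
  pts <- reference_points(round(runif(n, 0, 100), 3),
                          round(runif(n, -100, 0), 3),
                          rep(classes, each = 50), classes)
  for (fmt in c("csv", "geojson")) {
    path <- file.path(withr::local_tempdir(), paste0("pts.", fmt))
    write_points(pts, path, fmt)
    back <- read_points(path, fmt, class_list = classes)
    expect_equal(nrow(back), 150)
    expect_equal(back$x, pts$x)
    expect_equal(back$y, pts$y)
    expect_identical(back$label, pts$label)
  }
})

test_that("empty point files yield empty collections; bad labels are located", {
  path <- file.path(withr::local_tempdir(), "empty.csv")
  writeLines("x,y,label", path)
  out <- read_points(path, "csv")
  expect_equal(nrow(out), 0)

  path2 <- file.path(withr::local_tempdir(), "bad.csv")
  writeLines(c("x,y,label", "1,2,herbaceous", "3,4,rock"), path2)
  expect_error(read_points(path2, "csv",
                           class_list = c("herbaceous", "bare_soil")),
               "row 2.*rock")
})

test_that("endmember libraries round-trip through wide CSV in class order", {
  lib <- tiny_library(40)
  path <- file.path(withr::local_tempdir(), "lib.csv")
  write_library(lib, path)
  expect_identical(
    strsplit(readLines(path, n = 1), ",")[[1]],
    c("wavelength_nm", lib$class_names))
  back <- read_library(path)
  expect_identical(back$class_names, lib$class_names)
  expect_equal(back$spectra, lib$spectra, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("labeled ROI polygons round-trip through GeoJSON", {
  rs <- region_set(list(rect_ring(0, 0, 5, 5), rect_ring(10, 0, 14, 3)),
                   c("herbaceous", "bare_soil"))
  path <- file.path(withr::local_tempdir(), "rois.geojson")
  write_regions(rs, path)
  back <- read_regions(path)
  expect_identical(back$labels, rs$labels)
  expect_equal(back$polygons, rs$polygons)
})
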
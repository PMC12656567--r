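# Fixture-archive dialect: a directory holding a JSON manifest and a
# gzipped little-endian float64 payload (BSQ order). Self-contained, no
# imaging libraries involved; intended for test fixtures and caching.

write_cube_archive <- function(cube, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(cube$reflectance)
  jsonlite::write_json(list(
    kind = "spectral_cube", rows = d[1], cols = d[2], bands = d[3],
    wavelengths_nm = cube$wavelengths_nm, band_valid = cube$band_valid,
    pixel_size_m = cube$pixel_size_m, origin_xy = cube$origin_xy,
    crs_label = cube$crs_label, scale_factor = cube$scale_factor,
    sentinel = cube$sentinel),
    file.path(path, "manifest.json"), auto_unbox = TRUE, digits = NA)
  con <- gzfile(file.path(path, "reflectance.bin.gz"), "wb")
  writeBin(as.numeric(cube$reflectance), con, size = 8, endian = "little")
  close(con)
  con <- gzfile(file.path(path, "pixel_valid.bin.gz"), "wb")
  writeBin(as.integer(cube$pixel_valid), con, size = 1)
  close(con)
  path
}

read_cube_archive <- function(path) {
  man_path <- file.path(path, "manifest.json")
  if (!file.exists(man_path)) stop("missing archive manifest: ", man_path)
  m <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  n <- m$rows * m$cols * m$bands
  con <- gzfile(file.path(path, "reflectance.bin.gz"), "rb")
  vals <- readBin(con, numeric(), n = n + 1, size = 8, endian = "little")
  close(con)
  if (length(vals) != n)
    stop("archive payload length (", length(vals),
         ") does not match manifest dimensions (", n, ")")
  con <- gzfile(file.path(path, "pixel_valid.bin.gz"), "rb")
  pv <- readBin(con, integer(), n = m$rows * m$cols + 1, size = 1)
  close(con)
  spectral_cube(array(vals, c(m$rows, m$cols, m$bands)), m$wavelengths_nm,
                band_valid = m$band_valid,
                pixel_valid = matrix(pv == 1, m$rows, m$cols),
                pixel_size_m = m$pixel_size_m, origin_xy = m$origin_xy,
                crs_label = m$crs_label, scale_factor = m$scale_factor,
                sentinel = m$sentinel)
}

#' Write a spectral cube
#'
#' Dialects: `"envi"` (flat BSQ binary + text header, scaled 16-bit
#' integers, sentinel written verbatim), `"geotiff"` (multi-page 16-bit
#' TIFF + JSON sidecar for wavelengths and georeferencing), or `"archive"`
#' (gzipped float64 + JSON manifest; exact, library-free).
#'
#' @param cube a [spectral_cube()].
#' @param path output path (a directory for `"archive"`).
#' @param dialect storage dialect.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, dialect = c("envi", "geotiff", "archive")) {
  stopifnot(inherits(cube, "spectral_cube"))
  dialect <- match.arg(dialect)
  switch(dialect,
         envi = write_cube_envi(cube, path),
         geotiff = write_cube_tiff(cube, path),
         archive = write_cube_archive(cube, path))
  invisible(path)
}

#' Read a spectral cube
#'
#' Counterpart of [write_cube()]. Integer storage is unscaled by the
#' declared scale factor; pixels carrying the no-data sentinel come back
#' with `pixel_valid = FALSE`. Inconsistent metadata (e.g. a header
#' declaring more bands than the payload holds) is an error, never a silent
#' repair.
#'
#' @param path input path.
#' @param dialect storage dialect; see [write_cube()].
#' @return A [spectral_cube()].
#' @export
read_cube <- function(path, dialect = c("envi", "geotiff", "archive")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         envi = read_cube_envi(path),
         geotiff = read_cube_tiff(path),
         archive = read_cube_archive(path))
}
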
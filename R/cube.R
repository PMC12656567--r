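#' Spectral reflectance cube
#'
#' In-memory container for a hyperspectral reflectance cube: a rows x cols x
#' bands array of unitless reflectance (0-1 scale after unscaling), a
#' strictly increasing wavelength axis, per-band and per-pixel validity
#' flags, and simple georeferencing (pixel size, map coordinates of the
#' north-west corner, free-text CRS tag).
#'
#' Map convention: x increases eastward, y northward; pixel (1,1) sits at the
#' north-west corner; a point on a shared cell edge belongs to the cell to
#' its south-east (half-open cell intervals).
#'
#' @param reflectance numeric array, rows x cols x bands.
#' @param wavelengths_nm numeric vector of band-center wavelengths, strictly
#'   increasing, length equal to the band dimension.
#' @param band_valid logical vector per band (default all `TRUE`).
#' @param pixel_valid logical matrix rows x cols (default all `TRUE`).
#' @param pixel_size_m ground sampling distance in metres (> 0).
#' @param origin_xy map coordinates `c(x, y)` of the outer (north-west)
#'   corner of pixel (1,1).
#' @param crs_label free-text coordinate system tag.
#' @param scale_factor integer scale used when the cube is stored as scaled
#'   integers on disk (reflectance = stored / scale_factor).
#' @param sentinel no-data sentinel in stored (integer) units.
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(reflectance, wavelengths_nm,
                          band_valid = NULL, pixel_valid = NULL,
                          pixel_size_m = 1, origin_xy = c(0, 0),
                          crs_label = "local", scale_factor = 10000,
                          sentinel = -9999) {
  if (!is.array(reflectance) || length(dim(reflectance)) != 3L)
    stop("`reflectance` must be a rows x cols x bands array")
  d <- dim(reflectance)
  if (length(wavelengths_nm) != d[3])
    stop("wavelength count (", length(wavelengths_nm),
         ") does not match band dimension (", d[3], ")")
  if (any(diff(wavelengths_nm) <= 0))
    stop("`wavelengths_nm` must be strictly increasing")
  if (is.null(band_valid)) band_valid <- rep(TRUE, d[3])
  if (is.null(pixel_valid)) pixel_valid <- matrix(TRUE, d[1], d[2])
  stopifnot(length(band_valid) == d[3],
            all(dim(pixel_valid) == d[1:2]))
  if (!is.numeric(pixel_size_m) || length(pixel_size_m) != 1 ||
      pixel_size_m <= 0)
    stop("`pixel_size_m` must be a single positive number")
  structure(list(reflectance = reflectance,
                 wavelengths_nm = as.numeric(wavelengths_nm),
                 band_valid = as.logical(band_valid),
                 pixel_valid = pixel_valid,
                 pixel_size_m = pixel_size_m,
                 origin_xy = as.numeric(origin_xy),
                 crs_label = crs_label,
                 scale_factor = scale_factor,
                 sentinel = sentinel),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$reflectance)
  cat(sprintf("<spectral_cube> %d x %d pixels, %d bands (%g-%g nm)\n",
              d[1], d[2], d[3], min(x$wavelengths_nm), max(x$wavelengths_nm)))
  cat(sprintf("  valid pixels: %d / %d; valid bands: %d / %d\n",
              sum(x$pixel_valid), d[1] * d[2], sum(x$band_valid), d[3]))
  cat(sprintf("  pixel size: %g m; origin (NW): (%g, %g); crs: %s\n",
              x$pixel_size_m, x$origin_xy[1], x$origin_xy[2], x$crs_label))
  invisible(x)
}

#' @export
dim.spectral_cube <- function(x) dim(x$reflectance)

#' Check cube invariants
#'
#' Verifies the structural invariants plus, optionally, non-negativity and
#' finiteness of all valid-pixel, valid-band reflectance values (freshly
#' simulated or freshly read cubes may carry injected defects that
#' [mask_invalid()] is responsible for flagging).
#'
#' @param cube a `spectral_cube`.
#' @param strict check the valid-data non-negativity invariant.
#' @return `TRUE` invisibly, or an error.
#' @export
check_cube <- function(cube, strict = FALSE) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (strict) {
    vals <- cube$reflectance[, , cube$band_valid, drop = FALSE]
    msk <- array(cube$pixel_valid, dim(vals))
    v <- vals[msk]
    if (any(!is.finite(v)) || any(v < 0))
      stop("valid-pixel, valid-band reflectance contains negative or ",
           "non-finite values; run mask_invalid() first")
  }
  invisible(TRUE)
}

# map coordinates of pixel centers; rows index north->south
pixel_centers <- function(cube) {
  d <- dim(cube$reflectance)
  px <- cube$pixel_size_m
  x <- cube$origin_xy[1] + (seq_len(d[2]) - 0.5) * px
  y <- cube$origin_xy[2] - (seq_len(d[1]) - 0.5) * px
  list(x = x, y = y)
}

# map point -> (row, col), half-open cells, edge point goes south-east.
# Returns NA for points outside the grid.
point_to_rowcol <- function(cube, x, y) {
  d <- dim(cube$reflectance)
  px <- cube$pixel_size_m
  col <- floor((x - cube$origin_xy[1]) / px) + 1
  row <- floor((cube$origin_xy[2] - y) / px) + 1
  bad <- col < 1 | col > d[2] | row < 1 | row > d[1]
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

# rows x cols x K array view of spectra at valid pixels:
# returns matrix n_valid_pixels x n_valid_bands plus index bookkeeping
cube_pixel_matrix <- function(cube, bands = NULL) {
  d <- dim(cube$reflectance)
  if (is.null(bands)) bands <- which(cube$band_valid)
  idx <- which(cube$pixel_valid)
  flat <- matrix(cube$reflectance, d[1] * d[2], d[3])
  list(values = flat[idx, bands, drop = FALSE], pixel_index = idx,
       bands = bands)
}
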
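# TIFF-backed raster I/O. Plain TIFF cannot carry wavelengths or map
# georeferencing, so every TIFF written here is accompanied by a JSON
# sidecar (<path>.aux.json) holding the band axis, georeferencing, and the
# value mapping. Cubes are stored as 16-bit pages under an affine integer
# mapping (stored = round(reflectance * scale) + offset) so sentinel and
# negative defects survive; fraction maps are stored as float32 pages in
# [0, 1] plus one validity page.

tiff_sidecar <- function(path) paste0(path, ".aux.json")

write_cube_tiff <- function(cube, path) {
  d <- dim(cube$reflectance)
  scale <- cube$scale_factor
  offset <- 10000                       # shifts sentinel -9999 into range
  denom <- 65535
  sc <- round(cube$reflectance * scale)
  sent_refl <- cube$sentinel / scale
  sc[abs(cube$reflectance - sent_refl) < 0.5 / scale] <- cube$sentinel
  sc[!is.finite(sc)] <- cube$sentinel
  stored <- pmax(pmin(sc + offset, denom), 0) / denom
  pages <- lapply(seq_len(d[3]), function(b) stored[, , b])
  tiff::writeTIFF(pages, path, bits.per.sample = 16, reduce = FALSE)
  jsonlite::write_json(list(
    kind = "spectral_cube", wavelengths_nm = cube$wavelengths_nm,
    scale_factor = scale, integer_offset = offset, integer_denom = denom,
    sentinel = cube$sentinel, pixel_size_m = cube$pixel_size_m,
    origin_xy = cube$origin_xy, crs_label = cube$crs_label,
    band_valid = cube$band_valid),
    tiff_sidecar(path), auto_unbox = TRUE, digits = NA)
  path
}

read_cube_tiff <- function(path) {
  side <- tiff_sidecar(path)
  if (!file.exists(path)) stop("missing TIFF file: ", path)
  if (!file.exists(side)) stop("missing TIFF sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != length(meta$wavelengths_nm))
    stop("TIFF page count (", length(pages),
         ") does not match sidecar wavelength count (",
         length(meta$wavelengths_nm), ")")
  d <- c(dim(pages[[1]]), length(pages))
  ints <- vapply(pages, function(p) round(p * meta$integer_denom),
                 matrix(0, d[1], d[2])) - meta$integer_offset
  pixel_valid <- !apply(ints == meta$sentinel, c(1, 2), any)
  spectral_cube(ints / meta$scale_factor, meta$wavelengths_nm,
                band_valid = meta$band_valid %||% rep(TRUE, d[3]),
                pixel_valid = pixel_valid,
                pixel_size_m = meta$pixel_size_m,
                origin_xy = meta$origin_xy, crs_label = meta$crs_label,
                scale_factor = meta$scale_factor, sentinel = meta$sentinel)
}

#' Write fractional abundance maps to a multi-page TIFF
#'
#' One float32 page per class (band names in the JSON sidecar, in class
#' order) plus a final validity page; invalid pixels read back as invalid.
#'
#' @param stack a [fraction_stack()].
#' @param path output path (`.tif`); a `<path>.aux.json` sidecar is written
#'   alongside.
#' @return `path`, invisibly.
#' @export
write_fraction_maps <- function(stack, path) {
  stopifnot(inherits(stack, "fraction_stack"))
  d <- dim(stack$fractions)
  pages <- lapply(seq_len(d[3]), function(k) {
    m <- stack$fractions[, , k]
    m[!is.finite(m)] <- 0
    pmin(pmax(m, 0), 1)
  })
  pages[[d[3] + 1]] <- (stack$pixel_valid) * 1
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  jsonlite::write_json(list(
    kind = "fraction_stack", class_names = stack$class_names,
    mode = stack$mode, pixel_size_m = stack$pixel_size_m,
    origin_xy = stack$origin_xy, crs_label = stack$crs_label),
    tiff_sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read fractional abundance maps written by [write_fraction_maps()]
#'
#' @param path path to the `.tif` written by [write_fraction_maps()].
#' @return A [fraction_stack()] (residual RMSE is not persisted and reads
#'   back as zero).
#' @export
read_fraction_maps <- function(path) {
  side <- tiff_sidecar(path)
  if (!file.exists(path)) stop("missing TIFF file: ", path)
  if (!file.exists(side)) stop("missing TIFF sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  K <- length(meta$class_names)
  if (length(pages) != K + 1)
    stop("TIFF page count does not match sidecar class count")
  d <- dim(pages[[1]])
  arr <- array(unlist(pages[seq_len(K)]), c(d[1], d[2], K))
  valid <- pages[[K + 1]] > 0.5
  arr_flat <- matrix(arr, d[1] * d[2], K)
  arr_flat[!c(valid), ] <- NA_real_
  fraction_stack(array(arr_flat, c(d[1], d[2], K)), meta$class_names,
                 mode = meta$mode, pixel_valid = valid,
                 pixel_size_m = meta$pixel_size_m,
                 origin_xy = meta$origin_xy, crs_label = meta$crs_label)
}
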
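#' Mask invalid reflectance
#'
#' Flags as invalid every pixel that carries the no-data sentinel or any
#' band below `min_valid` (default 0, so strictly negative reflectance masks
#' the pixel). Only currently valid bands are inspected, so noisy
#' water-absorption windows should be excluded first ([exclude_bands()]);
#' otherwise their corrupted values would condemn nearly every pixel.
#' Reflectance data are never altered; only validity flags change. The
#' count of newly masked pixels is attached as attribute
#' `"n_newly_masked"`.
#'
#' @param cube a [spectral_cube()].
#' @param sentinel no-data sentinel in stored integer units (default the
#'   cube's own, normally -9999).
#' @param min_valid minimum acceptable reflectance (unitless).
#' @return The cube with an updated `pixel_valid` mask.
#' @export
mask_invalid <- function(cube, sentinel = NULL, min_valid = 0) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (is.null(sentinel)) sentinel <- cube$sentinel
  d <- dim(cube$reflectance)
  flat <- matrix(cube$reflectance, d[1] * d[2], d[3])
  flat <- flat[, cube$band_valid, drop = FALSE]
  sentinel_refl <- sentinel / cube$scale_factor
  bad <- rowSums(flat < min_valid | !is.finite(flat) |
                   abs(flat - sentinel_refl) < 0.5 / cube$scale_factor) > 0
  badm <- matrix(bad, d[1], d[2])
  newly <- sum(badm & cube$pixel_valid)
  cube$pixel_valid <- cube$pixel_valid & !badm
  if (!any(cube$pixel_valid))
    message("mask_invalid: all pixels are now masked")
  attr(cube, "n_newly_masked") <- newly
  cube
}

#' Exclude spectral bands
#'
#' Marks the given 1-based inclusive band-index ranges invalid (masking, not
#' deletion: the wavelength axis is unchanged). Typically used to drop the
#' atmospheric water-absorption windows; see [water_band_ranges()]. The
#' remaining valid-band count is attached as attribute `"n_bands_valid"`.
#'
#' @param cube a [spectral_cube()].
#' @param ranges list of length-2 integer vectors, 1-based inclusive.
#' @return The cube with an updated `band_valid` flag.
#' @export
exclude_bands <- function(cube, ranges = water_band_ranges()) {
  stopifnot(inherits(cube, "spectral_cube"))
  nb <- dim(cube$reflectance)[3]
  bv <- cube$band_valid
  for (rg in ranges) {
    if (length(rg) != 2 || rg[1] > rg[2])
      stop("each range must be an increasing 1-based inclusive pair")
    if (rg[1] < 1 || rg[2] > nb)
      stop("band range ", rg[1], "-", rg[2], " exceeds band count ", nb)
    bv[rg[1]:rg[2]] <- FALSE
  }
  if (!any(bv)) stop("all bands excluded")
  cube$band_valid <- bv
  attr(cube, "n_bands_valid") <- sum(bv)
  cube
}

#' Clip a cube to an analysis polygon
#'
#' Flags invalid every pixel whose center falls outside the polygon
#' (pixel-center containment rule). The retained area in hectares is
#' attached as attribute `"area_ha"`.
#'
#' @param cube a [spectral_cube()].
#' @param aoi a [region_set()] with exactly one polygon, or an n x 2 vertex
#'   matrix.
#' @param crop also crop the array to the bounding window of the retained
#'   pixels.
#' @return The clipped cube.
#' @export
clip_to_polygon <- function(cube, aoi, crop = FALSE) {
  stopifnot(inherits(cube, "spectral_cube"))
  ring <- if (inherits(aoi, "region_set")) {
    if (length(aoi$polygons) != 1)
      stop("`aoi` must contain exactly one polygon")
    aoi$polygons[[1]]
  } else as.matrix(aoi)
  ring <- close_ring(ring)
  d <- dim(cube$reflectance)
  ctr <- pixel_centers(cube)
  pts <- cbind(rep(ctr$x, each = d[1]), rep(ctr$y, d[2]))
  inside <- matrix(mgcv::in.out(ring, pts), d[1], d[2])
  if (!any(inside)) stop("polygon does not overlap the cube extent")
  cube$pixel_valid <- cube$pixel_valid & inside
  if (crop) {
    rows <- range(which(apply(inside, 1, any)))
    cols <- range(which(apply(inside, 2, any)))
    cube$reflectance <- cube$reflectance[rows[1]:rows[2],
                                         cols[1]:cols[2], , drop = FALSE]
    cube$pixel_valid <- cube$pixel_valid[rows[1]:rows[2],
                                         cols[1]:cols[2], drop = FALSE]
    cube$origin_xy <- c(
      cube$origin_xy[1] + (cols[1] - 1) * cube$pixel_size_m,
      cube$origin_xy[2] - (rows[1] - 1) * cube$pixel_size_m)
  }
  attr(cube, "area_ha") <-
    sum(cube$pixel_valid) * cube$pixel_size_m^2 / 1e4
  cube
}
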
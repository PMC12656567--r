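#' Endmember library
#'
#' K class mean-reflectance spectra on a shared wavelength axis, with
#' per-class provenance (ROI id, pixel count, per-band standard deviation)
#' when built from imagery.
#'
#' @param spectra K x B numeric matrix of mean reflectance.
#' @param class_names K unique labels.
#' @param wavelengths_nm B band-center wavelengths.
#' @param band_valid optional logical vector per band.
#' @param provenance optional data frame (class, roi_id, n_pixels).
#' @param band_sd optional K x B matrix of per-band standard deviations.
#' @return An object of class `endmember_library`.
#' @export
endmember_library <- function(spectra, class_names, wavelengths_nm,
                              band_valid = NULL, provenance = NULL,
                              band_sd = NULL) {
  spectra <- as.matrix(spectra)
  K <- nrow(spectra)
  if (K < 2) stop("an endmember library needs >= 2 classes")
  if (length(class_names) != K) stop("one class name per spectrum required")
  if (anyDuplicated(class_names)) stop("class names must be unique")
  if (length(wavelengths_nm) != ncol(spectra))
    stop("wavelength count must equal the band dimension")
  if (is.null(band_valid)) band_valid <- rep(TRUE, ncol(spectra))
  v <- spectra[, band_valid, drop = FALSE]
  if (any(!is.finite(v)) || any(v < 0))
    stop("spectra must be finite and >= 0 on valid bands")
  rownames(spectra) <- class_names
  structure(list(spectra = spectra,
                 class_names = as.character(class_names),
                 wavelengths_nm = as.numeric(wavelengths_nm),
                 band_valid = as.logical(band_valid),
                 provenance = provenance, band_sd = band_sd),
            class = "endmember_library")
}

#' @export
print.endmember_library <- function(x, ...) {
  cat(sprintf("<endmember_library> %d classes x %d bands (%d valid)\n",
              nrow(x$spectra), ncol(x$spectra), sum(x$band_valid)))
  cat("  classes:", paste(x$class_names, collapse = ", "), "\n")
  invisible(x)
}

#' Mean spectrum of a region
#'
#' Per-band arithmetic mean of the reflectance of all valid pixels inside a
#' region (polygon ring in map coordinates, or a logical pixel mask), with
#' the pixel count and per-band standard deviation for the provenance
#' record. Pixels excluded by preprocessing masks never enter the mean.
#'
#' @param cube a [spectral_cube()].
#' @param region an n x 2 polygon vertex matrix (map coordinates) or a
#'   logical rows x cols mask.
#' @return list with `spectrum` (length B), `n_pixels`, `sd` (length B).
#' @export
extract_mean_spectrum <- function(cube, region) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$reflectance)
  if (is.matrix(region) && is.logical(region)) {
    inside <- region
  } else {
    ring <- close_ring(as.matrix(region))
    ctr <- pixel_centers(cube)
    pts <- cbind(rep(ctr$x, each = d[1]), rep(ctr$y, d[2]))
    inside <- matrix(mgcv::in.out(ring, pts), d[1], d[2])
  }
  sel <- inside & cube$pixel_valid
  n <- sum(sel)
  if (n < 1) stop("region contains no valid pixels")
  flat <- matrix(cube$reflectance, d[1] * d[2], d[3])
  vals <- flat[which(sel), , drop = FALSE]
  list(spectrum = colMeans(vals), n_pixels = n,
       sd = apply(vals, 2, stats::sd))
}

close_ring <- function(p) {
  if (!all(p[1, ] == p[nrow(p), ])) p <- rbind(p, p[1, ])
  p
}

#' Build an endmember library from labeled ROIs
#'
#' One mean spectrum per class label; multiple regions sharing a label are
#' pooled at the pixel level before averaging (so the result is the
#' pixel-weighted mean of the region means). Rows are ordered by
#' `class_order`.
#'
#' @param cube a [spectral_cube()].
#' @param regions a [region_set()] with >= 2 distinct labels.
#' @param class_order optional explicit class ordering (default: order of
#'   first appearance).
#' @return An [endmember_library()].
#' @export
build_library <- function(cube, regions, class_order = NULL) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(regions, "region_set"))
  labs <- regions$labels
  if (length(unique(labs)) < 2)
    stop("at least 2 distinct labels required")
  if (is.null(class_order)) class_order <- unique(labs)
  if (!setequal(class_order, unique(labs)))
    stop("`class_order` must contain exactly the region labels")
  d <- dim(cube$reflectance)
  ctr <- pixel_centers(cube)
  pts <- cbind(rep(ctr$x, each = d[1]), rep(ctr$y, d[2]))
  flat <- matrix(cube$reflectance, d[1] * d[2], d[3])
  K <- length(class_order)
  spectra <- matrix(NA_real_, K, d[3])
  band_sd <- matrix(NA_real_, K, d[3])
  prov <- data.frame(class = class_order, roi_ids = NA_character_,
                     n_pixels = NA_integer_, stringsAsFactors = FALSE)
  for (k in seq_len(K)) {
    ids <- which(labs == class_order[k])
    inside <- rep(FALSE, d[1] * d[2])
    for (i in ids)
      inside <- inside | mgcv::in.out(close_ring(regions$polygons[[i]]), pts)
    sel <- which(inside & c(cube$pixel_valid))
    if (!length(sel))
      stop("label '", class_order[k], "' has zero valid pixels")
    vals <- flat[sel, , drop = FALSE]
    spectra[k, ] <- colMeans(vals)
    band_sd[k, ] <- apply(vals, 2, stats::sd)
    prov$roi_ids[k] <- paste(ids, collapse = ",")
    prov$n_pixels[k] <- length(sel)
  }
  endmember_library(spectra, class_order, cube$wavelengths_nm,
                    band_valid = cube$band_valid, provenance = prov,
                    band_sd = band_sd)
}

#' Spectral angle between two spectra
#'
#' arccos of the normalized inner product over the shared valid bands; in
#' \[0, pi/2\] for non-negative spectra, zero for identical or proportional
#' spectra (scale invariance).
#'
#' @param s1,s2 numeric spectra of equal length.
#' @param valid optional logical band mask.
#' @return angle in radians.
#' @export
spectral_angle <- function(s1, s2, valid = NULL) {
  if (length(s1) != length(s2)) stop("spectra must share the band axis")
  if (!is.null(valid)) {
    s1 <- s1[valid]
    s2 <- s2[valid]
  }
  n1 <- sqrt(sum(s1^2))
  n2 <- sqrt(sum(s2^2))
  if (n1 == 0 || n2 == 0) stop("zero-norm spectrum")
  acos(min(1, max(-1, sum(s1 * s2) / (n1 * n2))))
}

#' Pairwise spectral-angle separability matrix
#'
#' Symmetric K x K matrix of pairwise spectral angles over the library's
#' valid bands, zero on the diagonal. A quantitative surrogate for visual
#' separability inspection; no threshold is enforced here.
#'
#' @param lib an [endmember_library()].
#' @return K x K numeric matrix (radians) with class dimnames.
#' @export
separability_matrix <- function(lib) {
  stopifnot(inherits(lib, "endmember_library"))
  K <- nrow(lib$spectra)
  out <- matrix(0, K, K, dimnames = list(lib$class_names, lib$class_names))
  for (i in seq_len(K - 1)) for (j in (i + 1):K) {
    a <- spectral_angle(lib$spectra[i, ], lib$spectra[j, ],
                        valid = lib$band_valid)
    out[i, j] <- a
    out[j, i] <- a
  }
  out
}
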
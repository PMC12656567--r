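#' Wavelength grid for NEON-like scenes
#'
#' 5 nm spacing starting at 380 nm; with the default 426 bands the grid runs
#' 380-2505 nm, emulating the band count and spacing of airborne
#' hyperspectral surface-reflectance tiles.
#'
#' @param n_bands number of bands.
#' @return numeric vector of band-center wavelengths (nm).
#' @export
neon_wavelengths <- function(n_bands = 426) {
  stopifnot(n_bands >= 1)
  380 + 5 * (seq_len(n_bands) - 1)
}

#' Default water-absorption band ranges
#'
#' 1-based inclusive band-index pairs covering the ~1400 nm and ~1900 nm
#' atmospheric water-absorption windows on the 426-band grid. Two presets
#' are shipped because both appear in practice: `"default"` (192-212,
#' 282-314) and `"alternate"` (190-211, 281-314).
#'
#' @param preset `"default"` or `"alternate"`.
#' @return list of length-2 integer vectors (1-based inclusive ranges).
#' @export
water_band_ranges <- function(preset = c("default", "alternate")) {
  preset <- match.arg(preset)
  switch(preset,
         default = list(c(192L, 212L), c(282L, 314L)),
         alternate = list(c(190L, 211L), c(281L, 314L)))
}

#' Default three-class endmember shape descriptors
#'
#' Herbaceous vegetation and mixed forbs are vegetation-shaped (chlorophyll
#' absorption in the red, sharp near-infrared rise); bare soil is a
#' monotone-trending brightening curve without a red edge. Parameters are
#' chosen to emulate typical semi-arid grassland spectra.
#'
#' @return list of class-shape descriptors for
#'   [generate_endmember_spectra()].
#' @export
default_class_specs <- function() {
  list(
    list(name = "herbaceous", shape = "vegetation", nir = 0.45,
         green_amp = 0.04, edge_nm = 715, swir_decay = 0.35),
    list(name = "mixed_forbs", shape = "vegetation", nir = 0.26,
         green_amp = 0.09, edge_nm = 700, swir_decay = 0.15),
    list(name = "bare_soil", shape = "soil", low = 0.08, high = 0.38)
  )
}

# deterministic smooth spectral shapes ---------------------------------------

veg_shape <- function(wl, nir = 0.45, green_amp = 0.05, edge_nm = 715,
                      swir_decay = 0.3) {
  base <- 0.04 +
    green_amp * exp(-((wl - 550) / 35)^2) -
    0.015 * exp(-((wl - 670) / 30)^2)
  edge <- nir / (1 + exp(-(wl - edge_nm) / 14))
  # liquid-water absorption features and gentle SWIR decline
  dips <- 1 - 0.55 * exp(-((wl - 1450) / 60)^2) -
    0.65 * exp(-((wl - 1940) / 75)^2) -
    0.25 * exp(-((wl - 1200) / 45)^2) * 0.3
  decline <- ifelse(wl > 1100, 1 - swir_decay * (wl - 1100) / 1400, 1)
  pmax(base + edge * dips * pmax(decline, 0.1), 0.001)
}

soil_shape <- function(wl, low = 0.08, high = 0.38) {
  t <- (wl - min(wl)) / (max(wl) - min(wl))
  # concave monotone brightening typical of dry silty soils
  s <- low + (high - low) * (1 - (1 - t)^1.6)
  pmax(s, 0.001)
}

smooth_perturbation <- function(wl, amplitude = 0.008, n_terms = 4) {
  t <- (wl - min(wl)) / (max(wl) - min(wl))
  coefs <- rnorm(n_terms, 0, amplitude)
  phases <- runif(n_terms, 0, 2 * pi)
  out <- numeric(length(wl))
  for (j in seq_len(n_terms))
    out <- out + coefs[j] * cos(2 * pi * j * t + phases[j])
  out
}

#' Generate a synthetic endmember library
#'
#' Produces K smooth, non-negative class spectra on a strictly increasing
#' 5 nm wavelength grid. Vegetation-shaped classes carry a reflectance rise
#' between the red and near-infrared ("red edge"); soil-shaped classes are
#' monotone-trending without it. A small seeded smooth perturbation makes
#' repeated classes distinguishable while keeping spectra realistic; the
#' same seed always reproduces bitwise-identical spectra.
#'
#' @param n_bands number of bands (>= 2).
#' @param class_specs list of descriptors as in [default_class_specs()]
#'   (>= 2 classes).
#' @param seed integer seed.
#' @param min_angle minimum acceptable pairwise spectral angle (radians)
#'   between generated classes; violation is an error.
#' @return An [endmember_library()] object.
#' @export
generate_endmember_spectra <- function(n_bands = 426,
                                       class_specs = default_class_specs(),
                                       seed = 1, min_angle = 0.05) {
  if (n_bands < 2) stop("`n_bands` must be >= 2")
  if (length(class_specs) < 2) stop("at least 2 classes required")
  if (missing(seed) || is.null(seed)) stop("`seed` must be given")
  wl <- neon_wavelengths(n_bands)
  nm <- vapply(class_specs, `[[`, "", "name")
  spectra <- withr::with_seed(seed, {
    t(vapply(class_specs, function(cs) {
      base <- switch(cs$shape,
        vegetation = veg_shape(wl,
          nir = cs$nir %||% 0.45, green_amp = cs$green_amp %||% 0.05,
          edge_nm = cs$edge_nm %||% 715,
          swir_decay = cs$swir_decay %||% 0.3),
        soil = soil_shape(wl, low = cs$low %||% 0.08,
                          high = cs$high %||% 0.38),
        stop("unknown shape: ", cs$shape))
      pmax(base + smooth_perturbation(wl), 0.001)
    }, numeric(n_bands)))
  })
  lib <- endmember_library(spectra, nm, wl)
  ang <- separability_matrix(lib)
  off <- ang[upper.tri(ang)]
  if (any(off < min_angle)) {
    ij <- which(ang == min(off) & upper.tri(ang), arr.ind = TRUE)[1, ]
    stop(sprintf("classes '%s' and '%s' are insufficiently separable ",
                 nm[ij[1]], nm[ij[2]]),
         sprintf("(angle %.4f < %.4f rad)", min(off), min_angle))
  }
  lib
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a spatially autocorrelated ground-truth fraction field
#'
#' Per-pixel draw from a Dirichlet distribution with the given concentration
#' weights (the standard normalized-gamma construction), optionally smoothed
#' per class layer with an isotropic Gaussian kernel and renormalized per
#' pixel so exact simplex membership is preserved. Smoothing produces the
#' spatially coherent cover patches seen in real fractional-abundance maps.
#'
#' @param rows,cols grid size (>= 1).
#' @param concentration K positive Dirichlet weights; names become class
#'   names.
#' @param smoothness_px Gaussian kernel sigma in pixels (>= 0; 0 = no
#'   smoothing).
#' @param seed integer seed.
#' @param class_names optional class labels (default from `concentration`
#'   names, else `class1..K`).
#' @return A [fraction_stack()] with mode `"truth"`.
#' @export
generate_fraction_field <- function(rows, cols, concentration,
                                    smoothness_px = 0, seed = 1,
                                    class_names = NULL) {
  stopifnot(rows >= 1, cols >= 1)
  if (any(concentration <= 0)) stop("concentration weights must be > 0")
  if (smoothness_px < 0) stop("`smoothness_px` must be >= 0")
  K <- length(concentration)
  if (is.null(class_names))
    class_names <- names(concentration) %||% paste0("class", seq_len(K))
  n <- rows * cols
  fr <- withr::with_seed(seed, {
    g <- matrix(rgamma(n * K, shape = rep(concentration, each = n)), n, K)
    g / rowSums(g)
  })
  arr <- array(fr, c(rows, cols, K))
  if (smoothness_px > 0 && min(rows, cols) >= 5) {
    radius <- 2 * ceiling(2 * smoothness_px) + 1
    max_odd <- min(rows, cols)
    if (max_odd %% 2 == 0) max_odd <- max_odd - 1
    radius <- min(radius, max_odd)
    for (k in seq_len(K))
      arr[, , k] <- EBImage::gblur(arr[, , k], sigma = smoothness_px,
                                   radius = radius, boundary = "replicate")
    arr[arr < 0] <- 0
    tot <- rowSums(matrix(arr, n, K))
    arr <- array(matrix(arr, n, K) / tot, c(rows, cols, K))
  }
  fraction_stack(arr, class_names, mode = "truth")
}

#' Synthetic scene ground truth
#'
#' Bundles everything needed to render and later score a synthetic scene:
#' the true fraction field, the endmember library, the noise level, the
#' seed, which band ranges are corrupted, and how many pixels carry the
#' no-data sentinel.
#'
#' @param fractions ground-truth [fraction_stack()].
#' @param library an [endmember_library()]; class count and order must match
#'   `fractions`.
#' @param noise_sd additive Gaussian noise sd, reflectance units.
#' @param seed integer seed governing rendering randomness.
#' @param corrupted_band_ranges list of 1-based inclusive band-index pairs
#'   replaced by high-variance noise when rendering.
#' @param n_bad_pixels number of pixels set to the no-data sentinel.
#' @return An object of class `scene_truth`.
#' @export
scene_truth <- function(fractions, library, noise_sd = 0, seed = 1,
                        corrupted_band_ranges = list(), n_bad_pixels = 0) {
  stopifnot(inherits(fractions, "fraction_stack"),
            inherits(library, "endmember_library"))
  if (!identical(fractions$class_names, library$class_names))
    stop("class mismatch between fractions (",
         paste(fractions$class_names, collapse = ","), ") and library (",
         paste(library$class_names, collapse = ","), ")")
  fr <- matrix(fractions$fractions, ncol = length(fractions$class_names))
  sums <- rowSums(fr)
  ok <- c(fractions$pixel_valid)
  if (any(abs(sums[ok] - 1) > 1e-9) || any(fr[ok, ] < 0))
    stop("ground-truth fractions must be >= 0 and sum to 1 within 1e-9")
  nb <- ncol(library$spectra)
  for (rg in corrupted_band_ranges)
    if (rg[1] < 1 || rg[2] > nb || rg[1] > rg[2])
      stop("corrupted band range ", rg[1], "-", rg[2],
           " outside 1..", nb)
  structure(list(fractions = fractions, library = library,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 corrupted_band_ranges = corrupted_band_ranges,
                 n_bad_pixels = as.integer(n_bad_pixels)),
            class = "scene_truth")
}

#' Render a synthetic reflectance cube from ground truth
#'
#' Forward model: each pixel's spectrum is the abundance-weighted sum of the
#' endmember spectra plus i.i.d. Gaussian noise. Bands in the truth's
#' corrupted ranges are replaced by high-variance noise (emulating
#' water-absorption windows); a seeded set of pixels is written as the
#' no-data sentinel. Identical truth always renders an identical cube.
#'
#' @param truth a [scene_truth()].
#' @return A [spectral_cube()] (all validity flags `TRUE`; defects are for
#'   [mask_invalid()] / [exclude_bands()] to find).
#' @export
render_cube <- function(truth) {
  stopifnot(inherits(truth, "scene_truth"))
  fs <- truth$fractions
  lib <- truth$library
  d <- dim(fs$fractions)
  K <- d[3]
  if (K != nrow(lib$spectra))
    stop("K mismatch between fractions and library")
  B <- ncol(lib$spectra)
  n <- d[1] * d[2]
  F <- matrix(fs$fractions, n, K)
  refl <- F %*% lib$spectra                      # n x B linear mixing
  cube <- withr::with_seed(truth$seed + 1L, {
    if (truth$noise_sd > 0)
      refl <- refl + matrix(rnorm(n * B, 0, truth$noise_sd), n, B)
    for (rg in truth$corrupted_band_ranges) {
      bands <- rg[1]:rg[2]
      refl[, bands] <- matrix(rnorm(n * length(bands), 0.3, 0.5),
                              n, length(bands))
    }
    sentinel_refl <- -9999 / 10000
    if (truth$n_bad_pixels > 0) {
      bad <- sample.int(n, truth$n_bad_pixels)
      refl[bad, ] <- sentinel_refl
    }
    spectral_cube(array(refl, c(d[1], d[2], B)), lib$wavelengths_nm,
                  pixel_size_m = fs$pixel_size_m, origin_xy = fs$origin_xy,
                  crs_label = fs$crs_label)
  })
  cube
}

#' Sample purity-thresholded reference points
#'
#' Stratified sampling of validation points: for each class, `n_per_class`
#' distinct pixels whose true fraction for that class is at least `purity`,
#' returned as pixel-center map coordinates. Emulates manually digitized
#' reference points over visually pure patches.
#'
#' @param truth a [scene_truth()].
#' @param n_per_class points per class.
#' @param purity minimum true fraction in (0, 1].
#' @param seed integer seed.
#' @return A [reference_points()] data frame.
#' @export
sample_reference_points <- function(truth, n_per_class, purity = 0.75,
                                    seed = 1) {
  stopifnot(inherits(truth, "scene_truth"))
  if (purity <= 0 || purity > 1) stop("`purity` must be in (0, 1]")
  fs <- truth$fractions
  d <- dim(fs$fractions)
  n <- d[1] * d[2]
  fr <- matrix(fs$fractions, n, d[3])
  valid <- c(fs$pixel_valid)
  used <- logical(n)
  out <- withr::with_seed(seed, {
    recs <- list()
    for (k in seq_len(d[3])) {
      qual <- which(fr[, k] >= purity & valid & !used)
      if (length(qual) < n_per_class)
        stop(sprintf(
          "class '%s': only %d qualifying pixels at purity %.2f but %d requested",
          fs$class_names[k], length(qual), purity, n_per_class))
      pick <- if (length(qual) == 1) qual else sample(qual, n_per_class)
      used[pick] <- TRUE
      rc <- arrayInd(pick, d[1:2])
      px <- fs$pixel_size_m
      recs[[k]] <- data.frame(
        x = fs$origin_xy[1] + (rc[, 2] - 0.5) * px,
        y = fs$origin_xy[2] - (rc[, 1] - 0.5) * px,
        label = fs$class_names[k], stringsAsFactors = FALSE)
    }
    do.call(rbind, recs)
  })
  reference_points(out$x, out$y, out$label, class_list = fs$class_names)
}

#' Simulate a complete synthetic scene
#'
#' Convenience wrapper: generate an endmember library and ground-truth
#' fraction field, bundle them as scene truth, and render the reflectance
#' cube. All randomness flows from `seed`.
#'
#' @param rows,cols grid size.
#' @param n_bands number of spectral bands.
#' @param class_specs endmember shape descriptors.
#' @param concentration Dirichlet concentration (length K, matching
#'   `class_specs`).
#' @param smoothness_px Gaussian smoothing sigma for the fraction field.
#' @param noise_sd additive noise sd, reflectance units.
#' @param corrupted_band_ranges corrupted band ranges (default: the water
#'   windows, so preprocessing is exercised).
#' @param n_bad_pixels pixels written as the no-data sentinel.
#' @param seed integer seed.
#' @return list with elements `truth` ([scene_truth()]) and `cube`
#'   ([spectral_cube()]).
#' @export
simulate_scene <- function(rows = 100, cols = 100, n_bands = 426,
                           class_specs = default_class_specs(),
                           concentration = c(0.12, 0.15, 0.10),
                           smoothness_px = 0.5, noise_sd = 0.005,
                           corrupted_band_ranges = water_band_ranges(),
                           n_bad_pixels = 0, seed = 1) {
  lib <- generate_endmember_spectra(n_bands, class_specs, seed = seed)
  nm <- vapply(class_specs, `[[`, "", "name")
  fld <- generate_fraction_field(rows, cols, setNames(concentration, nm),
                                 smoothness_px = smoothness_px,
                                 seed = seed + 1L)
  truth <- scene_truth(fld, lib, noise_sd = noise_sd, seed = seed,
                       corrupted_band_ranges = corrupted_band_ranges,
                       n_bad_pixels = n_bad_pixels)
  list(truth = truth, cube = render_cube(truth))
}
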
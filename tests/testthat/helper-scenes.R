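# small in-code fixtures shared across the suite

tiny_library <- function(n_bands = 80, seed = 42) {
  generate_endmember_spectra(n_bands, default_class_specs(), seed = seed)
}

# small noiseless or noisy scene with no injected defects
tiny_scene <- function(rows = 20, cols = 20, n_bands = 80, noise_sd = 0,
                       seed = 7, smoothness_px = 0.5, ...) {
  simulate_scene(rows, cols, n_bands, noise_sd = noise_sd,
                 corrupted_band_ranges = list(), n_bad_pixels = 0,
                 smoothness_px = smoothness_px, seed = seed, ...)
}

# cube whose every pixel has the same given spectrum
constant_cube <- function(spectrum, rows = 4, cols = 4) {
  arr <- array(rep(spectrum, each = rows * cols),
               c(rows, cols, length(spectrum)))
  spectral_cube(arr, neon_wavelengths(length(spectrum)))
}

# axis-aligned rectangle ring (x0, y0) lower-left .. (x1, y1) upper-right
rect_ring <- function(x0, y0, x1, y1) {
  rbind(c(x0, y0), c(x1, y0), c(x1, y1), c(x0, y1), c(x0, y0))
}
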
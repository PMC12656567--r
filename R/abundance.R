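#' Histogram summary of a fraction map
#'
#' Pixel counts over `n_bins` equal-width bins spanning \[0, 1\]:
#' left-closed, right-open bins with the last bin closed at 1 (so a value
#' exactly at an interior edge joins the upper bin). Invalid (NA) pixels
#' are excluded. Both medians are reported under unambiguous names: the
#' median of the pixel fractions and the median of the per-bin tallies —
#' summary tables in the field sometimes conflate the two.
#'
#' @param map numeric fraction matrix (NA = invalid), values in \[0, 1\].
#' @param n_bins number of bins (default 10).
#' @return An object of class `histogram_summary`: list with `bin_edges`
#'   (n_bins + 1 values from 0 to 1), `counts`, `n_valid`, `mean`, `sd`,
#'   `median_fraction`, `median_of_counts`.
#' @export
histogram_counts <- function(map, n_bins = 10) {
  if (n_bins < 1) stop("`n_bins` must be >= 1")
  v <- map[is.finite(map)]
  if (any(v < 0 | v > 1)) stop("fractions outside [0, 1]")
  edges <- seq(0, 1, length.out = n_bins + 1)
  idx <- pmin(findInterval(v, edges), n_bins)   # last bin closed at 1
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(bin_edges = edges, counts = counts,
                 n_valid = length(v),
                 mean = if (length(v)) mean(v) else NA_real_,
                 sd = if (length(v) > 1) stats::sd(v) else NA_real_,
                 median_fraction = if (length(v)) stats::median(v)
                                   else NA_real_,
                 median_of_counts = stats::median(counts)),
            class = "histogram_summary")
}

#' Median of histogram bin tallies
#'
#' Median of the per-bin pixel counts (not of the pixel fractions). For an
#' even bin count the two central tallies are averaged; when integer output
#' is requested a half-integer is rounded half away from zero.
#'
#' @param hist a `histogram_summary` or a bare vector of counts.
#' @param integer round to integer (half away from zero)?
#' @return numeric (or integer-valued) median.
#' @export
median_of_counts <- function(hist, integer = FALSE) {
  counts <- if (inherits(hist, "histogram_summary")) hist$counts else hist
  if (!length(counts)) stop("need >= 1 bin")
  m <- stats::median(counts)
  if (integer) m <- sign(m) * floor(abs(m) + 0.5)
  m
}

#' Categorize a fraction map into low / medium / high cover
#'
#' Three lower-inclusive intervals: low \[0, breaks1), medium
#' \[breaks1, breaks2), high \[breaks2, 1\].
#'
#' @param map numeric fraction matrix (NA = invalid).
#' @param breaks two increasing values inside (0, 1); default
#'   `c(0.3, 0.6)`.
#' @param labels three category names.
#' @return list with `categories` (character matrix) and `counts` (named
#'   vector).
#' @export
categorize_abundance <- function(map, breaks = c(0.3, 0.6),
                                 labels = c("low", "medium", "high")) {
  if (length(breaks) != 2 || diff(breaks) <= 0 ||
      breaks[1] <= 0 || breaks[2] >= 1)
    stop("`breaks` must be two increasing values inside (0, 1)")
  idx <- findInterval(map, breaks) + 1L
  cats <- matrix(labels[idx], nrow(map), ncol(map))
  cats[!is.finite(map)] <- NA_character_
  counts <- setNames(integer(3), labels)
  tab <- table(factor(cats[is.finite(map)], levels = labels))
  counts[names(tab)] <- as.integer(tab)
  list(categories = cats, counts = counts)
}

#' Abundance-weighted area in hectares
#'
#' Sum of pixel fraction times pixel area over valid pixels, in hectares.
#' For a sum-to-one fraction stack the weighted areas of all classes add up
#' exactly to the valid-pixel footprint area (a conservation law worth
#' testing on every scene).
#'
#' @param map numeric fraction matrix (NA = invalid).
#' @param pixel_area_m2 area of one pixel in square metres (> 0).
#' @return hectares.
#' @export
weighted_area_ha <- function(map, pixel_area_m2 = 1) {
  if (pixel_area_m2 <= 0) stop("`pixel_area_m2` must be > 0")
  sum(map[is.finite(map)]) * pixel_area_m2 / 1e4
}

#' Histogram summaries for every class of a stack
#'
#' @param stack a [fraction_stack()].
#' @param n_bins bins per histogram.
#' @return named list of `histogram_summary`, one per class.
#' @export
stack_histograms <- function(stack, n_bins = 10) {
  stopifnot(inherits(stack, "fraction_stack"))
  setNames(lapply(stack$class_names, function(cl) {
    m <- fraction_map(stack, cl)
    m[m < 0] <- 0                       # guard constrained-mode dust
    m[m > 1] <- 1
    histogram_counts(m, n_bins)
  }), stack$class_names)
}
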
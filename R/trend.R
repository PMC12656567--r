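#' Per-pixel change slope between two acquisition years
#'
#' For two time points the per-pixel least-squares trend reduces exactly to
#' the difference quotient `(f2 - f1) / (t2 - t1)`, in fraction units per
#' year. A pixel is valid only where both inputs are valid and finite.
#'
#' @param f1,f2 fraction maps: numeric matrices (NA = invalid) or
#'   [fraction_stack()]s together with `class_name`.
#' @param t1,t2 calendar years, `t2 > t1`.
#' @param class_name class to extract when stacks are supplied.
#' @return An object of class `trend_raster`: list with `slope` matrix
#'   (NA where invalid), `valid`, `year_pair`, `class_name`.
#' @export
slope_map <- function(f1, f2, t1, t2, class_name = NULL) {
  if (t2 <= t1) stop("`t2` must be greater than `t1`")
  geo <- NULL
  if (inherits(f1, "fraction_stack")) {
    geo <- list(px = f1$pixel_size_m, origin = f1$origin_xy)
    geo2 <- list(px = f2$pixel_size_m, origin = f2$origin_xy)
    if (!identical(geo, geo2))
      stop("fraction maps are not co-registered (georeferencing differs)")
    if (is.null(class_name))
      stop("`class_name` required when passing fraction stacks")
    f1 <- fraction_map(f1, class_name)
    f2 <- fraction_map(f2, class_name)
  }
  if (!all(dim(f1) == dim(f2)))
    stop("fraction maps are not co-registered (shape differs)")
  valid <- is.finite(f1) & is.finite(f2)
  slope <- (f2 - f1) / (t2 - t1)
  slope[!valid] <- NA_real_
  structure(list(slope = slope, valid = valid,
                 year_pair = c(t1, t2), class_name = class_name,
                 geo = geo),
            class = "trend_raster")
}

#' Default trend slope breaks
#'
#' Slope thresholds (fraction units per year) separating decline, moderate
#' decline, stability, and increase over a four-year span; the implied
#' extreme slopes are then +/- 0.25 per year.
#'
#' @return numeric vector of three increasing breaks.
#' @export
default_trend_breaks <- function() c(-0.085, -0.036, 0.037)

#' Classify a trend raster into categories
#'
#' Half-open, lower-inclusive interval assignment covering the full real
#' line: `length(breaks) + 1` categories; a slope exactly at a break joins
#' the upper interval.
#'
#' @param trend a `trend_raster` from [slope_map()].
#' @param breaks strictly increasing slope thresholds.
#' @param labels category names, `length(breaks) + 1` of them.
#' @return list with `categories` (character matrix, NA where invalid) and
#'   `counts` (named integer vector over all categories).
#' @export
classify_trend <- function(trend, breaks = default_trend_breaks(),
                           labels = c("decline", "moderate_decline",
                                      "stable", "increase")) {
  stopifnot(inherits(trend, "trend_raster"))
  if (any(diff(breaks) <= 0)) stop("`breaks` must be strictly increasing")
  if (length(labels) != length(breaks) + 1)
    stop("need length(breaks) + 1 labels")
  idx <- findInterval(trend$slope, breaks) + 1L   # lower-inclusive
  cats <- matrix(labels[idx], nrow(trend$slope), ncol(trend$slope))
  cats[!trend$valid] <- NA_character_
  counts <- setNames(integer(length(labels)), labels)
  tab <- table(factor(cats[trend$valid], levels = labels))
  counts[names(tab)] <- as.integer(tab)
  list(categories = cats, counts = counts)
}

#' Mean and standard deviation of trend slopes
#'
#' @param trend a `trend_raster`.
#' @param sd_type `"sample"` (n - 1 denominator, default) or
#'   `"population"`.
#' @return list with `mean`, `sd`, `n`.
#' @export
trend_summary <- function(trend, sd_type = c("sample", "population")) {
  stopifnot(inherits(trend, "trend_raster"))
  sd_type <- match.arg(sd_type)
  v <- trend$slope[trend$valid]
  if (!length(v)) stop("no valid pixels")
  s <- if (length(v) > 1) stats::sd(v) else 0
  if (sd_type == "population" && length(v) > 1)
    s <- s * sqrt((length(v) - 1) / length(v))
  list(mean = mean(v), sd = s, n = length(v))
}
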
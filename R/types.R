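#' Fractional abundance stack
#'
#' Per-class fractional abundance maps plus per-pixel reconstruction RMSE.
#' Fractions are the weights of the linear mixing model; in fully
#' constrained mode every valid pixel lies on the unit simplex.
#'
#' @param fractions numeric array rows x cols x K.
#' @param class_names K class labels.
#' @param residual_rmse rows x cols matrix of per-pixel reconstruction RMSE
#'   in reflectance units (zeros for ground-truth stacks).
#' @param mode one of `"ols"`, `"sto"` (sum-to-one), `"nnls"`
#'   (non-negative), `"fcls"` (fully constrained), or `"truth"`.
#' @param pixel_valid logical rows x cols mask.
#' @param pixel_size_m,origin_xy,crs_label georeferencing, as in
#'   [spectral_cube()].
#' @return An object of class `fraction_stack`.
#' @export
fraction_stack <- function(fractions, class_names, residual_rmse = NULL,
                           mode = "truth", pixel_valid = NULL,
                           pixel_size_m = 1, origin_xy = c(0, 0),
                           crs_label = "local") {
  if (!is.array(fractions) || length(dim(fractions)) != 3L)
    stop("`fractions` must be a rows x cols x K array")
  d <- dim(fractions)
  if (length(class_names) != d[3])
    stop("`class_names` length must equal the class dimension")
  if (anyDuplicated(class_names)) stop("class names must be unique")
  if (is.null(residual_rmse)) residual_rmse <- matrix(0, d[1], d[2])
  if (is.null(pixel_valid)) pixel_valid <- matrix(TRUE, d[1], d[2])
  dimnames(fractions) <- list(NULL, NULL, class_names)
  structure(list(fractions = fractions,
                 class_names = as.character(class_names),
                 residual_rmse = residual_rmse,
                 mode = mode,
                 pixel_valid = pixel_valid,
                 pixel_size_m = pixel_size_m,
                 origin_xy = as.numeric(origin_xy),
                 crs_label = crs_label),
            class = "fraction_stack")
}

#' @export
print.fraction_stack <- function(x, ...) {
  d <- dim(x$fractions)
  cat(sprintf("<fraction_stack> %d x %d pixels, %d classes [%s], mode=%s\n",
              d[1], d[2], d[3], paste(x$class_names, collapse = ", "),
              x$mode))
  cat(sprintf("  valid pixels: %d / %d; mean RMSE: %.5f\n",
              sum(x$pixel_valid), d[1] * d[2],
              mean(x$residual_rmse[x$pixel_valid])))
  invisible(x)
}

#' Extract one class's fraction map
#'
#' @param stack a `fraction_stack`.
#' @param class_name class label.
#' @param na_invalid replace invalid pixels with `NA`.
#' @return numeric matrix rows x cols.
#' @export
fraction_map <- function(stack, class_name, na_invalid = TRUE) {
  stopifnot(inherits(stack, "fraction_stack"))
  k <- match(class_name, stack$class_names)
  if (is.na(k)) stop("unknown class: ", class_name)
  m <- stack$fractions[, , k]
  if (na_invalid) m[!stack$pixel_valid] <- NA_real_
  m
}

#' Labeled polygon regions
#'
#' A set of closed polygon rings in map coordinates, one class label per
#' polygon (several polygons may share a label, e.g. multiple ROIs of the
#' same land-cover class).
#'
#' @param polygons list of n x 2 numeric matrices (x, y vertices). Rings are
#'   closed implicitly; a duplicated final vertex is accepted.
#' @param labels character vector, one label per polygon.
#' @return An object of class `region_set`.
#' @export
region_set <- function(polygons, labels) {
  if (length(polygons) != length(labels))
    stop("one label per polygon required")
  if (any(!nzchar(labels))) stop("labels must be non-empty")
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2) stop("polygon vertices must be n x 2 (x, y)")
    # drop explicit closing vertex; closure is implicit
    if (nrow(p) > 1 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), ]
    if (nrow(unique(p)) < 3) stop("each ring needs >= 3 distinct vertices")
    unname(p)
  })
  structure(list(polygons = polygons, labels = as.character(labels)),
            class = "region_set")
}

#' Reference points
#'
#' Class-labeled validation points in map coordinates.
#'
#' @param x,y numeric map coordinates.
#' @param label class label per point.
#' @param class_list optional declared class list; labels outside it are an
#'   error.
#' @return A `data.frame` with columns `x`, `y`, `label` and class
#'   `reference_points`.
#' @export
reference_points <- function(x, y, label, class_list = NULL) {
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("point coordinates must be finite")
  if (!is.null(class_list)) {
    bad <- which(!label %in% class_list)
    if (length(bad))
      stop("label outside declared class list at row ", bad[1], ": ",
           label[bad[1]])
  }
  out <- data.frame(x = as.numeric(x), y = as.numeric(y),
                    label = as.character(label),
                    stringsAsFactors = FALSE)
  class(out) <- c("reference_points", "data.frame")
  out
}

#' Statistical test result
#'
#' Uniform container for the change-test statistics: statistic name and
#' value, two-sided p, effective sample size after zero-removal, and whether
#' the p-value is exact or approximate.
#'
#' @param statistic_name `"V"` (Wilcoxon signed-rank) or `"W"`
#'   (Shapiro-Wilk).
#' @param statistic numeric statistic value.
#' @param p_two_sided two-sided p-value.
#' @param n_effective pairs/observations actually used.
#' @param method `"exact"` or `"approximate"`.
#' @param notes character notes on tie/zero handling.
#' @return An object of class `unmix_test`.
#' @export
unmix_test <- function(statistic_name, statistic, p_two_sided, n_effective,
                       method = "exact", notes = character()) {
  stopifnot(p_two_sided > 0, p_two_sided <= 1)
  structure(list(statistic_name = statistic_name,
                 statistic = as.numeric(statistic),
                 p_two_sided = as.numeric(p_two_sided),
                 n_effective = as.integer(n_effective),
                 method = method, notes = notes),
            class = "unmix_test")
}

#' @export
print.unmix_test <- function(x, ...) {
  cat(sprintf("%s = %g, two-sided p = %.4g (n = %d, %s)\n",
              x$statistic_name, x$statistic, x$p_two_sided, x$n_effective,
              x$method))
  if (length(x$notes)) cat("  ", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}
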
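# Tabular carriers: reference points as CSV (header x,y,label) or GeoJSON
# points; endmember libraries as wide CSV (wavelength_nm, class1, ...);
# ROI polygons as GeoJSON with a `label` property.

#' Write reference points
#'
#' @param points a [reference_points()] data frame.
#' @param path output path.
#' @param format `"csv"` (header `x,y,label`) or `"geojson"`.
#' @return `path`, invisibly.
#' @export
write_points <- function(points, path, format = c("csv", "geojson")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(points)[, c("x", "y", "label")], path,
                     row.names = FALSE, quote = FALSE)
  } else {
    feats <- lapply(seq_len(nrow(points)), function(i) list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(points$x[i], points$y[i])),
      properties = list(label = points$label[i])))
    jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read reference points
#'
#' An empty file yields an empty collection, not an error; a label outside
#' the declared class list is an error naming the offending row.
#'
#' @param path input path.
#' @param format `"csv"` or `"geojson"`.
#' @param class_list optional declared class list for validation.
#' @return A [reference_points()] data frame.
#' @export
read_points <- function(path, format = c("csv", "geojson"),
                        class_list = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("missing points file: ", path)
  if (format == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!nrow(df)) return(reference_points(numeric(), numeric(),
                                           character(), class_list))
    need <- c("x", "y", "label")
    if (!all(need %in% names(df)))
      stop("points CSV must have columns x, y, label")
    if (!is.numeric(df$x) || !is.numeric(df$y))
      stop("non-numeric coordinates in points CSV")
    reference_points(df$x, df$y, df$label, class_list)
  } else {
    gj <- jsonlite::read_json(path)
    feats <- gj$features
    if (!length(feats)) return(reference_points(numeric(), numeric(),
                                                character(), class_list))
    xy <- t(vapply(feats, function(f)
      as.numeric(unlist(f$geometry$coordinates)[1:2]), numeric(2)))
    lab <- vapply(feats, function(f)
      as.character(f$properties$label), character(1))
    reference_points(xy[, 1], xy[, 2], lab, class_list)
  }
}

#' Write an endmember library as wide CSV
#'
#' Header `wavelength_nm,<class1>,...,<classK>`, one row per band, columns
#' ordered by the library's declared class order.
#'
#' @param lib an [endmember_library()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path) {
  stopifnot(inherits(lib, "endmember_library"))
  df <- data.frame(wavelength_nm = lib$wavelengths_nm,
                   t(lib$spectra), check.names = FALSE)
  names(df) <- c("wavelength_nm", lib$class_names)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an endmember library from wide CSV
#'
#' @param path input path (format of [write_library()]).
#' @return An [endmember_library()].
#' @export
read_library <- function(path) {
  if (!file.exists(path)) stop("missing library file: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (names(df)[1] != "wavelength_nm")
    stop("library CSV must start with a wavelength_nm column")
  endmember_library(t(as.matrix(df[, -1, drop = FALSE])),
                    names(df)[-1], df$wavelength_nm)
}

#' Write labeled ROI polygons as GeoJSON
#'
#' @param regions a [region_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  feats <- lapply(seq_along(regions$polygons), function(i) {
    ring <- close_ring(regions$polygons[[i]])
    coords <- lapply(seq_len(nrow(ring)), function(j) as.numeric(ring[j, ]))
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(coords)),
         properties = list(label = regions$labels[i]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read labeled ROI polygons from GeoJSON
#'
#' Expects Polygon features with a `label` property.
#'
#' @param path input path.
#' @return A [region_set()].
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("missing regions file: ", path)
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  if (!length(feats)) stop("regions file holds no features")
  polys <- lapply(feats, function(f) {
    ring <- f$geometry$coordinates[[1]]
    do.call(rbind, lapply(ring, function(v) as.numeric(unlist(v)[1:2])))
  })
  labs <- vapply(feats, function(f) as.character(f$properties$label),
                 character(1))
  region_set(polys, labs)
}
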
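#' Predicted class at reference points
#'
#' A point's prediction is the class whose fractional abundance at the
#' point's pixel is at least `tau`; if several qualify (possible below 0.5
#' or outside sum-to-one modes) the largest fraction wins, ties broken
#' lexicographically by class name; if none qualifies the point is
#' `"unclassified"`.
#'
#' @param stack a [fraction_stack()].
#' @param points a [reference_points()] data frame.
#' @param tau fractional-abundance threshold in (0, 1).
#' @return character vector of predicted labels (or `"unclassified"`).
#' @export
predicted_class_at_points <- function(stack, points, tau = 0.5) {
  stopifnot(inherits(stack, "fraction_stack"))
  if (tau <= 0 || tau >= 1) stop("`tau` must be in (0, 1)")
  d <- dim(stack$fractions)
  px <- stack$pixel_size_m
  col <- floor((points$x - stack$origin_xy[1]) / px) + 1
  row <- floor((stack$origin_xy[2] - points$y) / px) + 1
  out_of <- which(col < 1 | col > d[2] | row < 1 | row > d[1])
  if (length(out_of))
    stop("point(s) outside raster extent at index ",
         paste(out_of, collapse = ", "))
  frm <- matrix(stack$fractions, d[1] * d[2], d[3])
  idx <- row + (col - 1) * d[1]
  vapply(seq_along(idx), function(i) {
    fr <- frm[idx[i], ]
    qual <- which(fr >= tau)
    if (!length(qual)) return("unclassified")
    qual <- qual[order(-fr[qual], stack$class_names[qual])]
    stack$class_names[qual[1]]
  }, character(1))
}

#' Confusion matrix from label sequences
#'
#' Cell (i, j) counts points of reference class i predicted as class j.
#' Points predicted `"unclassified"` are, by default, excluded from the
#' cells and reported in `n_unclassified`; set
#' `unclassified = "column"` to keep them as a dedicated column.
#'
#' @param reference,predicted equal-length label vectors.
#' @param class_order K class labels.
#' @param unclassified `"drop"` or `"column"`.
#' @return An object of class `unmix_confusion`: list with `counts` (K x K
#'   or K x (K+1) matrix), `class_order`, `n_unclassified`, `total`.
#' @export
confusion_matrix <- function(reference, predicted, class_order,
                             unclassified = c("drop", "column")) {
  unclassified <- match.arg(unclassified)
  if (length(reference) != length(predicted))
    stop("label sequences must have equal length")
  okr <- reference %in% class_order
  okp <- predicted %in% c(class_order, "unclassified")
  if (any(!okr)) stop("unknown reference label: ", reference[!okr][1])
  if (any(!okp)) stop("unknown predicted label: ", predicted[!okp][1])
  n_uncl <- sum(predicted == "unclassified")
  if (unclassified == "drop") {
    keep <- predicted != "unclassified"
    counts <- table(factor(reference[keep], levels = class_order),
                    factor(predicted[keep], levels = class_order))
  } else {
    counts <- table(factor(reference, levels = class_order),
                    factor(predicted,
                           levels = c(class_order, "unclassified")))
  }
  counts <- unclass(as.matrix(counts))
  names(dimnames(counts)) <- c("reference", "predicted")
  structure(list(counts = counts, class_order = class_order,
                 n_unclassified = n_uncl, total = sum(counts)),
            class = "unmix_confusion")
}

#' Build a confusion object from a printed counts matrix
#'
#' @param counts K x K matrix, rows = reference, columns = predicted.
#' @param class_order optional class labels (default from dimnames).
#' @param total optional declared grand total. Published tables sometimes
#'   print a grand total inconsistent with their own cells; passing the
#'   declared value here preserves the table as printed (the default is
#'   `sum(counts)`).
#' @return An `unmix_confusion`.
#' @export
as_confusion <- function(counts, class_order = rownames(counts),
                         total = sum(counts)) {
  counts <- as.matrix(counts)
  if (is.null(class_order))
    class_order <- paste0("class", seq_len(nrow(counts)))
  dimnames(counts) <- list(reference = class_order,
                           predicted = colnames(counts) %||% class_order)
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = counts, class_order = class_order,
                 n_unclassified = 0L, total = total),
            class = "unmix_confusion")
}

#' @export
print.unmix_confusion <- function(x, ...) {
  cat("<confusion matrix> reference rows x predicted columns\n")
  print(x$counts)
  if (x$n_unclassified)
    cat("unclassified (excluded):", x$n_unclassified, "\n")
  invisible(x)
}

#' Overall, user's and producer's accuracy
#'
#' Overall accuracy is trace/total. The per-class metrics follow, by
#' default, the convention of the source tables this pipeline mirrors:
#' user's accuracy = diagonal / reference-row total and producer's =
#' diagonal / predicted-column total, which is the reverse of the textbook
#' assignment; `convention = "standard"` swaps them. Metrics whose
#' denominator is zero are returned as `NA` rather than 0. Values are
#' returned unrounded, as proportions in \[0, 1\].
#'
#' @param cm an `unmix_confusion`.
#' @param convention `"rowwise"` (row-based user's) or `"standard"`.
#' @return list with `overall`, `users` (named K-vector), `producers`.
#' @export
accuracy_metrics <- function(cm, convention = c("rowwise", "standard")) {
  convention <- match.arg(convention)
  stopifnot(inherits(cm, "unmix_confusion"))
  K <- length(cm$class_order)
  counts <- cm$counts[, seq_len(K), drop = FALSE]  # ignore uncl. column
  total <- cm$total
  if (total == 0) stop("empty confusion matrix")
  diagv <- diag(counts)
  rs <- rowSums(cm$counts)
  cs <- colSums(counts)
  by_row <- ifelse(rs > 0, diagv / rs, NA_real_)
  by_col <- ifelse(cs > 0, diagv / cs, NA_real_)
  users <- if (convention == "rowwise") by_row else by_col
  producers <- if (convention == "rowwise") by_col else by_row
  list(overall = sum(diagv) / total,
       users = setNames(users, cm$class_order),
       producers = setNames(producers, cm$class_order))
}

#' Threshold-based accuracy assessment at reference points
#'
#' Convenience composition: predict classes at the points at threshold
#' `tau`, tabulate against the reference labels, and compute the accuracy
#' metrics.
#'
#' @param stack a [fraction_stack()].
#' @param points a [reference_points()] data frame.
#' @param tau fractional-abundance threshold.
#' @param class_order class labels (default the stack's).
#' @inheritParams accuracy_metrics
#' @return list with `confusion` and `metrics`.
#' @export
assess_accuracy <- function(stack, points, tau = 0.5,
                            class_order = stack$class_names,
                            convention = "rowwise") {
  pred <- predicted_class_at_points(stack, points, tau)
  cm <- confusion_matrix(points$label, pred, class_order)
  list(confusion = cm, metrics = accuracy_metrics(cm, convention))
}
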
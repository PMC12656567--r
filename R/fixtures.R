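#' Bundled example bin counts
#'
#' Per-bin pixel counts of fractional abundance (ten equal-width bins from
#' 0 to 1) for three land-cover classes — herbaceous vegetation, mixed
#' forbs, bare soil — in two acquisition years (2018, 2022) over a
#' semi-arid grassland flux footprint mapped at 1 m from airborne
#' hyperspectral imagery. These counts are the pairing unit of the bundled
#' change-test example.
#'
#' @return data frame with columns `bin_lo`, `bin_hi` and one count column
#'   per class-year (`herbaceous_2018`, ..., `bare_soil_2022`).
#' @export
example_bin_counts <- function() {
  utils::read.csv(system.file("extdata", "abundance_bin_counts.csv",
                              package = "grassunmix"),
                  stringsAsFactors = FALSE)
}

#' Bundled example confusion matrices
#'
#' Reference-versus-predicted counts from the accuracy assessment of an
#' unmixing-based land-cover map of the same grassland site, thresholded at
#' 50% and at 75% fractional abundance (150 reference points declared, 50
#' per class). Rows are reference classes, columns predicted classes.
#'
#' Both tables are preserved exactly as printed, including the declared
#' grand total of 150. Note that the 75%-threshold table is internally
#' inconsistent in its source: its cells sum to 154 (one reference row
#' totals 54), yet its printed grand total and the declared sampling design
#' say 150. The declared total is kept so the table's own printed overall
#' accuracy follows from it; the cell-level discrepancy is the source
#' table's, not this package's.
#'
#' @param threshold 50 or 75 (percent fractional-abundance threshold).
#' @return An [as_confusion()] object.
#' @export
example_confusion <- function(threshold = 50) {
  stopifnot(threshold %in% c(50, 75))
  f <- system.file("extdata",
                   sprintf("confusion_threshold%d.csv", threshold),
                   package = "grassunmix")
  df <- utils::read.csv(f, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$reference
  as_confusion(m, class_order = df$reference, total = 150)
}

#' Change-test table for the bundled bin counts
#'
#' Runs [change_tests()] (2018 minus 2022) for each class of
#' [example_bin_counts()] — or any data frame in the same layout — and
#' returns the statistics in one table.
#'
#' @param counts data frame in the layout of [example_bin_counts()].
#' @return data frame with one row per class: Shapiro-Wilk `W` and
#'   `shapiro_p`, Wilcoxon `V` and `wilcoxon_p`, and the p-value method.
#' @export
change_test_table <- function(counts = example_bin_counts()) {
  cols <- setdiff(names(counts), c("bin_lo", "bin_hi"))
  classes <- unique(sub("_(\\d{4})$", "", cols))
  years <- sort(unique(sub("^.*_(\\d{4})$", "\\1", cols)))
  if (length(years) != 2)
    stop("expected exactly two years in the count columns")
  out <- lapply(classes, function(cl) {
    c1 <- counts[[paste0(cl, "_", years[1])]]
    c2 <- counts[[paste0(cl, "_", years[2])]]
    ct <- change_tests(c1, c2)
    data.frame(class = cl,
               W = ct$shapiro$statistic, shapiro_p = ct$shapiro$p_two_sided,
               V = ct$wilcoxon$statistic,
               wilcoxon_p = ct$wilcoxon$p_two_sided,
               method = ct$wilcoxon$method, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
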
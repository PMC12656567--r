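#' Paired differences of histogram bin counts
#'
#' Elementwise `counts(a) - counts(b)` for two histograms with identical
#' bin structure; the pairing unit of the change tests is the abundance
#' bin, not the pixel.
#'
#' @param hist_a,hist_b `histogram_summary` objects with equal bin edges.
#' @return numeric vector of signed differences, one per bin.
#' @export
paired_bin_differences <- function(hist_a, hist_b) {
  stopifnot(inherits(hist_a, "histogram_summary"),
            inherits(hist_b, "histogram_summary"))
  if (length(hist_a$bin_edges) != length(hist_b$bin_edges) ||
      any(hist_a$bin_edges != hist_b$bin_edges))
    stop("histograms have different bin structure")
  hist_a$counts - hist_b$counts
}

#' Exact null distribution of the signed-rank statistic
#'
#' Probability of each value V = 0 .. n(n+1)/2 of the Wilcoxon signed-rank
#' statistic under the null, computed by convolution over the ranks
#' 1..n (each rank independently enters the positive sum with probability
#' 1/2). Sums to 1 exactly up to floating point.
#'
#' @param n number of non-zero pairs.
#' @return numeric vector of length n(n+1)/2 + 1; element k is P(V = k-1).
#' @export
signed_rank_null_distribution <- function(n) {
  stopifnot(n >= 1)
  maxV <- n * (n + 1) / 2
  p <- c(1, numeric(maxV))
  for (r in seq_len(n)) {
    shifted <- c(numeric(r), p[seq_len(maxV + 1 - r)])
    p <- (p + shifted) / 2
  }
  p
}

#' Exact Wilcoxon signed-rank test
#'
#' Paired two-sided test on `d = x - y`. Zero differences are dropped
#' (Wilcoxon's original treatment); absolute differences are ranked with
#' average ranks for ties; V is the sum of ranks of the positive
#' differences. When there are no ties among the non-zero |d| and the
#' effective n is at most 25, the two-sided p-value is exact, from the full
#' sign-flip null distribution computed by rank convolution, doubling the
#' smaller tail: `p = min(1, 2 min(P(V <= v), P(V >= v)))`. Otherwise a
#' normal approximation with tie correction and continuity correction is
#' used and flagged in `method`.
#'
#' @param x,y equal-length paired numeric vectors.
#' @param exact_limit largest effective n for the exact route.
#' @return An [unmix_test()] with `statistic_name = "V"`.
#' @export
wilcoxon_signed_rank_exact <- function(x, y, exact_limit = 25) {
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  if (!length(x)) stop("need >= 1 pair")
  d <- x - y
  nz <- d != 0
  n_zero <- sum(!nz)
  d <- d[nz]
  n <- length(d)
  if (n == 0) stop("all differences are zero")
  rk <- rank(abs(d))
  V <- sum(rk[d > 0])
  ties <- anyDuplicated(abs(d)) > 0
  notes <- character()
  if (n_zero) notes <- c(notes, sprintf("%d zero pair(s) dropped", n_zero))
  if (!ties && n <= exact_limit) {
    dist <- signed_rank_null_distribution(n)
    v <- as.integer(round(V))
    lower <- sum(dist[seq_len(v + 1)])
    upper <- sum(dist[(v + 1):length(dist)])
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    if (ties) notes <- c(notes, "ties among |d|: average ranks, normal approximation")
    mu <- n * (n + 1) / 4
    tvals <- table(abs(d))
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tvals^3 - tvals) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "approximate"
  }
  unmix_test("V", V, p, n, method = method, notes = notes)
}

#' Shapiro-Wilk normality test
#'
#' W statistic and p-value for a sample of 3 to 5000 observations
#' (Royston's AS R94 approximation, as implemented in base R's
#' `shapiro.test`), wrapped in the package's uniform test-result container
#' with clean error contracts for out-of-range n and zero variance.
#'
#' @param x numeric sample.
#' @return An [unmix_test()] with `statistic_name = "W"`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3 || n > 5000) stop("sample size must be in [3, 5000], got ", n)
  if (stats::sd(x) == 0) stop("zero variance: all values identical")
  sw <- stats::shapiro.test(x)
  unmix_test("W", unname(sw$statistic), sw$p.value, n, method = "approximate")
}

#' Normal Q-Q plotting points
#'
#' Blom-type plotting positions `(i - 0.375) / (n + 0.25)` mapped through
#' the standard normal quantile function, paired with the sorted sample.
#'
#' @param x numeric sample, n >= 2.
#' @return data frame with columns `theoretical` and `sample`, both
#'   non-decreasing.
#' @export
qq_points <- function(x) {
  n <- length(x)
  if (n < 2) stop("need n >= 2")
  pos <- (seq_len(n) - 0.375) / (n + 0.25)
  data.frame(theoretical = stats::qnorm(pos), sample = sort(x))
}

#' Change tests for one land-cover class from paired bin counts
#'
#' Given per-bin pixel counts for two acquisition years, computes the
#' paired differences (year 1 minus year 2), the Shapiro-Wilk normality
#' test on the differences, and the exact Wilcoxon signed-rank test.
#'
#' @param counts_1,counts_2 per-bin pixel counts for the two years.
#' @return list with `differences`, `shapiro` and `wilcoxon`
#'   ([unmix_test()]s).
#' @export
change_tests <- function(counts_1, counts_2) {
  d <- counts_1 - counts_2
  list(differences = d,
       shapiro = shapiro_wilk(d),
       wilcoxon = wilcoxon_signed_rank_exact(counts_1, counts_2))
}
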
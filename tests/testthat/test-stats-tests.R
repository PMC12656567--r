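test_that("paired bin differences are elementwise and antisymmetric", {
  m <- matrix(runif(100), 10, 10)
  h <- histogram_counts(m)
  expect_equal(paired_bin_differences(h, h), rep(0, 10))

  set.seed(2)
  h2 <- histogram_counts(matrix(runif(100), 10, 10))
  expect_equal(paired_bin_differences(h, h2),
               -paired_bin_differences(h2, h))
  expect_equal(paired_bin_differences(h, h2), h$counts - h2$counts)

  h3 <- histogram_counts(m, n_bins = 5)
  expect_error(paired_bin_differences(h, h3), "bin structure")
})

test_that("bundled bin counts give the expected first-bin difference", {
  tab <- example_bin_counts()
  d <- tab$herbaceous_2018 - tab$herbaceous_2022
  expect_equal(d[1], 39728 - 110840)
  expect_equal(d[1], -71112)
})

test_that("tiny signed-rank cases match explicit enumeration", {
  # d = (1, 2, 3): V = 6, one of 8 equally likely assignments in each tail
  out <- wilcoxon_signed_rank_exact(c(1, 2, 3), c(0, 0, 0))
  expect_equal(out$statistic, 6)
  expect_equal(out$p_two_sided, 2 * (1 / 8))
  expect_equal(out$n_effective, 3)
  expect_equal(out$method, "exact")

  # zeros dropped
  z <- wilcoxon_signed_rank_exact(c(5, 1, 2, 3), c(5, 0, 0, 0))
  expect_equal(z$n_effective, 3)
  expect_equal(z$p_two_sided, 0.25)
  expect_match(paste(z$notes, collapse = " "), "zero")

  expect_error(wilcoxon_signed_rank_exact(1:3, 1:3), "all differences")
  expect_error(wilcoxon_signed_rank_exact(1:3, 1:2), "equal length")
})

test_that("the rank convolution equals full 2^n enumeration at n = 10", {
  n <- 10
  dist <- signed_rank_null_distribution(n)
  expect_equal(sum(dist), 1, tolerance = 1e-12)
  # brute force: V for all 2^10 sign assignments of ranks 1..10
  maxV <- n * (n + 1) / 2
  tally <- numeric(maxV + 1)
  for (mask in 0:(2^n - 1)) {
    v <- sum(which(bitwAnd(mask, 2^(0:(n - 1))) > 0))
    tally[v + 1] <- tally[v + 1] + 1
  }
  expect_equal(dist, tally / 2^n, tolerance = 1e-12)
  # two-sided exact p agrees with the enumeration for every attainable V
  for (v in 0:maxV) {
    p_enum <- min(1, 2 * min(sum(tally[1:(v + 1)]) / 2^n,
                             sum(tally[(v + 1):(maxV + 1)]) / 2^n))
    expect_equal(
      min(1, 2 * min(sum(dist[1:(v + 1)]), sum(dist[(v + 1):(maxV + 1)]))),
      p_enum, tolerance = 1e-12)
  }
})

test_that("V(x,y) and V(y,x) partition the total rank sum without ties", {
  set.seed(6)
  x <- rnorm(12)
  y <- rnorm(12)
  a <- wilcoxon_signed_rank_exact(x, y)
  b <- wilcoxon_signed_rank_exact(y, x)
  expect_equal(a$statistic + b$statistic, 12 * 13 / 2)
  expect_equal(a$p_two_sided, b$p_two_sided)
})

test_that("the exact route agrees with the reference implementation", {
  set.seed(30)
  for (i in 1:10) {
    x <- rnorm(15)
    y <- rnorm(15)
    ours <- wilcoxon_signed_rank_exact(x, y)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_two_sided, ref$p.value, tolerance = 1e-12)
  }
})

test_that("ties and large n fall back to a flagged normal approximation", {
  tied <- wilcoxon_signed_rank_exact(c(3, 3, 5, 8, 1, 4), rep(0, 6))
  expect_equal(tied$method, "approximate")
  expect_match(paste(tied$notes, collapse = " "), "ties")

  set.seed(7)
  x <- rnorm(40)
  y <- rnorm(40)
  big <- wilcoxon_signed_rank_exact(x, y)
  expect_equal(big$method, "approximate")
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(big$p_two_sided, ref$p.value, tolerance = 1e-10)
})

test_that("Shapiro-Wilk wrapper enforces contracts and closed-form n = 3", {
  out <- shapiro_wilk(c(-1, 0, 1))
  expect_equal(out$statistic, 1, tolerance = 1e-6)
  expect_error(shapiro_wilk(c(1, 2)), "sample size")
  expect_error(shapiro_wilk(rep(3, 10)), "zero variance")
  # affine invariance
  set.seed(9)
  x <- rexp(30)
  expect_equal(shapiro_wilk(7 * x + 3)$statistic,
               shapiro_wilk(x)$statistic, tolerance = 1e-10)
})

test_that("Q-Q points use Blom-type plotting positions", {
  two <- qq_points(c(5, -5))
  expect_equal(two$theoretical,
               stats::qnorm(c((1 - 0.375) / 2.25, (2 - 0.375) / 2.25)))
  expect_equal(two$sample, c(-5, 5))

  set.seed(10)
  q <- qq_points(rnorm(25))
  expect_false(is.unsorted(q$theoretical))
  expect_false(is.unsorted(q$sample))
  # symmetric positions around zero
  expect_equal(q$theoretical, -rev(q$theoretical), tolerance = 1e-12)
  expect_error(qq_points(1), "n >= 2")
})

test_that("the bundled change-test table reproduces the documented statistics", {
  tab <- change_test_table()
  expect_equal(tab$V, c(43, 33, 10))
  expect_equal(tab$wilcoxon_p, c(134 / 1024, 640 / 1024, 86 / 1024),
               tolerance = 1e-12)
  expect_equal(tab$W, c(0.546, 0.824, 0.504), tolerance = 1e-3)
  expect_true(all(tab$method == "exact"))
})
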
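point_stack <- function(frs, classes = c("a", "b", "c")) {
  K <- length(classes)
  arr <- array(NA_real_, c(1, length(frs), K))
  for (i in seq_along(frs)) arr[1, i, ] <- frs[[i]]
  fraction_stack(arr, classes, mode = "fcls")
}

test_that("threshold prediction picks qualifying classes with tie-breaks", {
  st <- point_stack(list(c(1, 0, 0), c(0.4, 0.35, 0.25), c(0.4, 0.4, 0.2),
                         c(0.2, 0.3, 0.5)))
  pts <- reference_points(c(0.5, 1.5, 2.5, 3.5), rep(-0.5, 4),
                          c("a", "a", "b", "c"))
  expect_equal(predicted_class_at_points(st, pts, 0.5),
               c("a", "unclassified", "unclassified", "c"))
  # below 0.5 several classes can qualify: largest wins, ties lexicographic
  expect_equal(predicted_class_at_points(st, pts, 0.3),
               c("a", "a", "a", "c"))
  expect_error(predicted_class_at_points(st, pts, 1.5), "tau")
  far <- reference_points(99, 99, "a")
  expect_error(predicted_class_at_points(st, far, 0.5), "index 1")
})

test_that("confusion matrices tabulate reference rows against predicted columns", {
  ref <- c("a", "a", "b", "b", "c")
  cm <- confusion_matrix(ref, ref, c("a", "b", "c"))
  expect_equal(unname(diag(cm$counts)), c(2, 2, 1))
  expect_equal(sum(cm$counts) - sum(diag(cm$counts)), 0)

  pred <- c("a", "unclassified", "a", "b", "c")
  cm2 <- confusion_matrix(ref, pred, c("a", "b", "c"))
  expect_equal(cm2$n_unclassified, 1)
  expect_equal(cm2$total, 4)
  cm3 <- confusion_matrix(ref, pred, c("a", "b", "c"),
                          unclassified = "column")
  expect_equal(cm3$counts["a", "unclassified"], 1)

  empty <- confusion_matrix(character(), character(), c("a", "b"))
  expect_equal(empty$total, 0)
  expect_error(accuracy_metrics(empty), "empty")
  expect_error(confusion_matrix("a", "z", c("a", "b")), "unknown predicted")
})

test_that("bundled 50%-threshold assessment reproduces its printed metrics", {
  cm <- example_confusion(50)
  expect_equal(unname(c(t(cm$counts))),
               c(36, 10, 4, 9, 41, 0, 0, 1, 49))
  m <- accuracy_metrics(cm)
  expect_equal(m$overall, 0.84)
  expect_equal(unname(m$users), c(0.72, 0.82, 0.98))
  expect_equal(unname(m$producers), c(36 / 45, 41 / 52, 49 / 53))
  # printed rounded forms: 80%, 79%, 92%
  expect_equal(round(100 * unname(m$producers)), c(80, 79, 92))
})

test_that("bundled 75%-threshold assessment reproduces its printed metrics", {
  m <- accuracy_metrics(example_confusion(75))
  expect_equal(m$overall, 0.60)
  expect_equal(unname(m$users), c(26 / 50, 27 / 54, 37 / 50))
  expect_equal(round(100 * unname(m$users)), c(52, 50, 74))
  expect_equal(round(100 * unname(m$producers)), c(72, 42, 69))
})

test_that("identity matrices score 1 and overall is permutation-invariant", {
  cm <- as_confusion(diag(5) * 7, letters[1:5])
  m <- accuracy_metrics(cm)
  expect_equal(m$overall, 1)
  expect_true(all(m$users == 1) && all(m$producers == 1))

  counts <- example_confusion(50)$counts
  perm <- c(3, 1, 2)
  mp <- accuracy_metrics(as_confusion(counts[perm, perm],
                                      rownames(counts)[perm]))
  expect_equal(mp$overall, 0.84)
  expect_true(all(unlist(accuracy_metrics(example_confusion(75))[-1]) >= 0 &
                    unlist(accuracy_metrics(example_confusion(75))[-1]) <= 1))
})

test_that("the convention switch swaps user's and producer's accuracy", {
  cm <- example_confusion(50)
  a <- accuracy_metrics(cm, "rowwise")
  b <- accuracy_metrics(cm, "standard")
  expect_equal(a$users, b$producers)
  expect_equal(a$producers, b$users)
})

test_that("scene-level assessment agrees with a per-point lookup oracle", {
  scn <- tiny_scene(25, 25, 60, noise_sd = 0.01, seed = 91)
  st <- unmix_cube(scn$cube, scn$truth$library, "fcls")
  pts <- sample_reference_points(scn$truth, 8, purity = 0.7, seed = 5)
  pred <- predicted_class_at_points(st, pts, 0.5)
  for (i in seq_len(nrow(pts))) {
    col <- floor(pts$x[i]) + 1
    row <- floor(-pts$y[i]) + 1
    fr <- st$fractions[row, col, ]
    oracle <- if (max(fr) >= 0.5) st$class_names[which.max(fr)]
              else "unclassified"
    expect_identical(pred[i], oracle)
  }
  acc <- assess_accuracy(st, pts, 0.5)
  expect_equal(acc$confusion$total + acc$confusion$n_unclassified,
               nrow(pts))
})
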
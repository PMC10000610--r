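# Feature extraction, SVM training/CV, and confusion-matrix metrics.

make_features <- function(q, id = "s", cl = NA_integer_) {
  structure(list(sample_id = id, true_class = cl, q = q,
                 std = q / 10, R = rep(1, length(q)),
                 z = seq_along(q), absent = rep(FALSE, length(q))),
            class = "sample_features")
}

test_that("feature extraction is deterministic and flags absent layers", {
  m <- make_class_sample(3, "trim", seed = 4, n_theta = 96, n_z = 48)
  f1 <- extract_features(m, n_layers = 12L, sample_id = "a")
  f2 <- extract_features(m, n_layers = 12L, sample_id = "a")
  expect_identical(f1$q, f2$q)
  expect_identical(f1$std, f2$std)
  expect_length(f1$q, 12L)
  expect_true(all(f1$q >= 0))
  expect_false(any(f1$absent))

  # a mesh with no closed contours anywhere: a single tilted wall
  wall <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 1),
                              c(1, 1, 1)),
                        rbind(c(1L, 2L, 3L), c(2L, 4L, 3L)))
  expect_error(extract_features(wall, n_layers = 8L), "failed at every")
})

test_that("perfect-cone features sit below the tessellation noise floor", {
  n_theta <- 96L
  f <- extract_features(make_perfect_cone(60, 42, n_theta, 48),
                        n_layers = 20L)
  floors <- vapply(f$R, tessellation_noise_floor, 0, n_theta = n_theta)
  expect_true(all(f$q < floors))
})

test_that("training separates separable classes and rejects bad input", {
  set.seed(5)
  feats <- c(lapply(1:6, function(i) make_features(runif(10, 0, 0.1))),
             lapply(1:6, function(i) make_features(runif(10, 5, 6))),
             lapply(1:6, function(i) make_features(runif(10, 20, 22))))
  labels <- rep(0:2, each = 6)
  model <- train_classifier(feats, labels)
  expect_equal(predict(model, feats), labels)   # resubstitution

  # identical vectors with conflicting labels: trains, but cannot resolve
  confl <- lapply(1:4, function(i) make_features(rep(1, 10)))
  m2 <- train_classifier(confl, c(0, 0, 1, 1))
  expect_lt(mean(predict(m2, confl) == c(0, 0, 1, 1)), 1)

  expect_error(train_classifier(feats[1], labels[1]), "two samples")
  expect_error(train_classifier(feats[1:3], rep(0, 3)), "distinct classes")
  expect_error(train_classifier(feats, labels[1:5]), "length")
  bad <- c(feats[1:5], list(make_features(runif(7))))
  expect_error(train_classifier(bad, rep(0:1, 3)), "inconsistent")
})

test_that("stratified CV balances folds and enforces class counts", {
  set.seed(8)
  feats <- unlist(lapply(0:3, function(cl) {
    lapply(1:6, function(i) make_features(runif(10, cl * 8, cl * 8 + 1)))
  }), recursive = FALSE)
  labels <- rep(0:3, each = 6)
  cv <- cross_validate(feats, labels, k = 4, seed = 2)
  expect_equal(as.vector(table(cv$folds)), rep(6L, 4L))  # 6/6/6/6
  for (f in 1:4) {
    percls <- table(factor(labels[cv$folds == f], levels = 0:3))
    expect_true(all(percls >= 1 & percls <= 2))   # balanced strata
  }
  expect_equal(sum(cv$confusion), 24L)
  expect_equal(cv$loss, 1 - cv$accuracy)
  expect_equal(cv$accuracy, 1)              # trivially separable by design

  cv5 <- cross_validate(feats, labels, k = 5, seed = 2)
  expect_equal(sum(cv5$confusion), 24L)
  expect_error(cross_validate(feats, labels, k = 7, seed = 2),
               "at least k samples")
  expect_error(cross_validate(feats, labels, k = 1, seed = 2), ">= 2")
})

test_that("CV fold assignment depends only on the seed", {
  feats <- unlist(lapply(0:1, function(cl) {
    lapply(1:4, function(i) make_features(rep(cl, 5) + i / 10))
  }), recursive = FALSE)
  labels <- rep(0:1, each = 4)
  a <- cross_validate(feats, labels, k = 4, seed = 3)
  b <- cross_validate(feats, labels, k = 4, seed = 3)
  expect_identical(a$folds, b$folds)
  expect_identical(a$predicted, b$predicted)
})

test_that("reference confusion matrix reproduces the benchmark metrics", {
  cm <- reference_confusion_matrix()
  expect_equal(rowSums(cm), rep(6, 4), ignore_attr = TRUE)
  expect_equal(sum(diag(cm)), 21)
  expect_equal(sum(cm), 24)
  expect_equal(sum(cm[, 4]), 6)

  met <- matrix_metrics(cm)
  expect_equal(met$accuracy, 0.875)
  expect_equal(unname(met$sensitivity), c(1, 5 / 6, 4 / 6, 1))
  expect_equal(round(100 * unname(met$sensitivity), 1),
               c(100, 83.3, 66.7, 100))
  expect_equal(unname(met$ppv), c(6 / 8, 5 / 6, 1, 1))
  expect_equal(round(100 * unname(met$ppv), 1), c(75, 83.3, 100, 100))
  # textbook specificity differs from the PPV column
  expect_equal(unname(met$specificity), c(16 / 18, 17 / 18, 1, 1))
})

test_that("metrics behave under permutation, perfection and emptiness", {
  cm <- reference_confusion_matrix()
  p <- c(3, 1, 4, 2)
  met <- matrix_metrics(cm)
  metp <- matrix_metrics(cm[p, p])
  expect_equal(unname(metp$sensitivity), unname(met$sensitivity[p]))
  expect_equal(unname(metp$ppv), unname(met$ppv[p]))
  expect_equal(metp$accuracy, met$accuracy)

  perfect <- diag(c(6, 6, 6, 6))
  mp <- matrix_metrics(perfect)
  expect_true(all(mp$sensitivity == 1) && all(mp$ppv == 1))
  expect_equal(mp$accuracy, 1)

  # zero row/column -> undefined (NA), never 0
  cm0 <- rbind(c(2, 0, 0), c(1, 1, 0), c(0, 0, 0))
  m0 <- matrix_metrics(cm0)
  expect_true(is.na(m0$sensitivity[3]))
  expect_true(is.na(m0$ppv[3]))
  expect_error(matrix_metrics(matrix(0, 2, 2)), "empty")
  expect_error(matrix_metrics(matrix(1, 2, 3)), "square")
})

test_that("confusion_matrix tabulates truth by prediction", {
  cm <- confusion_matrix(c(0, 0, 1, 1, 2), c(0, 1, 1, 1, 0),
                         levels = 0:2)
  expect_equal(dim(cm), c(3L, 3L))
  expect_equal(cm["0", "1"], 1L, ignore_attr = TRUE)
  expect_equal(cm["2", "0"], 1L, ignore_attr = TRUE)
  expect_equal(sum(cm), 5L)
})
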
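test_that("pooling matches its elementwise definitions", {
  c1 <- c(1, 0, 0); c2 <- c(0, 1, 0)
  expect_equal(pool_codes(cbind(c1, c2), "sum_normalized"), c(0.5, 0.5, 0))
  expect_equal(pool_codes(cbind(c1), "sum_normalized"), c1)
  M <- cbind(c(0.9, 0.1, 0), c(-0.2, 0.8, 0))
  expect_equal(pool_codes(M, "max_abs"), c(0.9, 0.8, 0))
  expect_warning(z <- pool_codes(matrix(0, 3, 0), "max_abs"), "empty")
  expect_equal(z, c(0, 0, 0))
})

test_that("pooling is permutation-invariant over descriptors", {
  set.seed(1)
  M <- matrix(rnorm(6 * 20), 6, 20)
  perm <- sample(20)
  for (m in c("sum_normalized", "max_abs"))
    expect_equal(pool_codes(M, m), pool_codes(M[, perm], m))
})

test_that("the SVM separates separable features and is seed-deterministic", {
  set.seed(2)
  X <- rbind(matrix(rnorm(40 * 5, mean = 0), 40, 5),
             matrix(rnorm(40 * 5, mean = 4), 40, 5))
  y <- rep(c("glioblastoma", "meningioma"), each = 40)
  model <- train_classifier(X, y, "svm_linear", seed = 3)
  pred <- predict_frame(model, X)
  expect_equal(as.character(pred$label), y)

  model2 <- train_classifier(X, y, "svm_linear", seed = 3)
  expect_identical(predict_frame(model2, X), pred)

  expect_error(train_classifier(X, rep("a", 80)), "single class")
  # degenerate inputs still yield a valid label
  z <- predict_frame(model, rep(0, 5))
  expect_true(as.character(z$label) %in% model$levels)
  expect_error(predict_frame(model, rep(0, 4)), "length")
})

test_that("labels carry no signal after permutation", {
  set.seed(4)
  X <- matrix(rnorm(200 * 4), 200, 4)
  y <- sample(rep(c("a", "b"), each = 100))
  model <- train_classifier(X[1:100, ], y[1:100], "svm_linear", seed = 1)
  acc <- mean(as.character(predict_frame(model, X[101:200, ])$label) ==
                y[101:200])
  expect_gt(acc, 0.5 - 3 * sqrt(0.25 / 100))
  expect_lt(acc, 0.5 + 3 * sqrt(0.25 / 100))
})

test_that("grouped splits never leak videos and are seed-stable", {
  ids <- sprintf("v%02d", 1:20)
  labs <- rep(c("glioblastoma", "meningioma"), each = 10)
  fpv <- rep(10L, 20)
  splits <- video_grouped_splits(labs, ids, fpv, 0.8, 5, seed = 9)
  expect_length(splits, 5)
  for (s in splits) {
    expect_length(intersect(s$train, s$test), 0)
    expect_setequal(c(s$train, s$test), ids)
    for (cl in unique(labs))
      expect_equal(sum(ids[labs == cl] %in% s$test), 2)
  }
  splits2 <- video_grouped_splits(labs, ids, fpv, 0.8, 5, seed = 9)
  expect_identical(splits, splits2)
  expect_error(video_grouped_splits(c("a", "b"), c("v1", "v2"), c(1, 1)),
               "at least 2")
})

test_that("confusion-matrix metrics follow their definitions", {
  truth <- factor(c(rep("glioblastoma", 10), rep("meningioma", 10)))
  pred <- factor(c(rep("glioblastoma", 8), rep("meningioma", 2),
                   rep("meningioma", 9), "glioblastoma"),
                 levels = levels(truth))
  m <- confusion_metrics(truth, pred)
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$accuracy, 0.85)

  perfect <- confusion_metrics(truth, truth)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  # accuracy = (sens * P + spec * N) / (P + N) for any confusion matrix
  set.seed(5)
  t2 <- factor(sample(c("glioblastoma", "meningioma"), 60, replace = TRUE))
  p2 <- factor(sample(c("glioblastoma", "meningioma"), 60, replace = TRUE),
               levels = levels(t2))
  mm <- confusion_metrics(t2, p2)
  P <- sum(t2 == "glioblastoma"); N <- sum(t2 == "meningioma")
  expect_equal(mm$accuracy, (mm$sensitivity * P + mm$specificity * N) / (P + N))
})
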
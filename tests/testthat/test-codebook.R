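test_that("descriptor sampling is seeded, bounded, and excludes zero rows", {
  X <- rbind(matrix(rnorm(50 * 8), 50, 8), matrix(0, 5, 8))
  s1 <- sample_descriptors(X, 20, seed = 1)
  s2 <- sample_descriptors(X, 20, seed = 1)
  expect_identical(s1, s2)
  expect_equal(dim(s1), c(8L, 20L))

  expect_warning(all_of_them <- sample_descriptors(X, 100, seed = 1),
                 "only 50 available")
  expect_equal(ncol(all_of_them), 50)  # zero rows dropped first
  expect_error(sample_descriptors(matrix(0, 3, 8), 2), "no non-zero")
})

test_that("k-means fixed points and objective monotonicity hold", {
  set.seed(2)
  pts <- matrix(rnorm(5 * 4, sd = 5), 5, 4)  # 4 well-separated points
  cb <- kmeans_codebook(pts, m = 4, seed = 1)
  ord <- nearest_codeword(pts, cb)$index
  expect_equal(sort(ord), 1:4)
  expect_lt(max(nearest_codeword(pts, cb)$dist2), 1e-12)

  X <- frame_descriptor_pool()
  cb2 <- kmeans_codebook(t(X[1:400, ]), m = 16, seed = 3)
  expect_true(all(diff(cb2$objective) <= 1e-9))
  expect_lte(cb2$objective[length(cb2$objective)], cb2$objective[1])
})

test_that("k-means recovers the means of two separated Gaussian blobs", {
  set.seed(5)
  n <- 400
  mu1 <- c(0, 0); mu2 <- c(10, 10); sigma <- 1
  X <- cbind(matrix(rnorm(2 * n / 2, sd = sigma), 2) + mu1,
             matrix(rnorm(2 * n / 2, sd = sigma), 2) + mu2)
  cb <- kmeans_codebook(X, m = 2, seed = 5)
  est <- cb$B[, order(cb$B[1, ])]
  tol <- 3 * sigma / sqrt(n / 2)
  expect_lt(sqrt(sum((est[, 1] - mu1)^2)), tol)
  expect_lt(sqrt(sum((est[, 2] - mu2)^2)), tol)

  # independent cross-check: stats::kmeans reaches the same optimum here
  ref <- stats::kmeans(t(X), centers = 2, nstart = 10,
                       algorithm = "Lloyd", iter.max = 100)
  ours <- cb$objective[length(cb$objective)]
  expect_lt(abs(ours - ref$tot.withinss) / ref$tot.withinss, 1e-6)
})

test_that("codebook learning is deterministic under a fixed seed", {
  X <- t(frame_descriptor_pool()[1:300, ])
  a <- kmeans_codebook(X, m = 8, seed = 7)
  b <- kmeans_codebook(X, m = 8, seed = 7)
  expect_identical(a$B, b$B)
})

test_that("exhaustive nearest-codeword search matches a brute-force loop", {
  set.seed(6)
  B <- matrix(rnorm(16 * 32), 16, 32)
  queries <- matrix(rnorm(16 * 1000), 16, 1000)
  got <- nearest_codeword(queries, B)
  brute <- apply(queries, 2, function(x) {
    d2 <- colSums((B - x)^2)
    which.min(d2)  # which.min takes the first (lowest-index) minimum
  })
  expect_identical(as.integer(got$index), as.integer(brute))

  # exact codeword hit and deterministic tie-breaking
  expect_equal(nearest_codeword(B[, 3], B)$index, 3)
  expect_equal(nearest_codeword(B[, 3], B)$dist2, 0)
  Bt <- cbind(c(0, 0), c(2, 0))
  expect_equal(nearest_codeword(c(1, 0), Bt)$index, 1)
  expect_error(nearest_codeword(rnorm(5), B), "dimension")
})

test_that("the binary vocabulary tree respects its depth and leaf budget", {
  X <- t(frame_descriptor_pool()[1:600, ])
  tr <- build_vocab_tree(X, branch = 2, depth = 8, seed = 1)
  expect_lte(tr$m, 256)
  expect_gte(tr$m, 2)

  # depth 1 reduces to plain 2-means quantization
  tr1 <- build_vocab_tree(X, branch = 2, depth = 1, seed = 2)
  expect_equal(tr1$m, 2)
  q_tree <- tree_quantize(X, tr1)
  q_flat <- nearest_codeword(X, tr1)$index
  expect_identical(as.integer(q_tree), as.integer(q_flat))

  # a single distinct point collapses to a one-leaf tree
  one <- matrix(rep(c(1, 2, 3), 10), 3)
  tr_one <- build_vocab_tree(one, branch = 2, depth = 4, seed = 3)
  expect_equal(tr_one$m, 1)
})

test_that("greedy tree descent agrees with exhaustive search on most queries", {
  X <- t(frame_descriptor_pool())
  tr <- build_vocab_tree(X[, 1:800], branch = 2, depth = 6, seed = 4)
  set.seed(4)
  q <- X[, sample(ncol(X), 1000)]
  agree <- mean(tree_quantize(q, tr) == nearest_codeword(q, tr)$index)
  expect_gte(agree, 0.8)
})

test_that("codebooks round-trip through their archive format", {
  X <- t(frame_descriptor_pool()[1:300, ])
  cb <- kmeans_codebook(X, m = 8, seed = 7)
  path <- tempfile(fileext = ".rds")
  write_codebook(cb, path)
  back <- read_codebook(path)
  expect_identical(back$B, cb$B)
  expect_equal(back$version, 1L)
  unlink(path)
})
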
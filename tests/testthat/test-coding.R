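test_that("soft-thresholding implements the shrinkage operator exactly", {
  expect_equal(soft_threshold(1.2, 0.5), 0.7)
  expect_equal(soft_threshold(-1.2, 0.5), -0.7)
  expect_equal(soft_threshold(0.3, 0.5), 0)
  expect_equal(soft_threshold(c(2, -2, 0), c(1, 1, 1)), c(1, -1, 0))
  expect_error(soft_threshold(1, -0.1))
})

test_that("locality weights decay from 1 with distance as exp(dist/sigma)", {
  B <- cbind(c(0, 0), c(3, 0), c(0, 4))
  w <- locality_weights(c(0, 0), B, sigma = 1)
  expect_equal(w, c(1, exp(3), exp(4)))
  expect_equal(locality_weights(c(3, 0), B, sigma = 3)[1], exp(1))
  expect_true(all(locality_weights(rnorm(2), B, sigma = 1e12) < 1 + 1e-9))
  expect_true(all(locality_weights(rnorm(2), B, sigma = 0.5) >= 1))
  expect_error(locality_weights(c(0, 0), B, sigma = 0), "positive")
})

test_that("Bag-of-Words codes are one-hot at the nearest codeword", {
  B <- cbind(c(0, 0), c(1, 0))
  code <- encode_bow(c(0.9, 0), B)
  expect_equal(code$c, c(0, 1))
  expect_equal(encode_bow(B[, 2], B)$c, c(0, 1))
  set.seed(1)
  Bm <- matrix(rnorm(4 * 16), 4, 16)
  for (r in 1:50) {
    x <- rnorm(4)
    idx <- which.min(colSums((Bm - x)^2))
    cv <- encode_bow(x, Bm)$c
    expect_equal(sum(cv), 1)
    expect_equal(which(cv == 1), idx)
  }
})

test_that("sparse coding solves the constrained l1 problem", {
  # lambda = 0 with invertible square B: equality-constrained least squares,
  # checked against the KKT system solved directly
  set.seed(2)
  B <- diag(3) + matrix(rnorm(9, sd = 0.1), 3, 3)
  x <- B %*% c(0.2, 0.3, 0.5)
  code <- encode_sc(drop(x), B, lambda = 0)
  kkt <- solve(rbind(cbind(2 * crossprod(B), rep(1, 3)), c(1, 1, 1, 0)),
               c(2 * crossprod(B, x), 1))
  expect_equal(code$c, kkt[1:3], tolerance = 1e-5)

  # x on a codeword with small lambda: near-indicator with objective <= lambda
  Bm <- matrix(rnorm(4 * 6), 4, 6)
  cj <- encode_sc(Bm[, 3], Bm, lambda = 1e-4)
  expect_lte(cj$objective, 1e-4 + 1e-8)
  expect_gt(cj$c[3], 0.99)

  # random instances against the enumeration oracle
  set.seed(3)
  for (r in 1:10) {
    inst <- random_coding_instance()
    code <- encode_sc(inst$x, inst$B, lambda = 0.1)
    o <- oracle_lsc_enum(inst$x, inst$B, 0.1, rep(1, 6))
    expect_lt(abs(code$objective - o$objective) / max(abs(o$objective), 1e-12),
              1e-4)
  }
})

test_that("LLC has the closed-form solution of the weighted ridge problem", {
  # symmetric two-codeword geometry: equal weights force c = (1/2, 1/2)
  B <- cbind(c(1, 0), c(-1, 0))
  code <- encode_llc(c(0, 1), B, lambda = 0.5, sigma = 1)
  expect_equal(code$c, c(0.5, 0.5), tolerance = 1e-10)

  # the penalty dominates as lambda grows; with uniform weights the code
  # tends to the weight-adjusted minimum-norm feasible point
  set.seed(4)
  Bm <- matrix(rnorm(3 * 5), 3, 5)
  x <- rnorm(3)
  cbig <- encode_llc(x, Bm, lambda = 1e8, sigma = 1e12)
  expect_equal(cbig$c, rep(1 / 5, 5), tolerance = 1e-4)

  # random instances against the exact null-space oracle
  for (r in 1:20) {
    inst <- random_coding_instance()
    d <- locality_weights(inst$x, inst$B, 1)
    code <- encode_llc(inst$x, inst$B, lambda = 0.1, sigma = 1)
    o <- oracle_llc_exact(inst$x, inst$B, 0.1, d)
    expect_lt(max(abs(code$c - o$c)), 1e-6)
    expect_lt(abs(code$objective - o$objective) /
                max(abs(o$objective), 1e-12), 1e-6)
  }
})

test_that("LSC reduces to its limiting special cases", {
  set.seed(5)
  inst <- random_coding_instance()

  # x sitting on a codeword with tiny lambda: indicator code
  cj <- encode_lsc(inst$B[, 2], inst$B, lambda = 1e-8, sigma = 1)
  expect_gt(cj$c[2], 1 - 1e-4)
  expect_lt(cj$objective, 1e-6)

  # uniform locality weights (sigma -> Inf) recover sparse coding
  sc <- encode_sc(inst$x, inst$B, lambda = 0.1)
  lsc_unif <- encode_lsc(inst$x, inst$B, lambda = 0.1, sigma = 1e12)
  expect_lt(max(abs(sc$c - lsc_unif$c)), 1e-6)
})

test_that("LSC solves the locality-weighted l1 problem (enumeration oracle)", {
  set.seed(6)
  for (r in 1:10) {
    inst <- random_coding_instance()
    d <- locality_weights(inst$x, inst$B, 1)
    code <- encode_lsc(inst$x, inst$B, lambda = 0.1, sigma = 1)
    o <- oracle_lsc_enum(inst$x, inst$B, 0.1, d)
    expect_lt(abs(code$objective - o$objective) / max(abs(o$objective), 1e-12),
              1e-4)
    expect_lt(abs(sum(code$c) - 1), 1e-6)
  }
})

test_that("shrinking sigma concentrates the code mass on the nearest basis", {
  set.seed(7)
  inst <- random_coding_instance(d = 4, m = 6)
  nn <- nearest_codeword(inst$x, inst$B)$index
  mass <- vapply(c(4, 2, 1, 0.5, 0.25), function(s) {
    cv <- encode_lsc(inst$x, inst$B, lambda = 0.1, sigma = s,
                     max_iter = 5000)$c
    abs(cv[nn]) / sum(abs(cv))
  }, numeric(1))
  expect_true(all(diff(mass) >= -1e-6))
  expect_gt(mass[length(mass)], 0.99)
})

test_that("K-NN restricted LSC brackets the full solution correctly", {
  set.seed(8)
  for (r in 1:20) {
    inst <- random_coding_instance(d = 4, m = 12)
    full <- encode_lsc(inst$x, inst$B, lambda = 0.1, sigma = 1,
                       max_iter = 5000)
    # K = m: identical to the full solver up to solver tolerance
    km <- encode_lsc_fast(inst$x, inst$B, lambda = 0.1, sigma = 1, K = 12,
                          max_iter = 5000)
    expect_lt(abs(km$objective - full$objective) /
                max(abs(full$objective), 1e-12), 1e-5)
    # K = 1: the only feasible point is the indicator at the nearest basis
    k1 <- encode_lsc_fast(inst$x, inst$B, lambda = 0.1, sigma = 1, K = 1)
    expect_equal(sum(k1$c != 0), 1)
    expect_equal(which(k1$c != 0), nearest_codeword(inst$x, inst$B)$index)
    # restriction can only raise the optimum (up to solver tolerance)
    k5 <- encode_lsc_fast(inst$x, inst$B, lambda = 0.1, sigma = 1, K = 5,
                          max_iter = 5000)
    expect_gte(k5$objective, full$objective - 1e-5)
  }
  expect_error(encode_lsc_fast(rnorm(4), matrix(rnorm(16), 4, 4), K = 9),
               "K must be")
})

test_that("every scheme returns sum-to-one codes on random instances", {
  set.seed(9)
  for (r in 1:10) {
    inst <- random_coding_instance()
    for (scheme in c("sc", "llc", "lsc", "lsc_fast")) {
      cv <- switch(scheme,
        sc = encode_sc(inst$x, inst$B, 0.1, max_iter = 5000),
        llc = encode_llc(inst$x, inst$B, 0.1, 1),
        lsc = encode_lsc(inst$x, inst$B, 0.1, 1, max_iter = 5000),
        lsc_fast = encode_lsc_fast(inst$x, inst$B, 0.1, 1, K = 3,
                                   max_iter = 5000))
      expect_lt(abs(sum(cv$c) - 1), 1e-6)
      expect_true(all(is.finite(cv$c)))
    }
  }
})

test_that("batch encoding preserves order and handles degenerate inputs", {
  set.seed(10)
  B <- matrix(rnorm(8 * 10), 8, 10)
  cb <- structure(list(B = B, m = 10, method = "kmeans", tree = NULL),
                  class = "cle_codebook")
  X <- matrix(rnorm(5 * 8), 5, 8)
  X[3, ] <- 0  # a constant-patch descriptor

  empty <- encode_set(X[0, , drop = FALSE], cb, coding_params("lsc"))
  expect_equal(ncol(empty$codes), 0)

  cs <- encode_set(X, cb, coding_params("lsc", max_iter = 5000))
  expect_equal(ncol(cs$codes), 5)
  for (j in c(1, 2, 4, 5)) {
    single <- encode_lsc(X[j, ], cb, lambda = 0.1, sigma = 1,
                         max_iter = 5000)
    expect_equal(cs$codes[, j], single$c, tolerance = 1e-8)
  }
  # the zero descriptor gets its Bag-of-Words code under every scheme
  expect_equal(sum(cs$codes[, 3] != 0), 1)
  expect_equal(which(cs$codes[, 3] != 0), nearest_codeword(rep(0, 8), cb)$index)

  bow <- encode_set(X, cb, coding_params("bow"))
  expect_true(all(colSums(bow$codes) == 1))
  expect_true(all(bow$codes %in% c(0, 1)))
})
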
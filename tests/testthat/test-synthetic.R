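test_that("degenerate generator settings produce the expected constant frames", {
  p <- texture_params(blob_density = 1e-9, noise_sigma = 0,
                      background_level = 40)
  f <- generate_frame(p, width = 64, height = 48, seed = 1)
  expect_true(all(f == 40L))
  expect_identical(dim(f), c(48L, 64L))

  b <- generate_blank_frame(64, 48, level = 255, noise_sigma = 0)
  expect_true(all(b == 255L))
  expect_error(generate_frame(p, width = 0, height = 48), "positive")
})

test_that("generation is deterministic under a fixed seed", {
  p <- texture_params()
  f1 <- generate_frame(p, 120, 100, seed = 11)
  f2 <- generate_frame(p, 120, 100, seed = 11)
  expect_identical(f1, f2)

  d1 <- generate_dataset(2, 5, width = 64, height = 48, seed = 5)
  d2 <- generate_dataset(2, 5, width = 64, height = 48, seed = 5)
  expect_identical(d1, d2)
})

test_that("all generated pixels are 8-bit gray values", {
  ds <- tiny_dataset()
  for (v in ds$videos)
    for (f in v$frames) {
      expect_true(is.integer(f))
      expect_true(all(f >= 0L & f <= 255L))
    }
})

test_that("dataset structure matches the requested size and labelling", {
  ds <- generate_dataset(2, 10, blank_fraction = 0, width = 64, height = 48,
                         seed = 2)
  expect_length(ds$videos, 4)
  expect_equal(n_frames(ds), 40)
  expect_equal(as.integer(table(ds$labels)), c(2L, 2L))
  for (v in ds$videos) expect_length(unique(v$label), 1)
  expect_error(generate_dataset(0, 10), "at least one")
})

test_that("blank frames are injected at the configured per-video rate", {
  ds <- generate_dataset(2, 20, blank_fraction = 0.1, width = 64, height = 48,
                         seed = 3)
  blanks <- vapply(ds$videos, function(v) sum(v$is_blank), integer(1))
  expect_true(all(blanks == 2L))
  # and the total count sits inside the central 99% binomial envelope
  total <- sum(blanks)
  expect_gte(total, qbinom(0.005, 80, 0.1))
  expect_lte(total, qbinom(0.995, 80, 0.1))

  ds0 <- generate_dataset(2, 10, blank_fraction = 0, width = 64, height = 48,
                          seed = 3)
  ents <- frame_entropies(ds0)
  expect_true(all(ents$entropy > 0))
})

test_that("the two default texture classes are separable by blob count", {
  ds <- tiny_dataset()
  counts <- lapply(levels(ds$labels), function(cl) {
    unlist(lapply(ds$videos[ds$labels == cl],
                  function(v) v$n_blobs[!v$is_blank]))
  })
  m_glio <- mean(counts[[1]])
  m_mening <- mean(counts[[2]])
  expect_gte(m_glio, 2 * m_mening)
})

test_that("textured frames carry more entropy than constant frames", {
  p <- texture_params(blob_density = 20, blob_radius_range = c(3, 6))
  f <- generate_frame(p, 464, 336, seed = 4)
  const <- matrix(40L, 336, 464)
  expect_gt(gray_entropy(f), gray_entropy(const))
})

test_that("datasets round-trip through the on-disk PNG layout", {
  ds <- generate_dataset(1, 3, blank_fraction = 0, width = 48, height = 40,
                         seed = 9)
  dir <- tempfile("cleds")
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  back <- read_dataset(dir)
  expect_equal(length(back$videos), length(ds$videos))
  expect_equal(back$videos[[1]]$frames[[2]], ds$videos[[1]]$frames[[2]],
               ignore_attr = TRUE)
  expect_equal(as.character(back$labels), as.character(ds$labels))
  unlink(dir, recursive = TRUE)
})
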
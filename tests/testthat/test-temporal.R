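test_that("majority voting picks the mode and honors the tie rule", {
  expect_equal(majority_vote(c("A", "A", "B")), "A")
  expect_equal(majority_vote(c("A", "B"), tie = "B"), "B")
  expect_equal(majority_vote(rep("C", 5)), "C")
  expect_equal(majority_vote(c("A", "B", "B", "A"), tie = "A"), "A")
  expect_error(majority_vote(character(0)), "empty")
})

test_that("smoothing degenerates gracefully (T = 1, constant, single frame)", {
  stream <- data.frame(video_id = "v1", frame_index = 0:9,
                       raw_label = rep(c("A", "B"), 5))
  s1 <- smooth_stream(stream, T = 1)
  expect_equal(as.character(s1$smoothed_label), stream$raw_label)

  const <- data.frame(video_id = "v1", frame_index = 0:9,
                      raw_label = rep("A", 10))
  for (T in c(1, 3, 5, 9, 11))
    expect_true(all(smooth_stream(const, T)$smoothed_label == "A"))

  single <- data.frame(video_id = "v1", frame_index = 0,
                       raw_label = "B")
  expect_equal(as.character(smooth_stream(single, T = 7)$smoothed_label), "B")
})

test_that("smoothing never invents a label absent from the window", {
  set.seed(1)
  stream <- data.frame(video_id = rep(c("v1", "v2"), each = 30),
                       frame_index = rep(0:29, 2),
                       raw_label = sample(c("A", "B", "C"), 60,
                                          replace = TRUE))
  sm <- smooth_stream(stream, T = 5)
  for (i in seq_len(nrow(sm))) {
    rows <- which(sm$video_id == sm$video_id[i])
    pos <- match(i, rows)
    win <- rows[max(1, pos - 2):min(length(rows), pos + 2)]
    expect_true(as.character(sm$smoothed_label[i]) %in%
                  stream$raw_label[win])
  }
})

test_that("the causal window only looks backwards", {
  stream <- data.frame(video_id = "v1", frame_index = 0:4,
                       raw_label = c("A", "A", "B", "B", "B"))
  sm <- smooth_stream(stream, T = 3, causal = TRUE)
  # frame 3 sees (A,B,B) -> B; frame 2 sees (A,A,B) -> A
  expect_equal(as.character(sm$smoothed_label), c("A", "A", "A", "B", "B"))
})

test_that("smoothed error under iid flips matches the binomial tail", {
  set.seed(2)
  n <- 10000
  p <- 0.3
  raw <- ifelse(runif(n) < p, "B", "A")
  stream <- data.frame(video_id = "v", frame_index = seq_len(n) - 1,
                       raw_label = raw, true_label = "A")
  sm <- smooth_stream(stream, T = 5)
  interior <- 3:(n - 2)
  err <- mean(sm$smoothed_label[interior] != "A")
  expect_lt(abs(err - majority_error_rate(p, 5)), 0.03)
  expect_equal(majority_error_rate(p, 5), 0.16308, tolerance = 1e-4)
})

test_that("error decreases with window length; clean streams stay perfect", {
  set.seed(3)
  n <- 6000
  raw <- ifelse(runif(n) < 0.3, "B", "A")
  stream <- data.frame(video_id = "v", frame_index = seq_len(n) - 1,
                       raw_label = raw, true_label = "A")
  sweep <- window_sweep(stream, T_values = c(1, 3, 5, 7, 9))
  err <- 1 - sweep$accuracy
  se <- sqrt(err * (1 - err) / n)
  for (k in seq_len(4))
    expect_lte(err[k + 1], err[k] + 3 * max(se[k], se[k + 1]))

  clean <- data.frame(video_id = "v", frame_index = 0:99,
                      raw_label = "A", true_label = "A")
  expect_true(all(window_sweep(clean, c(1, 3, 5))$accuracy == 1))
})
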
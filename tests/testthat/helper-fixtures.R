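# Shared fixtures, built lazily and memoised for the test run. The small
# dataset keeps unit tests fast; the full-size dataset (native 464 x 336
# frames, 10 videos per class x 100 frames, 10% blanks) reproduces the study
# conditions for the end-to-end checks and is only built when one of those
# tests runs.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env, inherits = FALSE))
    assign(key, builder(), envir = .fixture_env)
  get(key, envir = .fixture_env, inherits = FALSE)
}

tiny_dataset <- function() {
  memo("tiny", function() {
    generate_dataset(3, 10, blank_fraction = 0.2, width = 120, height = 100,
                     seed = 7)
  })
}

tiny_config <- function(scheme = "bow", ...) {
  cle_config(discard_fraction = 0.2, scheme = scheme, m = 16,
             sample_n = 1500, tree_depth = 4, window = 3, ...)
}

# descriptors from two textured frames, for codebook tests
frame_descriptor_pool <- function() {
  memo("pool", function() {
    d <- do.call(rbind, lapply(c(3, 4), function(s) {
      f <- generate_frame(texture_params(), width = 464, height = 336,
                          seed = s)
      extract_dense(f)$descriptors
    }))
    d[rowSums(abs(d)) > 0, ]
  })
}

full_dataset <- function() {
  memo("full", function() {
    generate_dataset(10, 100, blank_fraction = 0.1, seed = 20)
  })
}

# Building the cache frees the raw frames of the memoised full dataset:
# every later stage works from the cached descriptors and entropies.
full_cache <- function() {
  memo("full_cache", function() {
    cache <- precompute_descriptors(full_dataset())
    assign("full", drop_frames(full_dataset()), envir = .fixture_env)
    gc(verbose = FALSE)
    cache
  })
}
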
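#' Gray-level entropy of a frame
#'
#' Shannon entropy of the 256-bin gray-level histogram over \[0, 255\], in
#' bits (log base 2). Empty bins contribute 0, so a constant frame has
#' entropy 0 and a frame populating all 256 levels equally has entropy 8.
#' Low-entropy frames have very little contrast and are pruned before
#' classification.
#'
#' @param frame single-channel integer matrix with values in \[0, 255\].
#' @return Entropy in bits, a scalar in \[0, 8\].
#' @export
#' @examples
#' gray_entropy(matrix(40L, 10, 10))                 # 0
#' gray_entropy(matrix(c(0L, 255L), 10, 10))         # 1
gray_entropy <- function(frame) {
  if (length(dim(frame)) != 2)
    stop("frame must be a single-channel matrix; convert multi-channel input first")
  v <- as.integer(frame)
  if (anyNA(v) || any(v < 0L) || any(v > 255L))
    stop("frame values must be integers in [0, 255]")
  counts <- tabulate(v + 1L, nbins = 256L)
  p <- counts[counts > 0] / length(v)
  -sum(p * log2(p))
}

#' Per-frame entropies of a dataset
#'
#' @param dataset a `cle_dataset`.
#' @param cache optional [precompute_descriptors()] cache; entropies stored
#'   there are used for frames whose pixel data has been dropped
#'   ([drop_frames()]).
#' @return A data.frame with columns `video_id`, `frame_index`, `entropy`.
#' @export
frame_entropies <- function(dataset, cache = NULL) {
  do.call(rbind, lapply(dataset$videos, function(v) {
    e <- vapply(seq_along(v$frames), function(i) {
      if (!is.null(cache)) {
        rec <- cache_record(cache, v$video_id, v$frame_index[i])
        if (!is.null(rec)) return(rec$entropy)
      }
      if (is.null(v$frames[[i]]))
        stop("frame ", v$video_id, "#", v$frame_index[i],
             " has no pixel data and no cache entry")
      gray_entropy(v$frames[[i]])
    }, numeric(1))
    data.frame(video_id = v$video_id, frame_index = v$frame_index,
               entropy = e)
  }))
}

#' Estimate the entropy pruning threshold
#'
#' Returns the empirical quantile of the entropy distribution such that,
#' under the strictly-below prune rule of [prune_frames()], at most
#' `discard_fraction` of frames are discarded and frames at the threshold are
#' kept. On a ties-free sample of size N the discarded count is exactly
#' `floor(discard_fraction * N)`.
#'
#' @param entropies numeric vector of entropies, or a data.frame with an
#'   `entropy` column (as returned by [frame_entropies()]).
#' @param discard_fraction target discarded fraction, in \[0, 1).
#' @return Threshold in bits.
#' @export
#' @examples
#' estimate_entropy_threshold(1:10, 0.1)  # 2: exactly one value falls below
estimate_entropy_threshold <- function(entropies, discard_fraction = 0.1) {
  if (is.data.frame(entropies)) entropies <- entropies$entropy
  if (length(entropies) == 0) stop("no entropy records")
  stopifnot(discard_fraction >= 0, discard_fraction < 1)
  s <- sort(entropies)
  k <- floor(discard_fraction * length(s) + 1e-9)
  s[min(k + 1L, length(s))]
}

#' Prune low-entropy frames from a dataset
#'
#' Keeps exactly the frames whose gray-level entropy is at or above the
#' threshold (discard strictly below), preserving temporal order and original
#' frame indices. Videos losing all frames are kept as empty sequences so the
#' caller can detect them.
#'
#' @param dataset a `cle_dataset`.
#' @param threshold entropy threshold in bits (>= 0).
#' @param entropies optional precomputed [frame_entropies()] table.
#' @return The pruned `cle_dataset`.
#' @export
prune_frames <- function(dataset, threshold, entropies = NULL) {
  stopifnot(threshold >= 0)
  if (is.null(entropies)) entropies <- frame_entropies(dataset)
  dataset$videos <- lapply(dataset$videos, function(v) {
    sub <- entropies[entropies$video_id == v$video_id, ]
    e <- sub$entropy[match(v$frame_index, sub$frame_index)]
    keep <- e >= threshold
    v$frames <- v$frames[keep]
    v$frame_index <- v$frame_index[keep]
    v$is_blank <- v$is_blank[keep]
    v$n_blobs <- v$n_blobs[keep]
    v
  })
  dataset
}
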
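#' Majority vote over a window of labels
#'
#' Returns the most frequent label in the window. Ties resolve to `tie`,
#' which defaults to the label at the window's centre position — i.e. the
#' current frame keeps its own raw label when the vote is inconclusive.
#'
#' @param labels non-empty vector of class labels.
#' @param tie label returned on a tie (default: centre element).
#' @return A single label (same type as `labels`).
#' @export
#' @examples
#' majority_vote(c("A", "A", "B"))  # "A"
majority_vote <- function(labels, tie = NULL) {
  if (length(labels) == 0) stop("empty voting window")
  if (is.null(tie)) tie <- labels[ceiling(length(labels) / 2)]
  tab <- table(labels)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1) {
    out <- winners
  } else {
    out <- as.character(tie)
  }
  if (is.factor(labels)) factor(out, levels = levels(labels))
  else if (is.numeric(labels)) as.numeric(out)
  else out
}

#' Smooth a prediction stream by sliding-window majority voting
#'
#' For each retained frame of each video, takes the window of `T` raw labels
#' surrounding it (centred by default, truncated at the stream boundaries —
#' never padded) and assigns the majority label; ties fall back to the
#' frame's own raw label. The window slides over the pruned stream in its
#' retained order. `T = 1` returns the raw labels unchanged. With
#' `causal = TRUE` the window is the current frame plus the `T - 1`
#' preceding ones, the variant usable in real time during surgery.
#'
#' @param stream data.frame with columns `video_id`, `frame_index`,
#'   `raw_label` (and optionally `raw_score`), ordered within videos.
#' @param T window length (>= 1; odd recommended for the centred variant).
#' @param causal logical; use the trailing window instead of the centred one.
#' @return The stream with an added/replaced `smoothed_label` column.
#' @export
smooth_stream <- function(stream, T = 5, causal = FALSE) {
  stopifnot(T >= 1, is.data.frame(stream))
  lev <- levels(as.factor(stream$raw_label))
  out <- stream
  out$smoothed_label <- factor(rep(NA_character_, nrow(stream)), levels = lev)
  for (vid in unique(stream$video_id)) {
    rows <- which(stream$video_id == vid)
    raw <- as.character(stream$raw_label[rows])
    n <- length(raw)
    sm <- character(n)
    back <- if (causal) T - 1L else floor((T - 1) / 2)
    fwd <- if (causal) 0L else ceiling((T - 1) / 2)
    for (i in seq_len(n)) {
      w <- raw[max(1L, i - back):min(n, i + fwd)]
      sm[i] <- majority_vote(w, tie = raw[i])
    }
    out$smoothed_label[rows] <- factor(sm, levels = lev)
  }
  out
}

#' Accuracy versus voting-window length
#'
#' Applies [smooth_stream()] over a grid of window lengths and tabulates the
#' frame-level accuracy against the true labels, reproducing the qualitative
#' accuracy-vs-T curve on data with known ground truth.
#'
#' @param stream data.frame with columns `video_id`, `frame_index`,
#'   `raw_label`, `true_label`.
#' @param T_values integer vector of window lengths (default odd 1..9).
#' @param causal passed to [smooth_stream()].
#' @return data.frame with columns `T` and `accuracy`.
#' @export
window_sweep <- function(stream, T_values = c(1, 3, 5, 7, 9),
                         causal = FALSE) {
  stopifnot("true_label" %in% names(stream))
  acc <- vapply(T_values, function(tt) {
    sm <- smooth_stream(stream, T = tt, causal = causal)
    mean(as.character(sm$smoothed_label) == as.character(sm$true_label))
  }, numeric(1))
  data.frame(T = T_values, accuracy = acc)
}
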
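#' Pool descriptor codes into a frame feature
#'
#' `sum_normalized`: elementwise sum of codes followed by L1 normalisation —
#' the occurrence histogram appropriate for Bag-of-Words. `max_abs`:
#' elementwise maximum of absolute values — the standard companion of signed
#' sparse codes, for which occurrence counting is meaningless. Pooling is
#' permutation-invariant over descriptors. An empty code set pools to the
#' zero vector (with a warning).
#'
#' @param codes a `"code_set"` from [encode_set()], or an m x n matrix of
#'   codes in columns.
#' @param method `"sum_normalized"` or `"max_abs"`.
#' @return Numeric feature vector of length m.
#' @export
pool_codes <- function(codes, method = c("sum_normalized", "max_abs")) {
  method <- match.arg(method)
  C <- if (inherits(codes, "code_set")) codes$codes else as.matrix(codes)
  if (ncol(C) == 0) {
    warning("empty code set; pooling to zero vector")
    return(numeric(nrow(C)))
  }
  if (method == "sum_normalized") {
    h <- rowSums(C)
    s <- sum(abs(h))
    if (s > 0) h / s else h
  } else {
    apply(abs(C), 1, max)
  }
}

default_pooling <- function(scheme) {
  if (scheme == "bow") "sum_normalized" else "max_abs"
}

#' Train the frame classifier
#'
#' Features are standardised (centre/scale estimated on the training split
#' and stored in the model) and fed to a support vector machine
#' (`svm_linear` with cost 1 by default, or `svm_rbf`) or, alternatively, a
#' random forest. Training is deterministic under `seed`.
#'
#' @param features numeric matrix, one frame feature per row.
#' @param labels factor (or coercible) of per-frame class labels; at least
#'   two classes must be present.
#' @param classifier `"svm_linear"`, `"svm_rbf"`, or `"random_forest"`.
#' @param cost SVM cost parameter.
#' @param seed optional integer seed.
#' @return An object of class `"cle_classifier"` holding the fitted decision
#'   function, the label levels, and the feature scaling.
#' @export
train_classifier <- function(features, labels,
                             classifier = c("svm_linear", "svm_rbf",
                                            "random_forest"),
                             cost = 1, seed = NULL) {
  classifier <- match.arg(classifier)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2)
    stop("training labels contain a single class")
  stopifnot(nrow(features) == length(labels))
  if (!is.null(seed)) set.seed(seed)
  ctr <- colMeans(features)
  scl <- apply(features, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- scale(features, center = ctr, scale = scl)
  fit <- switch(classifier,
    svm_linear = e1071::svm(Xs, labels, kernel = "linear", cost = cost,
                            scale = FALSE),
    svm_rbf = e1071::svm(Xs, labels, kernel = "radial", cost = cost,
                         scale = FALSE),
    random_forest = {
      if (!requireNamespace("randomForest", quietly = TRUE))
        stop("random_forest requires the randomForest package")
      randomForest::randomForest(Xs, labels)
    })
  structure(list(fit = fit, classifier = classifier,
                 center = ctr, scale = scl, levels = levels(labels)),
            class = "cle_classifier")
}

#' Predict frame labels from pooled features
#'
#' @param model a `"cle_classifier"`.
#' @param feature a single feature vector or a matrix of features in rows.
#' @return A data.frame with columns `label` (factor) and `score` (signed
#'   SVM decision value, or positive-class vote fraction for the forest).
#' @export
predict_frame <- function(model, feature) {
  X <- if (is.null(dim(feature))) matrix(feature, nrow = 1) else feature
  if (ncol(X) != length(model$center))
    stop("feature length does not match the trained model")
  Xs <- scale(X, center = model$center, scale = model$scale)
  if (model$classifier == "random_forest") {
    if (!requireNamespace("randomForest", quietly = TRUE))
      stop("random_forest requires the randomForest package")
    pr <- predict(model$fit, Xs, type = "prob")
    lab <- factor(model$levels[max.col(pr, ties.method = "first")],
                  levels = model$levels)
    score <- pr[, 1]
  } else {
    pr <- predict(model$fit, Xs, decision.values = TRUE)
    lab <- factor(as.character(pr), levels = model$levels)
    score <- drop(attr(pr, "decision.values"))
  }
  data.frame(label = lab, score = as.numeric(score))
}

#' Video-grouped stratified train/test splits
#'
#' Splits at the video level (no video ever appears on both sides), holding
#' out `1 - train_fraction` of the videos of each class. Because videos may
#' have unequal retained-frame counts, candidate splits are re-drawn (up to
#' 100 times) until the test-side frame fraction is within 5 percentage
#' points of the target; otherwise the closest draw is kept.
#'
#' @param video_labels factor of per-video class labels.
#' @param video_ids character vector of video ids (same order).
#' @param frames_per_video integer vector of retained frame counts.
#' @param train_fraction fraction of videos per class used for training.
#' @param n_splits number of independent random splits.
#' @param seed integer seed.
#' @return List of `n_splits` lists with elements `train` and `test`
#'   (character vectors of video ids).
#' @export
video_grouped_splits <- function(video_labels, video_ids, frames_per_video,
                                 train_fraction = 0.8, n_splits = 5,
                                 seed = 1) {
  video_labels <- as.factor(video_labels)
  stopifnot(length(video_ids) == length(video_labels),
            length(frames_per_video) == length(video_labels),
            train_fraction > 0, train_fraction < 1)
  if (any(table(video_labels) < 2))
    stop("need at least 2 videos per class for grouped splitting")
  set.seed(seed)
  target <- 1 - train_fraction
  lapply(seq_len(n_splits), function(s) {
    best <- NULL
    best_gap <- Inf
    for (try in 1:100) {
      test <- unlist(lapply(levels(video_labels), function(cl) {
        ids <- video_ids[video_labels == cl]
        n_test <- max(1L, round((1 - train_fraction) * length(ids)))
        sample(ids, n_test)
      }))
      frac <- sum(frames_per_video[video_ids %in% test]) /
        sum(frames_per_video)
      gap <- abs(frac - target)
      if (gap < best_gap) { best <- test; best_gap <- gap }
      if (gap <= 0.05) break
    }
    list(train = setdiff(video_ids, best), test = best)
  })
}

#' Classification metrics from a confusion matrix
#'
#' With the malignant class (glioblastoma) as positive:
#' accuracy = (TP+TN)/(TP+TN+FP+FN), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP).
#'
#' @param truth,predicted factors with identical levels.
#' @param positive the positive-class label (default `"glioblastoma"`; falls
#'   back to the first level if absent).
#' @return List with `accuracy`, `sensitivity`, `specificity`, `confusion`
#'   (2 x 2 table, truth in rows).
#' @export
confusion_metrics <- function(truth, predicted, positive = "glioblastoma") {
  truth <- as.factor(truth)
  predicted <- factor(predicted, levels = levels(truth))
  if (!positive %in% levels(truth)) positive <- levels(truth)[1]
  tp <- sum(truth == positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  tn <- sum(truth != positive & predicted != positive)
  fp <- sum(truth != positive & predicted == positive)
  list(accuracy = (tp + tn) / max(1, tp + tn + fp + fn),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       confusion = table(truth = truth, predicted = predicted))
}
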
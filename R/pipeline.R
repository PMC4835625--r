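#' Pipeline configuration
#'
#' All stage parameters of the classification pipeline in one validated,
#' YAML-serialisable object. Defaults: 10% entropy-based frame discarding;
#' dense 20 x 20 px patches at 10 px spacing; vocabulary of m = 256 codewords
#' learned from 100,000 sampled descriptors (binary vocabulary tree of depth
#' 8 for Bag-of-Words, flat k-means for the sparse coders); voting window
#' T = 5.
#'
#' @param discard_fraction entropy pruning fraction, in \[0, 1).
#' @param patch_size,spacing dense SIFT geometry in px.
#' @param m vocabulary size.
#' @param sample_n descriptors sampled for codebook learning.
#' @param tree_branch,tree_depth vocabulary-tree shape (Bag-of-Words path).
#' @param scheme coding scheme: `"bow"`, `"sc"`, `"llc"`, `"lsc"`,
#'   `"lsc_fast"`.
#' @param lambda,sigma,K,mu,tol,max_iter coding parameters, see
#'   [coding_params()].
#' @param pooling `"sum_normalized"`, `"max_abs"`, or `NULL` to choose by
#'   scheme (histogram pooling for BoW, max-abs for the signed coders).
#' @param classifier,cost classifier choice and SVM cost, see
#'   [train_classifier()].
#' @param window,causal majority-voting window length and variant, see
#'   [smooth_stream()].
#' @return An object of class `"cle_config"`.
#' @export
cle_config <- function(discard_fraction = 0.1, patch_size = 20, spacing = 10,
                       m = 256, sample_n = 100000, tree_branch = 2,
                       tree_depth = 8,
                       scheme = c("bow", "sc", "llc", "lsc", "lsc_fast"),
                       lambda = 0.1, sigma = 1, K = 5, mu = 0.1, tol = 1e-6,
                       max_iter = 500, pooling = NULL,
                       classifier = c("svm_linear", "svm_rbf",
                                      "random_forest"),
                       cost = 1, window = 5, causal = FALSE) {
  scheme <- match.arg(scheme)
  classifier <- match.arg(classifier)
  stopifnot(discard_fraction >= 0, discard_fraction < 1,
            patch_size >= 4, spacing >= 1, m >= 2, sample_n >= m,
            tree_branch >= 2, tree_depth >= 1, window >= 1)
  if (is.null(pooling)) pooling <- default_pooling(scheme)
  pooling <- match.arg(pooling, c("sum_normalized", "max_abs"))
  structure(list(discard_fraction = discard_fraction,
                 patch_size = patch_size, spacing = spacing, m = m,
                 sample_n = sample_n, tree_branch = tree_branch,
                 tree_depth = tree_depth, scheme = scheme, lambda = lambda,
                 sigma = sigma, K = K, mu = mu, tol = tol,
                 max_iter = max_iter, pooling = pooling,
                 classifier = classifier, cost = cost, window = window,
                 causal = causal),
            class = "cle_config")
}

#' @export
print.cle_config <- function(x, ...) {
  cat("CLE pipeline config: scheme =", x$scheme, "| m =", x$m,
      "| patch", x$patch_size, "/ spacing", x$spacing,
      "| discard", x$discard_fraction, "| T =", x$window, "\n")
  invisible(x)
}

#' Write / read a pipeline configuration as YAML
#'
#' Round-trips exactly: `read_config(write_config(cfg, f))` equals `cfg`.
#'
#' @param config a `cle_config`.
#' @param path YAML file path.
#' @return `path`, or the restored `cle_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(cle_config, vals)
}

# Polynomial rolling hash of the serialized config: a dependency-free
# fingerprint stored in every artifact so archive/config mismatches are
# detectable.
config_hash <- function(config) {
  bytes <- as.integer(serialize(unclass(config), NULL, version = 3))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

coding_params_from_config <- function(config) {
  coding_params(scheme = config$scheme, lambda = config$lambda,
                sigma = config$sigma, K = config$K, mu = config$mu,
                tol = config$tol, max_iter = config$max_iter)
}

# Keep only the named videos.
subset_dataset <- function(dataset, video_ids) {
  keep <- vapply(dataset$videos, function(v) v$video_id %in% video_ids,
                 logical(1))
  dataset$videos <- dataset$videos[keep]
  dataset$labels <- droplevels(dataset$labels[keep])
  dataset
}

#' Permute video labels (permutation-null control)
#'
#' Randomly reassigns the per-video class labels. Frame content is
#' untouched, so any classifier accuracy above chance on the permuted data
#' indicates leakage.
#'
#' @param dataset a `cle_dataset`.
#' @param seed integer seed.
#' @return The dataset with shuffled labels.
#' @export
permute_labels <- function(dataset, seed = 1) {
  set.seed(seed)
  perm <- sample(seq_along(dataset$videos))
  labs <- as.character(dataset$labels)[perm]
  for (i in seq_along(dataset$videos)) dataset$videos[[i]]$label <- labs[i]
  dataset$labels <- factor(labs, levels = levels(dataset$labels))
  dataset
}

# Stream over the frames of the given videos, extract dense SIFT, and draw a
# per-frame-stratified random sample of non-zero descriptors of total size
# ~sample_n (exact after the final subsample). Avoids materialising all
# descriptors of the training set at once.
collect_descriptor_sample <- function(dataset, video_ids, config, seed,
                                      cache = NULL) {
  set.seed(seed)
  vids <- Filter(function(v) v$video_id %in% video_ids, dataset$videos)
  nf <- sum(vapply(vids, function(v) length(v$frames), integer(1)))
  if (nf == 0) stop("no frames available for codebook learning")
  quota <- ceiling(1.3 * config$sample_n / nf)
  pool <- vector("list", nf)
  k <- 0L
  cache_ok <- !is.null(cache) && cache$patch_size == config$patch_size &&
    cache$spacing == config$spacing
  for (v in vids) {
    for (i in seq_along(v$frames)) {
      k <- k + 1L
      rec <- if (cache_ok) cache_record(cache, v$video_id, v$frame_index[i])
             else NULL
      if (!is.null(rec)) {
        pool[[k]] <- cache_sample_rows(rec, quota)
        next
      }
      d <- frame_descriptors(v$frames[[i]], v$video_id, v$frame_index[i],
                             config, cache)
      nz <- which(rowSums(abs(d)) > 0)
      if (length(nz) == 0) next
      take <- nz[sample.int(length(nz), min(quota, length(nz)))]
      pool[[k]] <- d[take, , drop = FALSE]
    }
  }
  pool <- do.call(rbind, pool)
  if (is.null(pool) || nrow(pool) == 0)
    stop("no non-zero descriptors found in the training frames")
  sample_descriptors(pool, min(config$sample_n, nrow(pool)))
}

train_codebook <- function(sample, config, seed) {
  if (config$scheme == "bow") {
    # leaf count is branch^depth, so the requested vocabulary size caps depth
    depth <- min(config$tree_depth,
                 ceiling(log(config$m, config$tree_branch)))
    build_vocab_tree(sample, branch = config$tree_branch, depth = depth,
                     seed = seed)
  } else {
    kmeans_codebook(sample, m = config$m, seed = seed)
  }
}

# Per-frame features for the given videos: extract -> encode -> pool.
# Returns features matrix plus frame bookkeeping and mean encode time.
dataset_features <- function(dataset, config, codebook,
                             video_ids = NULL, cache = NULL) {
  params <- coding_params_from_config(config)
  vids <- if (is.null(video_ids)) dataset$videos
          else Filter(function(v) v$video_id %in% video_ids, dataset$videos)
  total <- sum(vapply(vids, function(v) length(v$frames), integer(1)))
  feats <- vector("list", total)
  vid_col <- character(total)
  idx_col <- integer(total)
  lab_col <- character(total)
  k <- 0L
  t_enc <- 0
  for (v in vids) {
    for (i in seq_along(v$frames)) {
      k <- k + 1L
      dset <- frame_descriptors(v$frames[[i]], v$video_id, v$frame_index[i],
                                config, cache)
      t0 <- proc.time()[3]
      codes <- encode_set(dset, codebook, params)
      t_enc <- t_enc + (proc.time()[3] - t0)
      feats[[k]] <- pool_codes(codes, config$pooling)
      vid_col[k] <- v$video_id
      idx_col[k] <- v$frame_index[i]
      lab_col[k] <- as.character(v$label)
    }
  }
  list(features = do.call(rbind, feats),
       frames = data.frame(video_id = vid_col, frame_index = idx_col,
                           label = lab_col),
       mean_encode_time = if (k > 0) t_enc / k else NA_real_)
}

#' Train the full classification pipeline
#'
#' Runs the offline stages end to end on a labelled dataset: estimate the
#' entropy pruning threshold on the training frames, prune, learn the visual
#' codebook from a random sample of training descriptors, encode and pool
#' every retained frame, and train the frame classifier. Returns a fitted
#' model object; `predict()` applies the matching online stages to new
#' video.
#'
#' @param dataset a labelled `cle_dataset`.
#' @param config a [cle_config()].
#' @param seed integer seed controlling sampling, codebook initialisation
#'   and classifier training.
#' @param cache optional [precompute_descriptors()] cache for the dataset's
#'   frames.
#' @return An object of class `"cle_model"`.
#' @export
#' @seealso [predict.cle_model()], [cle_evaluate()]
cle_train <- function(dataset, config = cle_config(), seed = 1,
                      cache = NULL) {
  stopifnot(inherits(dataset, "cle_dataset"), inherits(config, "cle_config"))
  labs <- vapply(dataset$videos, function(v) as.character(v$label),
                 character(1))
  if (anyNA(labs)) {
    bad <- dataset$videos[[which(is.na(labs))[1]]]$video_id
    stop("missing label for video ", bad)
  }
  ent <- frame_entropies(dataset, cache)
  threshold <- estimate_entropy_threshold(ent, config$discard_fraction)
  pruned <- prune_frames(dataset, threshold, ent)

  sample <- collect_descriptor_sample(pruned,
                                      vapply(pruned$videos, `[[`, "",
                                             "video_id"),
                                      config, seed, cache)
  codebook <- train_codebook(sample, config, seed)

  fx <- dataset_features(pruned, config, codebook, cache = cache)
  clf <- train_classifier(fx$features, fx$frames$label,
                          classifier = config$classifier,
                          cost = config$cost, seed = seed)
  structure(list(config = config,
                 config_hash = config_hash(config),
                 threshold = threshold,
                 codebook = codebook,
                 classifier = clf,
                 levels = clf$levels,
                 n_train_frames = nrow(fx$frames),
                 frame_dim = dim(dataset$videos[[1]]$frames[[1]]),
                 provenance = list(
                   r_version = as.character(getRversion()),
                   package_version =
                     as.character(utils::packageVersion("endocode")),
                   n_videos = length(dataset$videos)),
                 mean_encode_time = fx$mean_encode_time,
                 seed = seed,
                 version = 1L),
            class = "cle_model")
}

#' @export
print.cle_model <- function(x, ...) {
  cat("CLE tissue classification model\n")
  cat("  scheme:", x$config$scheme, "| pooling:", x$config$pooling,
      "| classifier:", x$config$classifier, "\n")
  cat("  vocabulary: m =", x$codebook$m, "(", x$codebook$method, ")\n")
  cat("  entropy threshold:", format(x$threshold, digits = 4), "bits",
      "| trained on", x$n_train_frames, "frames\n")
  cat("  classes:", paste(x$levels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cle_model <- function(object, ...) {
  print(object)
  cat("  config hash:", object$config_hash, "| seed:", object$seed, "\n")
  cat("  mean per-frame encode time:",
      format(object$mean_encode_time, digits = 3), "s\n")
  invisible(object)
}

#' Classify new video with a trained model
#'
#' Online stages: prune frames below the archived entropy threshold, extract
#' dense descriptors (the grid adapts to the input resolution, with a
#' warning if it differs from a 464 x 336 native frame), encode with the
#' archived codebook, pool, classify, and smooth the per-video label stream
#' by majority voting.
#'
#' @param object a `"cle_model"`.
#' @param newdata a `cle_dataset` (labels may be absent).
#' @param window voting window length (default: the trained config's).
#' @param causal use the trailing (real-time) window variant.
#' @param ... unused.
#' @return A data.frame prediction stream with columns `video_id`,
#'   `frame_index`, `raw_label`, `raw_score`, `smoothed_label`. Frames
#'   pruned as uninformative are absent; a video losing all frames yields no
#'   rows (with a warning).
#' @export
predict.cle_model <- function(object, newdata, window = NULL, causal = NULL,
                              ...) {
  predict_stream(object, newdata, window, causal, cache = NULL)
}

predict_stream <- function(object, newdata, window = NULL, causal = NULL,
                           cache = NULL) {
  stopifnot(inherits(newdata, "cle_dataset"))
  if (is.null(window)) window <- object$config$window
  if (is.null(causal)) causal <- object$config$causal
  pruned <- prune_frames(newdata, object$threshold,
                         frame_entropies(newdata, cache))
  empty <- vapply(pruned$videos, function(v) length(v$frames) == 0,
                  logical(1))
  if (any(empty))
    warning("all frames pruned as uninformative in video(s): ",
            paste(vapply(pruned$videos[empty], `[[`, "", "video_id"),
                  collapse = ", "))
  pruned$videos <- pruned$videos[!empty]
  if (length(pruned$videos) == 0)
    return(data.frame(video_id = character(0), frame_index = integer(0),
                      raw_label = character(0), raw_score = numeric(0),
                      smoothed_label = character(0)))
  d <- dim(pruned$videos[[1]]$frames[[1]])
  if (!is.null(d) && !is.null(object$frame_dim) &&
      !identical(object$frame_dim, d))
    warning("input resolution differs from training; dense grid adapts")
  fx <- dataset_features(pruned, object$config, object$codebook,
                         cache = cache)
  pr <- predict_frame(object$classifier, fx$features)
  stream <- data.frame(video_id = fx$frames$video_id,
                       frame_index = fx$frames$frame_index,
                       raw_label = pr$label,
                       raw_score = pr$score)
  smooth_stream(stream, T = window, causal = causal)
}

#' Save / load a trained model archive
#'
#' Single-file archive embedding the codebook, coding parameters, pooling
#' method, classifier, label map, config hash and format version.
#'
#' @param model a `"cle_model"`.
#' @param path file path.
#' @return `path`, or the restored model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cle_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "cle_model") || is.null(m$version))
    stop("not a model archive")
  m
}

#' Evaluate the pipeline with video-grouped cross-validation
#'
#' The evaluation protocol of the method: 80/20 train/test splits drawn at
#' the video level (no frame of a training video ever enters the test side),
#' stratified by class, repeated `n_splits` times with independent draws.
#' Each split retrains the entire pipeline — entropy threshold, codebook and
#' classifier are estimated on the training videos only — and reports
#' frame-level accuracy, sensitivity and specificity (glioblastoma as the
#' positive class) before and after majority-vote smoothing.
#'
#' @param dataset a labelled `cle_dataset`.
#' @param config a [cle_config()].
#' @param n_splits number of repeated splits (default 5).
#' @param train_fraction fraction of videos per class for training.
#' @param seed integer seed.
#' @param cache optional [precompute_descriptors()] cache; built internally
#'   when `NULL`. Pass a prebuilt cache to share extraction work across
#'   evaluations of different schemes on the same dataset.
#' @return An object of class `"cle_eval"`: per-split metric data.frame,
#'   mean and sd of each metric, pooled confusion matrices, the split
#'   definitions, and the mean per-frame encoding time diagnostic.
#' @export
cle_evaluate <- function(dataset, config = cle_config(), n_splits = 5,
                         train_fraction = 0.8, seed = 1, cache = NULL) {
  stopifnot(inherits(dataset, "cle_dataset"))
  if (is.null(cache))
    cache <- precompute_descriptors(dataset, config$patch_size,
                                    config$spacing)
  vid_ids <- vapply(dataset$videos, `[[`, "", "video_id")
  vid_labels <- dataset$labels
  fpv <- vapply(dataset$videos, function(v) length(v$frames), integer(1))
  splits <- video_grouped_splits(vid_labels, vid_ids, fpv,
                                 train_fraction = train_fraction,
                                 n_splits = n_splits, seed = seed)
  per_split <- vector("list", n_splits)
  confusions <- vector("list", n_splits)
  enc_times <- numeric(n_splits)
  for (s in seq_len(n_splits)) {
    tr <- subset_dataset(dataset, splits[[s]]$train)
    te <- subset_dataset(dataset, splits[[s]]$test)
    model <- cle_train(tr, config, seed = seed + s, cache = cache)
    stream <- suppressWarnings(predict_stream(model, te, cache = cache))
    truth_map <- stats::setNames(
      vapply(te$videos, function(v) as.character(v$label), character(1)),
      vapply(te$videos, `[[`, "", "video_id"))
    truth <- factor(truth_map[stream$video_id], levels = model$levels)
    raw <- confusion_metrics(truth, stream$raw_label)
    smo <- confusion_metrics(truth, stream$smoothed_label)
    per_split[[s]] <- data.frame(split = s,
                                 accuracy = raw$accuracy,
                                 sensitivity = raw$sensitivity,
                                 specificity = raw$specificity,
                                 accuracy_smoothed = smo$accuracy,
                                 sensitivity_smoothed = smo$sensitivity,
                                 specificity_smoothed = smo$specificity)
    confusions[[s]] <- list(raw = raw$confusion, smoothed = smo$confusion)
    enc_times[s] <- model$mean_encode_time
  }
  tab <- do.call(rbind, per_split)
  metrics <- setdiff(names(tab), "split")
  structure(list(per_split = tab,
                 mean = colMeans(tab[metrics]),
                 sd = apply(tab[metrics], 2, stats::sd),
                 confusions = confusions,
                 splits = splits,
                 config = config,
                 config_hash = config_hash(config),
                 mean_encode_time = mean(enc_times),
                 seed = seed),
            class = "cle_eval")
}

#' @export
print.cle_eval <- function(x, ...) {
  cat("Video-grouped evaluation (", nrow(x$per_split), " splits, scheme = ",
      x$config$scheme, ")\n", sep = "")
  m <- x$mean; s <- x$sd
  for (k in names(m))
    cat(sprintf("  %-22s %.4f +/- %.4f\n", k, m[k], s[k]))
  cat("  mean per-frame encode time:",
      format(x$mean_encode_time, digits = 3), "s\n")
  invisible(x)
}

#' @export
plot.cle_eval <- function(x, ...) {
  tab <- x$per_split
  graphics::matplot(tab$split, tab[, c("accuracy", "accuracy_smoothed")],
                    type = "b", pch = c(1, 19), lty = 1,
                    xlab = "split", ylab = "accuracy", ylim = c(0, 1), ...)
  graphics::legend("bottomright", c("raw", "smoothed"), pch = c(1, 19))
  invisible(x)
}

#' Write an evaluation report to JSON and CSV
#'
#' @param eval_report a `"cle_eval"`.
#' @param prefix path prefix; writes `<prefix>.json` and `<prefix>.csv`.
#' @return The two paths, invisibly.
#' @export
write_eval_report <- function(eval_report, prefix) {
  stopifnot(inherits(eval_report, "cle_eval"))
  jd <- list(config = unclass(eval_report$config),
             config_hash = eval_report$config_hash,
             mean = as.list(eval_report$mean),
             sd = as.list(eval_report$sd),
             per_split = eval_report$per_split,
             mean_encode_time = eval_report$mean_encode_time,
             seed = eval_report$seed)
  jp <- paste0(prefix, ".json")
  cp <- paste0(prefix, ".csv")
  jsonlite::write_json(jd, jp, auto_unbox = TRUE, digits = NA)
  utils::write.csv(eval_report$per_split, cp, row.names = FALSE)
  invisible(c(jp, cp))
}
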
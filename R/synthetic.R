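#' Texture parameters for one synthetic tissue class
#'
#' Describes the cellular texture of one simulated tumour class: bright
#' nucleus-like blobs of a given density and size range on a dark background,
#' with additive Gaussian pixel noise. The two default classes emulate the
#' qualitative contrast between hypercellular glioblastoma (many small nuclei)
#' and the more uniform meningioma texture (fewer, larger structures).
#'
#' @param blob_density expected number of blobs per 100x100 px area (> 0).
#' @param blob_radius_range length-2 numeric, min/max blob radius in px
#'   (min >= 1).
#' @param blob_intensity_range length-2 numeric, min/max blob peak gray value
#'   in \[0, 255\].
#' @param background_level background gray value in \[0, 255\].
#' @param noise_sigma standard deviation of additive Gaussian pixel noise, in
#'   gray values.
#' @return An object of class `"texture_params"`.
#' @export
#' @examples
#' texture_params(blob_density = 25, blob_radius_range = c(2, 4))
texture_params <- function(blob_density = 25,
                           blob_radius_range = c(2, 4),
                           blob_intensity_range = c(120, 220),
                           background_level = 30,
                           noise_sigma = 8) {
  stopifnot(blob_density > 0,
            length(blob_radius_range) == 2,
            blob_radius_range[1] >= 1,
            blob_radius_range[1] <= blob_radius_range[2],
            length(blob_intensity_range) == 2,
            blob_intensity_range[1] >= 0,
            blob_intensity_range[1] <= blob_intensity_range[2],
            blob_intensity_range[2] <= 255,
            background_level >= 0, background_level <= 255,
            noise_sigma >= 0)
  structure(list(blob_density = blob_density,
                 blob_radius_range = as.numeric(blob_radius_range),
                 blob_intensity_range = as.numeric(blob_intensity_range),
                 background_level = background_level,
                 noise_sigma = noise_sigma),
            class = "texture_params")
}

#' Default per-class texture parameters
#'
#' Class `"glioblastoma"`: dense small blobs (density 25 per 100x100 px,
#' radius 2--4). Class `"meningioma"`: sparse large blobs (density 8,
#' radius 6--12). Mean blob counts per frame differ by more than 2x, which is
#' what makes the two-class recognition task well-posed.
#'
#' @return Named list of two `texture_params` objects.
#' @export
default_class_params <- function() {
  list(glioblastoma = texture_params(blob_density = 25,
                                     blob_radius_range = c(2, 4)),
       meningioma = texture_params(blob_density = 8,
                                   blob_radius_range = c(6, 12)))
}

#' Generate one synthetic endomicroscopy-like frame
#'
#' Draws a Poisson number of anti-aliased bright discs (Gaussian-falloff rim)
#' at uniform positions, combines them with the background by per-pixel
#' maximum, adds Gaussian noise, and quantises to 8-bit gray values.
#'
#' @param params a [texture_params()] object.
#' @param width,height frame size in px.
#' @param seed optional integer; if given, the frame is generated from this
#'   seed, otherwise from the current RNG state.
#' @return Integer matrix (`height` x `width`) with values in \[0, 255\] and
#'   attribute `n_blobs` (the drawn blob count).
#' @export
#' @examples
#' f <- generate_frame(texture_params(), width = 64, height = 48, seed = 1)
#' range(f)
generate_frame <- function(params, width = 464, height = 336, seed = NULL) {
  stopifnot(inherits(params, "texture_params"))
  if (width <= 0 || height <= 0) stop("frame dimensions must be positive")
  if (!is.null(seed)) set.seed(seed)
  n_blobs <- stats::rpois(1, params$blob_density * width * height / 1e4)
  if (n_blobs > 0) {
    row <- stats::runif(n_blobs, 0, height - 1)
    col <- stats::runif(n_blobs, 0, width - 1)
    rad <- stats::runif(n_blobs, params$blob_radius_range[1],
                        params$blob_radius_range[2])
    amp <- stats::runif(n_blobs, params$blob_intensity_range[1],
                        params$blob_intensity_range[2])
    img <- draw_blobs_cpp(height, width, row, col, rad, amp,
                          params$background_level, 0.8)
  } else {
    img <- matrix(params$background_level, height, width)
  }
  if (params$noise_sigma > 0)
    img <- img + matrix(stats::rnorm(height * width, 0, params$noise_sigma),
                        height, width)
  out <- matrix(as.integer(pmin(255, pmax(0, round(img)))), height, width)
  attr(out, "n_blobs") <- n_blobs
  out
}

#' Generate a near-blank low-entropy frame
#'
#' Emulates the uninformative frames a confocal probe records off-tissue:
#' a constant gray level plus (optionally) faint Gaussian noise. With
#' `noise_sigma = 0` the gray-level entropy is exactly 0 bits.
#'
#' @param width,height frame size in px.
#' @param level background gray value.
#' @param noise_sigma noise standard deviation in gray values (small).
#' @return Integer matrix with values in \[0, 255\].
#' @export
generate_blank_frame <- function(width = 464, height = 336, level = 40,
                                 noise_sigma = 1) {
  if (width <= 0 || height <= 0) stop("frame dimensions must be positive")
  img <- matrix(level, height, width)
  if (noise_sigma > 0)
    img <- img + matrix(stats::rnorm(height * width, 0, noise_sigma),
                        height, width)
  matrix(as.integer(pmin(255, pmax(0, round(img)))), height, width)
}

#' Generate a labelled synthetic two-class video dataset
#'
#' Produces `n_videos_per_class` videos per class, each a sequence of textured
#' frames with `round(blank_fraction * frames_per_video)` near-blank frames
#' injected at uniformly random positions. One global seed fans out to
#' per-video sub-seeds as `seed + video_index` (0-based index over all
#' videos), so videos are reproducible independently of each other.
#'
#' @param n_videos_per_class videos per class (>= 1).
#' @param frames_per_video frames in each video.
#' @param blank_fraction fraction of near-blank frames per video, in \[0, 1).
#' @param class_params named list of two [texture_params()]; names are the
#'   class labels. Defaults to [default_class_params()].
#' @param width,height frame size in px.
#' @param blank_level,blank_noise_sigma parameters of injected blank frames.
#' @param seed integer seed driving all randomness.
#' @return An object of class `"cle_dataset"`: a list with elements `videos`
#'   (each with `video_id`, `label`, `frames`, `frame_index`, `is_blank`,
#'   `n_blobs`), `labels` (per-video factor), `class_params`, `width`,
#'   `height`, `seed`.
#' @export
#' @examples
#' ds <- generate_dataset(2, 6, blank_fraction = 0, width = 64, height = 48,
#'                        seed = 1)
#' ds
generate_dataset <- function(n_videos_per_class, frames_per_video,
                             blank_fraction = 0.1,
                             class_params = default_class_params(),
                             width = 464, height = 336,
                             blank_level = 40, blank_noise_sigma = 1,
                             seed = 1) {
  if (n_videos_per_class < 1) stop("need at least one video per class")
  stopifnot(frames_per_video >= 1,
            blank_fraction >= 0, blank_fraction < 1,
            length(class_params) == 2, !is.null(names(class_params)))
  classes <- names(class_params)
  n_videos <- 2L * n_videos_per_class
  n_blank <- round(blank_fraction * frames_per_video)
  videos <- vector("list", n_videos)
  labels <- character(n_videos)
  for (v in seq_len(n_videos) - 1L) {
    cls <- classes[(v %/% n_videos_per_class) + 1L]
    set.seed(seed + v)
    blank_at <- if (n_blank > 0) sort(sample.int(frames_per_video, n_blank))
                else integer(0)
    frames <- vector("list", frames_per_video)
    n_blobs <- integer(frames_per_video)
    for (f in seq_len(frames_per_video)) {
      if (f %in% blank_at) {
        frames[[f]] <- generate_blank_frame(width, height, blank_level,
                                            blank_noise_sigma)
        n_blobs[f] <- 0L
      } else {
        frames[[f]] <- generate_frame(class_params[[cls]], width, height)
        n_blobs[f] <- attr(frames[[f]], "n_blobs")
      }
    }
    videos[[v + 1L]] <- list(video_id = sprintf("video_%03d", v),
                             label = cls,
                             frames = frames,
                             frame_index = seq_len(frames_per_video) - 1L,
                             is_blank = seq_len(frames_per_video) %in% blank_at,
                             n_blobs = n_blobs)
    labels[v + 1L] <- cls
  }
  structure(list(videos = videos,
                 labels = factor(labels, levels = classes),
                 class_params = class_params,
                 width = width, height = height,
                 blank_fraction = blank_fraction,
                 seed = seed),
            class = "cle_dataset")
}

#' @export
print.cle_dataset <- function(x, ...) {
  nf <- vapply(x$videos, function(v) length(v$frames), integer(1))
  cat("Synthetic CLE dataset: ", length(x$videos), " videos, ",
      sum(nf), " frames (", x$width, "x", x$height, ")\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' Total frame count of a dataset
#' @param dataset a `cle_dataset`.
#' @return Integer.
#' @export
n_frames <- function(dataset) {
  sum(vapply(dataset$videos, function(v) length(v$frames), integer(1)))
}

#' Write a dataset to disk as PNG frame directories
#'
#' Layout: one directory per video (`video_000/frame_00000.png`, ...), a
#' `labels.csv` with columns `video_id,label`, and a `manifest.yaml` recording
#' the generator parameters and seed.
#'
#' @param dataset a `cle_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (v in dataset$videos) {
    vd <- file.path(dir, v$video_id)
    dir.create(vd, showWarnings = FALSE)
    for (i in seq_along(v$frames)) {
      png::writePNG(v$frames[[i]] / 255,
                    file.path(vd, sprintf("frame_%05d.png", v$frame_index[i])))
    }
  }
  labs <- data.frame(video_id = vapply(dataset$videos, `[[`, "", "video_id"),
                     label = as.character(dataset$labels))
  utils::write.csv(labs, file.path(dir, "labels.csv"), row.names = FALSE)
  manifest <- list(width = dataset$width, height = dataset$height,
                   blank_fraction = dataset$blank_fraction,
                   seed = dataset$seed,
                   classes = lapply(dataset$class_params, unclass))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Read a dataset from a directory of per-video frame folders
#'
#' Expects the layout written by [write_dataset()]: per-video directories of
#' PNG (or TIFF, if the tiff package is installed) frames plus `labels.csv`.
#' Unlabelled directories are read with label `NA`.
#'
#' @param dir dataset directory.
#' @return A `cle_dataset` (generator metadata fields absent).
#' @export
read_dataset <- function(dir) {
  labfile <- file.path(dir, "labels.csv")
  labs <- if (file.exists(labfile)) utils::read.csv(labfile) else NULL
  vdirs <- sort(list.dirs(dir, recursive = FALSE))
  if (length(vdirs) == 0) stop("no video directories under ", dir)
  videos <- vector("list", length(vdirs))
  labels <- character(length(vdirs))
  for (i in seq_along(vdirs)) {
    vid <- basename(vdirs[i])
    files <- sort(list.files(vdirs[i], pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0) stop("no frames in ", vdirs[i])
    frames <- lapply(files, read_frame)
    lab <- if (!is.null(labs) && vid %in% labs$video_id)
      labs$label[match(vid, labs$video_id)] else NA_character_
    idx <- suppressWarnings(as.integer(gsub("\\D", "", basename(files))))
    if (anyNA(idx)) idx <- seq_along(files) - 1L
    videos[[i]] <- list(video_id = vid, label = lab, frames = frames,
                        frame_index = idx,
                        is_blank = rep(NA, length(frames)),
                        n_blobs = rep(NA_integer_, length(frames)))
    labels[i] <- lab
  }
  dims <- dim(videos[[1]]$frames[[1]])
  structure(list(videos = videos,
                 labels = factor(labels),
                 class_params = NULL,
                 width = dims[2], height = dims[1],
                 blank_fraction = NA_real_, seed = NA_integer_),
            class = "cle_dataset")
}

# Read one grayscale frame from PNG or TIFF into an integer [0,255] matrix.
read_frame <- function(path) {
  lower <- tolower(path)
  img <- if (grepl("\\.png$", lower)) {
    png::readPNG(path)
  } else {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF frames requires the tiff package")
    tiff::readTIFF(path)
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}
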
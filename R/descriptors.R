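#' Dense sampling grid of patch positions
#'
#' Top-left patch coordinates at every `(i * spacing, j * spacing)` for which
#' the full `patch_size` x `patch_size` patch fits inside the frame. The
#' number of positions is
#' `(floor((H - p)/s) + 1) * (floor((W - p)/s) + 1)`; at the native CLE
#' resolution of 464 x 336 with 20 px patches and 10 px spacing this is
#' 45 x 32 = 1440 patches per frame.
#'
#' @param frame_width,frame_height frame size in px.
#' @param patch_size patch side length in px (default 20).
#' @param spacing grid spacing in px (default 10).
#' @return Integer matrix with columns `row`, `col` (0-based top-left
#'   coordinates), rows in row-major grid order.
#' @export
#' @examples
#' nrow(dense_grid(464, 336))  # 1440
dense_grid <- function(frame_width, frame_height, patch_size = 20,
                       spacing = 10) {
  if (patch_size > frame_width || patch_size > frame_height)
    stop("patch larger than frame")
  stopifnot(spacing >= 1)
  rows <- seq(0L, frame_height - patch_size, by = spacing)
  cols <- seq(0L, frame_width - patch_size, by = spacing)
  cbind(row = rep(rows, each = length(cols)),
        col = rep(cols, times = length(rows)))
}

#' Upright SIFT descriptor of a single patch
#'
#' Gradient orientation histogram over a 4 x 4 spatial cell grid with 8
#' orientation bins (128 dimensions): gradients by central differences with
#' edge replication, Gaussian spatial weighting (sigma = patch/2), trilinear
#' interpolation across cells and orientation bins, L2 normalisation,
#' clipping at 0.2, renormalisation. Patches with zero gradient energy
#' (constant regions, common in low-contrast meningioma frames) yield the
#' zero vector rather than an error.
#'
#' @param patch square numeric matrix of gray values.
#' @return Numeric vector of length 128, entries in \[0, 0.2\] with Euclidean
#'   norm 1 (or all zeros).
#' @export
sift_descriptor <- function(patch) {
  if (nrow(patch) != ncol(patch)) stop("patch must be square")
  res <- dense_sift_cpp(patch, nrow(patch), nrow(patch))
  drop(res$descriptors)
}

#' Extract dense SIFT descriptors from a frame
#'
#' Applies [sift_descriptor()] at every [dense_grid()] position, in row-major
#' grid order. Dense extraction (rather than interest-point detection) is
#' required to represent uniform cellular regions.
#'
#' @param frame integer/numeric gray matrix.
#' @param patch_size,spacing grid geometry (defaults 20 / 10 px).
#' @return An object of class `"descriptor_set"`: list with `descriptors`
#'   (n x 128 matrix), `centers` (n x 2 patch-centre coordinates, 0-based),
#'   `patch_size`, `spacing`.
#' @export
extract_dense <- function(frame, patch_size = 20, spacing = 10) {
  res <- dense_sift_cpp(frame, patch_size, spacing)
  structure(list(descriptors = res$descriptors,
                 centers = res$centers,
                 patch_size = patch_size, spacing = spacing),
            class = "descriptor_set")
}

#' Persist / restore a descriptor set
#'
#' Descriptors are written as a flat binary array of doubles
#' (descriptor-major) with a JSON sidecar (`<path>.json`) recording the
#' dimensions, grid geometry and frame reference.
#'
#' @param dset a `"descriptor_set"` from [extract_dense()].
#' @param path file path for the binary array; the sidecar is `path` +
#'   `".json"`.
#' @param frame_ref optional list with `video_id` and `frame_index`.
#' @return `path` (write) or the restored `"descriptor_set"` (read).
#' @export
write_descriptors <- function(dset, path, frame_ref = NULL) {
  stopifnot(inherits(dset, "descriptor_set"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(dset$descriptors)), con, size = 8L)
  meta <- list(n = nrow(dset$descriptors), d = ncol(dset$descriptors),
               patch_size = dset$patch_size, spacing = dset$spacing,
               centers = dset$centers, frame_ref = frame_ref,
               layout = "descriptor-major", version = 1L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_descriptors
#' @export
read_descriptors <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- readBin(path, "numeric", meta$n * meta$d, size = 8L)
  structure(list(descriptors = t(matrix(vals, meta$d, meta$n)),
                 centers = matrix(unlist(meta$centers), ncol = 2),
                 patch_size = meta$patch_size, spacing = meta$spacing,
                 frame_ref = meta$frame_ref),
            class = "descriptor_set")
}

#' @export
print.descriptor_set <- function(x, ...) {
  cat("Dense descriptor set: ", nrow(x$descriptors), " descriptors x ",
      ncol(x$descriptors), " dims (patch ", x$patch_size, ", spacing ",
      x$spacing, ")\n", sep = "")
  invisible(x)
}
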
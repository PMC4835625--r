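#' Sample training descriptors for codebook learning
#'
#' Uniform sample without replacement (with replacement only if fewer
#' descriptors are available than requested, with a warning). Zero-vector
#' descriptors (constant patches) are excluded before sampling so the
#' vocabulary is learned on informative patches only.
#'
#' @param X numeric matrix of descriptors, one per row (n x d).
#' @param n sample size (default 100000).
#' @param seed optional integer seed.
#' @return A d x n matrix of sampled descriptors (column layout, ready for
#'   [kmeans_codebook()]).
#' @export
sample_descriptors <- function(X, n = 100000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nz <- rowSums(abs(X)) > 0
  X <- X[nz, , drop = FALSE]
  if (nrow(X) == 0) stop("no non-zero descriptors to sample from")
  if (n >= nrow(X)) {
    if (n > nrow(X))
      warning("requested ", n, " descriptors but only ", nrow(X),
              " available; returning all")
    return(t(X))
  }
  t(X[sample.int(nrow(X), n), , drop = FALSE])
}

# k-means++ seeding: first centre uniform, then proportional to squared
# distance to the nearest chosen centre. R RNG so set.seed() fixes it.
kmeanspp_init <- function(X, m) {
  n <- ncol(X)
  xn <- colSums(X^2)
  centers <- matrix(0, nrow(X), m)
  i1 <- sample.int(n, 1)
  centers[, 1] <- X[, i1]
  d2 <- pmax(0, xn + sum(centers[, 1]^2) - 2 * drop(crossprod(centers[, 1], X)))
  for (k in seq_len(m - 1L) + 1L) {
    tot <- sum(d2)
    ik <- if (tot <= 0) sample.int(n, 1)
          else sample.int(n, 1, prob = d2 / tot)
    centers[, k] <- X[, ik]
    dk <- pmax(0, xn + sum(centers[, k]^2) - 2 * drop(crossprod(centers[, k], X)))
    d2 <- pmin(d2, dk)
  }
  centers
}

#' Learn a flat k-means codebook
#'
#' Lloyd's algorithm with k-means++ initialisation. Empty clusters are
#' re-seeded deterministically from the farthest unassigned point. The
#' within-cluster sum of squares is recorded per iteration and is
#' non-increasing. This exhaustive-assignment codebook is the default for the
#' sparse and locality-constrained coders; the Bag-of-Words path uses
#' [build_vocab_tree()] instead.
#'
#' @param X d x n matrix of training descriptors (columns are descriptors).
#' @param m vocabulary size (default 256).
#' @param seed optional integer seed (k-means++ sampling).
#' @param max_iter maximum Lloyd iterations (default 100).
#' @param tol relative objective-change stopping tolerance (default 1e-4).
#' @return An object of class `"cle_codebook"`: list with `B` (d x m codeword
#'   matrix), `m`, `method = "kmeans"`, `objective` (per-iteration WCSS),
#'   `iterations`, `sample_n`, `seed`, and `tree = NULL`.
#' @export
kmeans_codebook <- function(X, m = 256, seed = NULL, max_iter = 100,
                            tol = 1e-4) {
  if (ncol(X) < m)
    stop("need at least m = ", m, " descriptors, got ", ncol(X))
  if (!is.null(seed)) set.seed(seed)
  C0 <- kmeanspp_init(X, m)
  fit <- lloyd_cpp(X, C0, max_iter, tol)
  structure(list(B = fit$centers, m = m, method = "kmeans",
                 objective = fit$objective, iterations = fit$iterations,
                 sample_n = ncol(X), seed = seed, tree = NULL,
                 version = 1L),
            class = "cle_codebook")
}

#' @export
print.cle_codebook <- function(x, ...) {
  cat("Visual codebook: m = ", x$m, ", d = ", nrow(x$B), ", method = ",
      x$method, if (!is.null(x$tree)) paste0(" (tree depth ", x$tree$depth, ")"),
      "\n", sep = "")
  invisible(x)
}

# Recursive node builder for the vocabulary tree.
vocab_tree_node <- function(X, branch, depth_left, max_iter, tol) {
  centroid <- rowMeans(X)
  all_same <- !any(X != X[, 1])
  if (depth_left == 0 || ncol(X) < branch || all_same) {
    return(list(leaf = TRUE, centroid = centroid))
  }
  C0 <- kmeanspp_init(X, branch)
  fit <- lloyd_cpp(X, C0, max_iter, tol)
  kids <- vector("list", branch)
  for (b in seq_len(branch)) {
    sel <- fit$cluster == b
    if (!any(sel)) return(list(leaf = TRUE, centroid = centroid))
    kids[[b]] <- vocab_tree_node(X[, sel, drop = FALSE], branch,
                                 depth_left - 1L, max_iter, tol)
  }
  list(leaf = FALSE, centers = fit$centers, children = kids)
}

# Collect leaf centroids (DFS order) and stamp leaf indices into the tree.
index_leaves <- function(node, counter) {
  if (node$leaf) {
    counter$n <- counter$n + 1L
    node$index <- counter$n
    counter$centroids[[counter$n]] <- node$centroid
  } else {
    node$children <- lapply(node$children, index_leaves, counter = counter)
  }
  node
}

#' Build a hierarchical k-means vocabulary tree
#'
#' Recursive k-means with `branch` clusters per node down to `depth` levels
#' (binary tree of depth 8 by default, giving at most 2^8 = 256 leaves =
#' codewords). Nodes with too few distinct points become leaves early. Leaf
#' centroids, in depth-first order, form the codebook; [tree_quantize()]
#' descends the tree greedily instead of searching all codewords.
#'
#' @param X d x n matrix of training descriptors.
#' @param branch branching factor (default 2).
#' @param depth maximum tree depth (default 8).
#' @param seed optional integer seed.
#' @param max_iter,tol per-node k-means controls.
#' @return A `"cle_codebook"` whose `B` holds the leaf centroids and whose
#'   `tree` field holds the search structure (`root`, `branch`, `depth`).
#' @export
build_vocab_tree <- function(X, branch = 2, depth = 8, seed = NULL,
                             max_iter = 50, tol = 1e-4) {
  stopifnot(branch >= 2, depth >= 1, ncol(X) >= 1)
  if (!is.null(seed)) set.seed(seed)
  root <- vocab_tree_node(X, branch, depth, max_iter, tol)
  counter <- new.env()
  counter$n <- 0L
  counter$centroids <- list()
  root <- index_leaves(root, counter)
  B <- do.call(cbind, counter$centroids)
  structure(list(B = B, m = ncol(B), method = "tree",
                 objective = NULL, iterations = NULL,
                 sample_n = ncol(X), seed = seed,
                 tree = c(list(root = root, branch = branch, depth = depth),
                          flatten_tree(root, branch, nrow(B))),
                 version = 1L),
            class = "cle_codebook")
}

# Flatten the recursive tree into the arrays the compiled walker uses:
# child-centroid matrix plus a signed child-id table (negative = leaf).
flatten_tree <- function(root, branch, d) {
  if (root$leaf)
    return(list(centers = matrix(root$centroid, d, 1),
                children = matrix(-root$index, 1, 1),
                root_leaf = root$index))
  nodes <- list()
  register <- function(node) {           # returns the 1-based internal id
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(centers = node$centers,
                         child_id = integer(branch))
    for (k in seq_len(branch)) {
      child <- node$children[[k]]
      nodes[[id]]$child_id[k] <<- if (child$leaf) -child$index
                                  else register(child)
    }
    id
  }
  register(root)
  centers <- matrix(0, d, branch * length(nodes))
  children <- matrix(0L, branch, length(nodes))
  for (j in seq_along(nodes)) {
    centers[, (j - 1L) * branch + seq_len(branch)] <- nodes[[j]]$centers
    children[, j] <- as.integer(nodes[[j]]$child_id)
  }
  list(centers = centers, children = children, root_leaf = NA_integer_)
}

#' Exhaustive nearest-codeword search
#'
#' Argmin of Euclidean distance over all codewords, ties broken by the lowest
#' index.
#'
#' @param x descriptor vector, or a matrix of descriptors in columns.
#' @param codebook a `cle_codebook` (or bare d x m matrix).
#' @return For a single descriptor, a list with `index` and `dist2`; for a
#'   matrix, a list of vectors `index`, `dist2`.
#' @export
nearest_codeword <- function(x, codebook) {
  B <- if (inherits(codebook, "cle_codebook")) codebook$B else codebook
  single <- is.null(dim(x))
  X <- if (single) matrix(x, ncol = 1) else x
  if (nrow(X) != nrow(B)) stop("descriptor dimension does not match codebook")
  res <- nn_assign_cpp(B, X)
  if (single) list(index = res$index[1], dist2 = res$dist2[1])
  else list(index = drop(res$index), dist2 = drop(res$dist2))
}

#' Quantize descriptors by greedy tree descent
#'
#' Descends the vocabulary tree root-to-leaf, choosing the nearest child
#' centroid at each level. This is a fast approximation: it is not guaranteed
#' to return the globally nearest leaf; agreement with [nearest_codeword()]
#' is a reported diagnostic.
#'
#' @param x descriptor vector or d x n matrix (columns are descriptors).
#' @param codebook a `cle_codebook` built by [build_vocab_tree()].
#' @return Integer codeword (leaf) index, or vector of indices.
#' @export
tree_quantize <- function(x, codebook) {
  if (is.null(codebook$tree)) stop("codebook has no vocabulary tree")
  single <- is.null(dim(x))
  X <- if (single) matrix(x, ncol = 1) else x
  if (nrow(X) != nrow(codebook$B))
    stop("descriptor dimension does not match codebook")
  tr <- codebook$tree
  out <- if (!is.na(tr$root_leaf)) rep(tr$root_leaf, ncol(X))
         else as.integer(tree_quantize_cpp(tr$centers, tr$children, X))
  if (single) out[1] else out
}

#' Serialize / restore a codebook
#'
#' Single-file archive with embedded metadata (method, seed, m, depth,
#' format version).
#'
#' @param codebook a `cle_codebook`.
#' @param path file path.
#' @return `path` (write) or the restored `cle_codebook` (read).
#' @export
write_codebook <- function(codebook, path) {
  saveRDS(codebook, path)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  cb <- readRDS(path)
  if (!inherits(cb, "cle_codebook")) stop("not a codebook archive")
  cb
}
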
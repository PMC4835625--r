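#' Coding parameters
#'
#' Bundle of the feature-coding hyperparameters. `lambda` weights the
#' sparsity (SC/LSC) or locality-ridge (LLC) penalty; `sigma` sets the decay
#' speed of the locality adaptor `d_j = exp(||x - b_j|| / sigma)` (distances
#' are plain Euclidean, computed on the L2-normalised descriptors); `K` is
#' the neighbour count for the fast restricted solver; `mu`, `tol`,
#' `max_iter` control the ADMM.
#'
#' @param scheme one of `"bow"`, `"sc"`, `"llc"`, `"lsc"`, `"lsc_fast"`.
#' @param lambda regularisation weight (> 0 for llc/lsc, >= 0 for sc).
#' @param sigma locality decay (> 0).
#' @param K neighbour count, 1 <= K <= m (fast coder).
#' @param mu initial ADMM penalty parameter (> 0); the solver rebalances it
#'   against the primal/dual residual ratio during iteration.
#' @param tol ADMM stopping tolerance on the primal, dual, and sum-to-one
#'   residuals.
#' @param max_iter ADMM iteration cap.
#' @return An object of class `"coding_params"`.
#' @export
coding_params <- function(scheme = c("bow", "sc", "llc", "lsc", "lsc_fast"),
                          lambda = 0.1, sigma = 1, K = 5, mu = 0.1,
                          tol = 1e-6, max_iter = 500) {
  scheme <- match.arg(scheme)
  stopifnot(lambda >= 0, sigma > 0, K >= 1, mu > 0, tol > 0, max_iter >= 1)
  structure(list(scheme = scheme, lambda = lambda, sigma = sigma, K = K,
                 mu = mu, tol = tol, max_iter = max_iter),
            class = "coding_params")
}

codebook_matrix <- function(codebook) {
  if (inherits(codebook, "cle_codebook")) codebook$B else as.matrix(codebook)
}

#' Soft-thresholding (shrinkage) operator
#'
#' `S_eps(v) = v - eps` if `v > eps`, `v + eps` if `v < -eps`, else 0 — the
#' proximal operator of the l1 norm, applied elementwise in the ADMM
#' c-update.
#'
#' @param v numeric vector.
#' @param eps threshold(s), >= 0 (recycled).
#' @return Shrunk values.
#' @export
#' @examples
#' soft_threshold(c(1.2, -1.2, 0.3), 0.5)  # 0.7 -0.7 0.0
soft_threshold <- function(v, eps) {
  stopifnot(all(eps >= 0))
  sign(v) * pmax(abs(v) - eps, 0)
}

#' Locality adaptor weights
#'
#' `d_j = exp(||x - b_j||_2 / sigma)`: every entry is >= 1 and grows with the
#' distance to the codeword, so coefficients on distant bases are penalised
#' more heavily. As `sigma -> Inf` all weights tend to 1 and locality
#' vanishes.
#'
#' @param x descriptor vector.
#' @param codebook `cle_codebook` or d x m matrix.
#' @param sigma decay parameter (> 0).
#' @return Numeric vector of length m, entries >= 1.
#' @export
locality_weights <- function(x, codebook, sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  B <- codebook_matrix(codebook)
  exp(sqrt(pmax(0, colSums((B - x)^2))) / sigma)
}

#' Bag-of-Words code
#'
#' Indicator vector at the nearest codeword: exactly one coefficient equals
#' 1, all others 0.
#'
#' @param x descriptor vector.
#' @param codebook `cle_codebook` or d x m matrix.
#' @return An object of class `"cle_code"`: list with `c` (length-m vector),
#'   `scheme`, `objective` (the squared distance to the chosen codeword).
#' @export
encode_bow <- function(x, codebook) {
  B <- codebook_matrix(codebook)
  nn <- nearest_codeword(x, B)
  cv <- numeric(ncol(B))
  cv[nn$index] <- 1
  new_code(cv, "bow", nn$dist2)
}

new_code <- function(cv, scheme, objective, converged = TRUE,
                     residual = NA_real_) {
  structure(list(c = cv, scheme = scheme, objective = objective,
                 converged = converged, residual = residual),
            class = "cle_code")
}

#' @export
print.cle_code <- function(x, ...) {
  nz <- sum(x$c != 0)
  cat("Code (", x$scheme, "): m = ", length(x$c), ", ", nz,
      " non-zeros, objective ", format(x$objective, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Sparse code (l1-regularised, sum-to-one)
#'
#' Minimises `||x - Bc||_2^2 + lambda * ||c||_1` subject to `1'c = 1`. This
#' is the uniform-weight special case of [encode_lsc()] (locality adaptor
#' identically 1) and is solved by the same ADMM.
#'
#' @inheritParams encode_bow
#' @param lambda sparsity weight (>= 0).
#' @param mu,tol,max_iter ADMM controls.
#' @return A `"cle_code"`.
#' @export
encode_sc <- function(x, codebook, lambda = 0.1, mu = 0.1, tol = 1e-6,
                      max_iter = 500) {
  B <- codebook_matrix(codebook)
  D <- matrix(1, ncol(B), 1)
  res <- lsc_admm_cpp(B, matrix(x, ncol = 1), lambda, 1, mu, tol, max_iter, D)
  code_from_admm(res, 1L, "sc")
}

code_from_admm <- function(res, j, scheme) {
  conv <- res$converged[j] == 1
  if (!conv)
    warning("ADMM did not converge within max_iter (residual ",
            format(res$residual[j], digits = 3), "); returning best iterate")
  new_code(res$codes[, j], scheme, res$objective[j], conv, res$residual[j])
}

#' Locality-constrained linear code (LLC)
#'
#' Minimises `||x - Bc||_2^2 + lambda * ||d .* c||_2^2` subject to
#' `1'c = 1`, with the locality adaptor `d` of [locality_weights()]. The
#' squared penalty keeps the problem smooth, so the solution is obtained in
#' closed form from one (m+1) x (m+1) KKT system — no iteration.
#'
#' @inheritParams encode_bow
#' @param lambda locality-ridge weight (> 0).
#' @param sigma locality decay (> 0).
#' @return A `"cle_code"`.
#' @export
encode_llc <- function(x, codebook, lambda = 0.1, sigma = 1) {
  stopifnot(lambda > 0)
  B <- codebook_matrix(codebook)
  m <- ncol(B)
  d <- locality_weights(x, B, sigma)
  H <- 2 * crossprod(B) + 2 * lambda * diag(d^2, m)
  s <- max(1, max(abs(diag(H))))  # equilibrate the constraint border
  M <- rbind(cbind(H, rep(s, m)), c(rep(s, m), 0))
  rhs <- c(2 * drop(crossprod(B, x)), s)
  sol <- tryCatch(solve(M, rhs), error = function(e) {
    warning("singular LLC KKT system; applying ridge jitter")
    solve(M + diag(1e-10 * s, m + 1), rhs)
  })
  cv <- sol[seq_len(m)]
  obj <- sum((x - B %*% cv)^2) + lambda * sum((d * cv)^2)
  new_code(cv, "llc", obj)
}

#' Locality-constrained sparse code (LSC)
#'
#' The locality-weighted l1 coding problem
#' `min ||x - Bc||_2^2 + lambda * ||d .* c||_1` subject to `1'c = 1`, which
#' enforces sparsity while concentrating the code on codewords near the
#' descriptor. Solved by ADMM with variable splitting `c = y`: the y-update
#' is an equality-constrained least-squares solve (sum-to-one handled
#' exactly via a KKT multiplier), the c-update is elementwise
#' soft-thresholding with per-entry threshold `lambda * d_j / (2 mu)`, and
#' the scaled dual is updated as `u <- u + c - y`. Iteration stops when the
#' primal residual `max|c - y|`, the dual residual, and the feasibility
#' residual `|sum(c) - 1|` are all at most `tol`. The penalty `mu` is
#' rebalanced (doubled/halved) when the primal and dual residuals diverge by
#' more than a decade; for large full codebooks (m of order hundreds) a
#' larger initial `mu` (about 1) converges in fewer iterations.
#'
#' @inheritParams encode_bow
#' @param lambda sparsity weight (> 0).
#' @param sigma locality decay (> 0).
#' @param mu ADMM penalty (> 0).
#' @param tol stopping tolerance.
#' @param max_iter iteration cap; on non-convergence the best iterate is
#'   returned with `converged = FALSE` and a warning.
#' @return A `"cle_code"` with `converged` flag.
#' @export
encode_lsc <- function(x, codebook, lambda = 0.1, sigma = 1, mu = 0.1,
                       tol = 1e-6, max_iter = 500) {
  stopifnot(lambda > 0, sigma > 0, mu > 0)
  B <- codebook_matrix(codebook)
  res <- lsc_admm_cpp(B, matrix(x, ncol = 1), lambda, sigma, mu, tol,
                      max_iter, matrix(0, 0, 0))
  code_from_admm(res, 1L, "lsc")
}

#' Fast K-nearest-neighbour LSC
#'
#' Restricts the LSC problem to the K nearest codewords of the descriptor,
#' solves the much smaller system with the same ADMM, and scatters the
#' coefficients back into a length-m code (zeros elsewhere). The restricted
#' optimum can only be as good as the full one, so its objective is an upper
#' bound on the full LSC objective; with `K = m` the two coincide.
#'
#' @inheritParams encode_lsc
#' @param K neighbour count, 1 <= K <= m.
#' @return A `"cle_code"`.
#' @export
encode_lsc_fast <- function(x, codebook, lambda = 0.1, sigma = 1, K = 5,
                            mu = 0.1, tol = 1e-6, max_iter = 500) {
  B <- codebook_matrix(codebook)
  if (K < 1 || K > ncol(B)) stop("K must be between 1 and m")
  idx <- knn_cpp(B, matrix(x, ncol = 1), K)
  res <- lsc_admm_knn_cpp(B, matrix(x, ncol = 1), idx, lambda, sigma, mu,
                          tol, max_iter)
  code_from_admm(res, 1L, "lsc_fast")
}

#' Encode a descriptor set
#'
#' Applies the configured coding scheme to every descriptor of a frame,
#' preserving order, using the batch compiled solvers. Zero descriptors
#' (constant patches) receive the Bag-of-Words code of the zero vector under
#' every scheme.
#'
#' @param descriptors a `"descriptor_set"` from [extract_dense()], or a bare
#'   n x d matrix.
#' @param codebook a `cle_codebook`.
#' @param params a [coding_params()] object.
#' @return An object of class `"code_set"`: list with `codes` (m x n matrix,
#'   one code per column), `scheme`, `objective`, `converged`, `iterations`.
#' @export
encode_set <- function(descriptors, codebook, params) {
  stopifnot(inherits(params, "coding_params"))
  X <- if (inherits(descriptors, "descriptor_set")) descriptors$descriptors
       else as.matrix(descriptors)
  B <- codebook_matrix(codebook)
  n <- nrow(X)
  m <- ncol(B)
  if (n == 0)
    return(structure(list(codes = matrix(0, m, 0), scheme = params$scheme,
                          objective = numeric(0), converged = logical(0),
                          iterations = integer(0)),
                     class = "code_set"))
  Xt <- t(X)
  zero <- colSums(abs(Xt)) == 0
  codes <- matrix(0, m, n)
  objective <- numeric(n)
  converged <- rep(TRUE, n)
  iterations <- integer(n)
  live <- which(!zero)

  if (params$scheme == "bow" || any(zero)) {
    # BoW path (also the stated convention for zero descriptors)
    bow_cols <- if (params$scheme == "bow") seq_len(n) else which(zero)
    if (length(bow_cols)) {
      Xb <- Xt[, bow_cols, drop = FALSE]
      idx <- if (!is.null(codebook$tree) && params$scheme == "bow")
        tree_quantize(Xb, codebook)
      else nn_assign_cpp(B, Xb)$index
      codes[cbind(idx, bow_cols)] <- 1
      objective[bow_cols] <- colSums((B[, idx, drop = FALSE] - Xb)^2)
    }
  }
  if (params$scheme != "bow" && length(live)) {
    Xl <- Xt[, live, drop = FALSE]
    res <- switch(params$scheme,
      sc = lsc_admm_cpp(B, Xl, params$lambda, 1, params$mu, params$tol,
                        params$max_iter, matrix(1, m, length(live))),
      lsc = lsc_admm_cpp(B, Xl, params$lambda, params$sigma, params$mu,
                         params$tol, params$max_iter, matrix(0, 0, 0)),
      lsc_fast = {
        if (params$K > m) stop("K must be between 1 and m")
        idx <- knn_cpp(B, Xl, params$K)
        lsc_admm_knn_cpp(B, Xl, idx, params$lambda, params$sigma,
                         params$mu, params$tol, params$max_iter)
      },
      llc = {
        cl <- lapply(seq_len(ncol(Xl)), function(j)
          encode_llc(Xl[, j], codebook, params$lambda, params$sigma))
        list(codes = vapply(cl, `[[`, numeric(m), "c"),
             objective = vapply(cl, `[[`, numeric(1), "objective"),
             converged = rep(1L, length(cl)),
             iterations = rep(0L, length(cl)))
      })
    codes[, live] <- res$codes
    objective[live] <- res$objective
    converged[live] <- res$converged == 1
    iterations[live] <- res$iterations
    if (!all(converged[live]))
      warning(sum(!converged[live]), " descriptor solves hit max_iter")
  }
  structure(list(codes = codes, scheme = params$scheme,
                 objective = objective, converged = converged,
                 iterations = iterations),
            class = "code_set")
}

#' @export
print.code_set <- function(x, ...) {
  cat("Code set (", x$scheme, "): ", ncol(x$codes), " codes of length ",
      nrow(x$codes), "\n", sep = "")
  invisible(x)
}
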
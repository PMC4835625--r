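# Independent oracles for the coding solvers. These never touch the package's
# ADMM/KKT code paths: the l1 problems are solved by exhaustive sign-pattern
# enumeration (exact for small m), the smooth problems by exact linear algebra
# in the null space of the sum-to-one constraint.

lsc_objective <- function(x, B, lambda, d, cv) {
  sum((x - B %*% cv)^2) + lambda * sum(d * abs(cv))
}

llc_objective <- function(x, B, lambda, d, cv) {
  sum((x - B %*% cv)^2) + lambda * sum((d * cv)^2)
}

# Exact minimiser of ||x - Bc||^2 + lambda * sum_j d_j |c_j|  s.t. 1'c = 1,
# by enumerating all support/sign patterns. The optimum's pattern is among
# them; candidates whose restricted solution violates its sign pattern are
# discarded. Exponential in m: use only for m <= 8.
oracle_lsc_enum <- function(x, B, lambda, d) {
  m <- ncol(B)
  stopifnot(m <= 8)
  best <- NULL
  bestobj <- Inf
  for (mask in 1:(2^m - 1)) {
    A <- which(bitwAnd(mask, 2^(0:(m - 1))) > 0)
    k <- length(A)
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
    BA <- B[, A, drop = FALSE]
    M <- rbind(cbind(2 * crossprod(BA), rep(1, k)), c(rep(1, k), 0))
    for (si in seq_len(nrow(signs))) {
      s <- signs[si, ]
      rhs <- c(2 * crossprod(BA, x) - lambda * d[A] * s, 1)
      sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      cA <- sol[seq_len(k)]
      if (any(sign(cA) != s & cA != 0)) next
      cv <- numeric(m)
      cv[A] <- cA
      obj <- lsc_objective(x, B, lambda, d, cv)
      if (obj < bestobj) {
        bestobj <- obj
        best <- cv
      }
    }
  }
  list(c = best, objective = bestobj)
}

# Exact minimiser of the smooth LLC problem via the null-space
# parameterisation c = c0 + N z (columns of N span {v : 1'v = 0}); the
# reduced problem is an unconstrained quadratic solved in closed form.
oracle_llc_exact <- function(x, B, lambda, d) {
  m <- ncol(B)
  c0 <- rep(1 / m, m)
  N <- rbind(diag(m - 1), rep(-1, m - 1))
  H <- 2 * crossprod(B) + 2 * lambda * diag(d^2, m)
  g <- H %*% c0 - 2 * crossprod(B, x)
  z <- solve(crossprod(N, H %*% N), -crossprod(N, g))
  cv <- drop(c0 + N %*% z)
  list(c = cv, objective = llc_objective(x, B, lambda, d, cv))
}

# A random small coding instance: descriptor-like x and codebook B.
random_coding_instance <- function(d = 4, m = 6) {
  list(B = matrix(stats::rnorm(d * m), d, m), x = stats::rnorm(d))
}

# Probability that majority voting over a window of odd length T fails under
# iid symmetric label flips at rate p (binomial tail, closed form).
majority_error_rate <- function(p, T) {
  k <- ceiling((T + 1) / 2)
  sum(stats::dbinom(k:T, T, p))
}
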
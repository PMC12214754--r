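# Internal helpers shared across modules.

#' @importFrom withr with_seed
NULL

# Evaluate `expr` under a fixed RNG state without disturbing the caller's RNG.
with_rng <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Derive a child seed from a parent seed; stays below 2^31.
child_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) %% 1009L
}

# Moore-Penrose pseudoinverse via SVD (relative tolerance on singular values).
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * s$d[1]
  if (!any(keep)) {
    return(matrix(0, ncol(A), nrow(A)))
  }
  s$v[, keep, drop = FALSE] %*%
    ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# Least squares without intercept; falls back to the pseudoinverse when the
# normal equations are numerically singular.
solve_normal <- function(Z, y, tol = 1e-10) {
  ZtZ <- crossprod(Z)
  Zty <- crossprod(Z, y)
  beta <- tryCatch(solve(ZtZ, Zty), error = function(e) NULL)
  if (is.null(beta) || anyNA(beta)) {
    beta <- pinv(ZtZ, tol = tol) %*% Zty
  }
  drop(beta)
}

# Rotation matrices (degrees), y-up right-handed model frame.
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, -sin(a),
           0, 1, 0,
           sin(a), 0, cos(a)), 3, 3)
}

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0,
           0, cos(a), sin(a),
           0, -sin(a), cos(a)), 3, 3)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
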
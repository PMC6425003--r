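# Generalized least squares solve for the alternating rank-fit updates;
# falls back to an SVD pseudoinverse when the normal matrix is singular.
gls_solve <- function(M, Qi, x) {
  A <- crossprod(M, Qi %*% M)
  b <- crossprod(M, Qi %*% x)
  out <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(out)) {
    sv <- svd(A)
    pos <- sv$d > max(sv$d) * 1e-12
    out <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos])
  }
  out
}

# Invert a jackknife covariance, ridge-regularizing when numerically
# singular (small panels make Q ill-conditioned).
safe_precision <- function(Q, ridge = 1e-5) {
  ok <- tryCatch({ chol(Q); rcond(Q) > 1e-12 },
                 error = function(e) FALSE)
  if (!ok) {
    warning("singular f4 covariance; adding ridge ",
            format(ridge), " x mean diagonal")
    Q <- Q + diag(ridge * mean(diag(Q)), nrow(Q))
  }
  solve(Q)
}

# Minimize (x - vec(AB))' Qi (x - vec(AB)) over A (L x r), B (r x R) by
# alternating generalized least squares; x is the column-major vec of an
# L x R matrix. r = 0 returns the null fit.
fit_rank <- function(x, Qi, L, R, r, init = NULL,
                     tol = 1e-10, max_iter = 2000) {
  if (r == 0)
    return(list(chisq = drop(crossprod(x, Qi %*% x)),
                fitted = matrix(0, L, R), A = NULL, B = NULL,
                iterations = 0L, converged = TRUE))
  X <- matrix(x, L, R)
  if (is.null(init)) {
    sv <- svd(X)
    A <- sv$u[, seq_len(r), drop = FALSE] %*%
      diag(sv$d[seq_len(r)], r)
    B <- t(sv$v[, seq_len(r), drop = FALSE])
  } else {
    A <- init$A; B <- init$B
  }
  IL <- diag(L); IR <- diag(R)
  chisq <- Inf
  for (it in seq_len(max_iter)) {
    M_A <- kronecker(t(B), IL)                 # vec(AB) = M_A vec(A)
    A <- matrix(gls_solve(M_A, Qi, x), L, r)
    M_B <- kronecker(IR, A)                    # vec(AB) = M_B vec(B)
    B <- matrix(gls_solve(M_B, Qi, x), r, R)
    e <- x - as.vector(A %*% B)
    new <- drop(crossprod(e, Qi %*% e))
    if (is.finite(chisq) && abs(chisq - new) <= tol * (1 + abs(new))) {
      return(list(chisq = new, fitted = A %*% B, A = A, B = B,
                  iterations = it, converged = TRUE))
    }
    chisq <- new
  }
  stop("rank-", r, " fit did not converge after ", max_iter,
       " iterations (last chi-square ", format(chisq), ")")
}

#' qpWave-style rank test of an f4 matrix
#'
#' Tests whether the f4 matrix X between left and right population sets
#' is consistent with rank r, i.e. whether r + 1 independent streams of
#' ancestry suffice to relate the left populations to the right
#' outgroups. The statistic is the minimized quadratic form
#' (vec(X - AB))' Q^-1 (vec(X - AB)) over rank-r factorizations AB,
#' computed by alternating weighted least squares; under the rank-r null
#' it is chi-square with (n_left - 1 - r)(n_right - 1 - r) degrees of
#' freedom.
#'
#' @param f4m an [build_f4_matrix()] result.
#' @param rank tested rank r, with 0 <= r < min(n_left - 1, n_right - 1).
#' @param ridge relative ridge added to a numerically singular
#'   covariance (with a warning).
#' @return Object of class `qpwave_test`: `chisq`, `dof`, `p_value`,
#'   `rank`, plus the fitted factorization.
#' @export
qpwave_rank_test <- function(f4m, rank, ridge = 1e-5) {
  stopifnot(inherits(f4m, "f4_matrix"))
  L <- length(f4m$left) - 1L
  R <- length(f4m$right) - 1L
  if (rank < 0 || rank >= min(L, R))
    stop("rank must satisfy 0 <= r < min(n_left - 1, n_right - 1) = ",
         min(L, R))
  Qi <- safe_precision(f4m$cov, ridge)
  ft <- fit_rank(f4m$est, Qi, L, R, rank)
  dof <- (L - rank) * (R - rank)
  structure(list(rank = rank, chisq = ft$chisq, dof = dof,
                 p_value = stats::pchisq(ft$chisq, dof, lower.tail = FALSE),
                 fitted = ft$fitted, A = ft$A, B = ft$B,
                 iterations = ft$iterations,
                 left = f4m$left, right = f4m$right),
            class = "qpwave_test")
}

#' @export
print.qpwave_test <- function(x, ...) {
  cat(sprintf("qpWave rank test: rank %d, chisq = %.4f, dof = %d, p = %.4g\n",
              x$rank, x$chisq, x$dof, x$p_value))
  invisible(x)
}
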
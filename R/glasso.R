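# Graphical lasso: L1-penalized Gaussian precision estimation by block
# coordinate descent (Friedman-style), with the penalty on off-diagonal
# entries only. Written in-package: the ordering stage depends on the
# precision diagonal and no sparse-inverse-covariance estimator ships with
# the supported dependency set.

.soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' Graphical lasso precision estimate
#'
#' Minimizes `tr(Omega S) - log det(Omega) + lambda * sum_{j != k}
#' |omega_jk|` over positive-definite `Omega`.  The diagonal is not
#' penalized, so for `lambda -> 0` (and well-conditioned `S`) the estimate
#' approaches the maximum-likelihood inverse `S^{-1}`, and for very large
#' `lambda` it decouples to `diag(1 / s_jj)`.
#'
#' The solver sweeps the columns of the working covariance `W`, solving
#' each column's lasso subproblem by coordinate descent and warm-starting
#' across sweeps; `lambda = 0` is handled by direct inversion.
#'
#' @param S symmetric covariance or correlation matrix with positive
#'   diagonal (labelled dimnames recommended).
#' @param lambda nonnegative off-diagonal L1 penalty.
#' @param tol relative convergence tolerance on the mean absolute change
#'   of the working covariance per sweep.
#' @param maxIter maximum number of outer sweeps.
#'
#' @return a [PrecisionFit-class] object.
#' @examples
#' S <- diag(3)
#' precisionDiagonal(glassoPrecision(S, 0.001))
#' @export
glassoPrecision <- function(S, lambda, tol = 1e-7, maxIter = 500L) {
  if (!is.matrix(S) || nrow(S) != ncol(S))
    stop("'S' must be a square matrix")
  if (max(abs(S - t(S))) > 1e-8 * (1 + max(abs(S))))
    stop("'S' must be symmetric")
  if (any(diag(S) <= 0)) stop("'S' must have a positive diagonal")
  if (lambda < 0) stop("'lambda' must be nonnegative")
  p <- nrow(S)
  labs <- rownames(S)
  if (p == 1L) {
    omega <- matrix(1 / S[1, 1], 1, 1, dimnames = dimnames(S))
    return(new("PrecisionFit", omega = omega, lambda = lambda,
               iterations = 0L, converged = TRUE))
  }
  if (lambda == 0) {
    omega <- solve(S)
    omega <- (omega + t(omega)) / 2
    dimnames(omega) <- dimnames(S)
    return(new("PrecisionFit", omega = omega, lambda = 0,
               iterations = 0L, converged = TRUE))
  }

  W <- S                                   # diagonal unpenalized: w_jj = s_jj
  Beta <- matrix(0, p, p)                  # column j: coefs of the j-subproblem
  offbar <- mean(abs(S[upper.tri(S)]))
  thr <- tol * max(offbar, .Machine$double.eps)
  innerThr <- 0.05 * thr
  it <- 0L
  converged <- FALSE
  while (it < maxIter) {
    it <- it + 1L
    Wold <- W
    for (j in seq_len(p)) {
      W11 <- W[-j, -j, drop = FALSE]
      s12 <- S[-j, j]
      b <- Beta[-j, j]
      repeat {
        bOld <- b
        for (k in seq_len(p - 1L)) {
          r <- s12[k] - sum(W11[k, ] * b) + W11[k, k] * b[k]
          b[k] <- .soft(r, lambda) / W11[k, k]
        }
        if (max(abs(b - bOld)) < innerThr) break
      }
      Beta[-j, j] <- b
      w12 <- as.vector(W11 %*% b)
      W[-j, j] <- w12
      W[j, -j] <- w12
    }
    if (mean(abs(W - Wold)[upper.tri(W)]) < thr) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    stop(sprintf(
      "graphical lasso did not converge in %d sweeps (lambda = %g)",
      it, lambda))

  omega <- matrix(0, p, p)
  for (j in seq_len(p)) {
    b <- Beta[-j, j]
    denom <- W[j, j] - sum(W[-j, j] * b)
    if (denom <= 0)
      stop(sprintf(
        "graphical lasso produced a non-positive partial variance (lambda = %g, %d sweeps)",
        lambda, it))
    omega[j, j] <- 1 / denom
    omega[-j, j] <- -b / denom
  }
  omega <- (omega + t(omega)) / 2
  dimnames(omega) <- dimnames(S)
  new("PrecisionFit", omega = omega, lambda = lambda, iterations = it,
      converged = TRUE)
}
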
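# Lawson-Hanson active-set non-negative least squares. Implemented in-package
# because the SOBP weight solver needs it and no NNLS solver ships with the
# supported dependency set. Deterministic: no randomness, ties resolved by
# first index.

#' Non-negative least squares
#'
#' Solves min_x ||A x - b||_2 subject to x >= 0 by the Lawson-Hanson
#' active-set algorithm. At the solution the KKT conditions hold: the gradient
#' w = t(A) (A x - b) is ~0 on the passive set (x_i > 0) and >= 0 on the
#' active set (x_i = 0).
#'
#' @param A Numeric matrix (m x n), m >= 1.
#' @param b Numeric vector length m.
#' @param tol Dual-feasibility tolerance (default scales with the problem).
#' @param max_iter Iteration cap; the algorithm converges in finitely many
#'   steps, the cap guards against numerically cycling inputs.
#' @return List with `x` (solution, length n), `fitted` (A x), and
#'   `deviance` (residual sum of squares).
#' @export
nnls_fit <- function(A, b, tol = NULL, max_iter = 10L * ncol(A)) {
  A <- as.matrix(A)
  b <- as.numeric(b)
  stopifnot(nrow(A) == length(b), ncol(A) >= 1L)
  n <- ncol(A)
  if (is.null(tol)) tol <- 1e-10 * max(abs(crossprod(A, b)), 1)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- as.numeric(crossprod(A, b))  # gradient of -0.5*RSS at x = 0
  it <- 0L
  while (any(!passive & w > tol) && it < max_iter) {
    it <- it + 1L
    j <- which(!passive & w > tol)
    j <- j[which.max(w[j])]
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      z <- numeric(n)
      z[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > 0)) {
        x <- z
        break
      }
      neg <- P[z[P] <= 0]
      ratio <- x[neg] / (x[neg] - z[neg])
      ratio[!is.finite(ratio)] <- 0
      alpha <- min(ratio)
      x <- x + alpha * (z - x)
      passive[P][x[P] <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- as.numeric(crossprod(A, b - A %*% x))
  }
  fitted <- as.numeric(A %*% x)
  list(x = x, fitted = fitted, deviance = sum((b - fitted)^2))
}
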
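# Lawson-Hanson active-set non-negative least squares: minimize
# ||A x - b||^2 subject to x >= 0.  Problems here are a few hundred
# columns at most, so the reference algorithm in plain R is adequate.
nnls_fit <- function(A, b, tol = NULL) {
  A <- as.matrix(A)
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- drop(crossprod(A, b))            # gradient of 1/2||Ax-b||^2 at 0 (negated)
  tol <- tol %||% (10 * .Machine$double.eps * max(abs(w)) * max(dim(A)))
  max_outer <- 30L * n
  outer <- 0L
  while (outer < max_outer) {
    outer <- outer + 1L
    cand <- which(!passive & w > tol)
    if (!length(cand)) break
    j <- cand[which.max(w[cand])]
    passive[j] <- TRUE
    repeat {
      P <- which(passive)
      z <- numeric(n)
      z[P] <- qr.coef(qr(A[, P, drop = FALSE]), b)
      z[P][is.na(z[P])] <- 0
      if (all(z[P] > tol)) { x <- z; break }
      neg <- P[z[P] <= tol]
      a <- x[neg] / (x[neg] - z[neg])
      a[!is.finite(a)] <- 0
      step <- min(a)
      x <- x + step * (z - x)
      passive[P][x[P] <= tol] <- FALSE
      x[!passive] <- 0
    }
    r <- b - A %*% x
    w <- drop(crossprod(A, r))
  }
  x
}
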
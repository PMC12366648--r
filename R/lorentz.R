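#' The Lorentz metric matrix J_D
#'
#' \eqn{J_D = \mathrm{diag}(-1, I_D)}, the Gram matrix of the indefinite inner
#' product \eqn{[u, v] = u^\top J_D v} on \eqn{R^{1,D}}.
#'
#' @param D Spatial dimension; the matrix is \eqn{(D+1)\times(D+1)}.
#' @return Diagonal numeric matrix.
#' @export
lorentz_J <- function(D) diag(c(-1, rep(1, D)))

lorentz_ip <- function(u, v) sum(u * v) - 2 * u[1L] * v[1L]

#' J-adjoint of a matrix
#'
#' \eqn{A^{[\top]} = J_D A^\top J_D}, the adjoint with respect to the Lorentzian
#' product; an involution.
#'
#' @param A Square matrix on \eqn{R^{1,D}}.
#' @return Square matrix of the same size.
#' @export
j_adjoint <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("A must be square")
  J <- lorentz_J(nrow(A) - 1L)
  J %*% t(A) %*% J
}

#' Test J-unitarity
#'
#' A matrix is J-unitary when it preserves the Lorentzian form:
#' \eqn{A^\top J_D A = J_D}.
#'
#' @param A Square matrix.
#' @param tol Tolerance on the max-abs residual.
#' @return Logical.
#' @export
is_j_unitary <- function(A, tol = 1e-8) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("A must be square")
  J <- lorentz_J(nrow(A) - 1L)
  max(abs(t(A) %*% J %*% A - J)) <= tol
}

#' J-eigendecomposition of a symmetric matrix
#'
#' Solves the Lorentzian eigenequation \eqn{A J_D v = \mathrm{sgn}[v, v]\,
#' \lambda\, v}: eigenvectors of the (non-symmetric) matrix \eqn{A J_D} are
#' normalized to \eqn{|[v, v]| = 1} and classified by the sign of their
#' Lorentzian norm. For a symmetric, J-diagonalizable `A` with distinct
#' absolute J-eigenvalues there is exactly one negative (timelike) pair and
#' \eqn{D} positive pairs, the stacked vectors `V` satisfy
#' \eqn{V^\top J_D V = J_D}, and \eqn{A = V \Lambda V^\top}.
#'
#' Sign conventions: the negative pair's vector has positive 0-th coordinate;
#' each positive pair's largest-magnitude entry is positive. Ordering: negative
#' pair first, then positive pairs by J-eigenvalue descending.
#'
#' @param A Symmetric \eqn{(D+1)\times(D+1)} matrix.
#' @param tol Relative tolerance for discarding imaginary parts and detecting
#'   null-norm (degenerate) eigenvectors.
#' @return An object of class `"j_eigen"`: list with `values` (J-eigenvalues,
#'   ordered), `signs` (+1/-1), `vectors` (columns, same order), and
#'   `non_unique` flag for near-repeated absolute values.
#' @export
j_eigen <- function(A, tol = 1e-9) {
  A <- as.matrix(A)
  D1 <- nrow(A)
  if (ncol(A) != D1) stop("A must be square")
  if (max(abs(A - t(A))) > tol * max(1, max(abs(A))))
    stop("A must be symmetric")
  A <- (A + t(A)) / 2
  J <- lorentz_J(D1 - 1L)
  e <- eigen(A %*% J)
  scale <- max(1, max(abs(A)))
  if (max(abs(Im(e$values))) > tol * scale)
    stop("A is not J_D-diagonalizable over the reals (complex eigenvalues of A J_D)")
  vals <- Re(e$values)
  vecs <- Re(e$vectors)
  signs <- numeric(D1)
  jvals <- numeric(D1)
  for (k in seq_len(D1)) {
    v <- vecs[, k]
    q <- lorentz_ip(v, v)
    if (abs(q) < tol * sum(v^2))
      stop("degenerate (null J-norm) eigenvector at eigenvalue ", vals[k])
    v <- v / sqrt(abs(q))
    s <- sign(q)
    # A J v = mu v with mu = s * lambda (Euclidean <-> Lorentzian correspondence)
    jvals[k] <- s * vals[k]
    signs[k] <- s
    if (s < 0) { if (v[1L] < 0) v <- -v } else {
      i <- which.max(abs(v)); if (v[i] < 0) v <- -v
    }
    vecs[, k] <- v
  }
  n_neg <- sum(signs < 0)
  ord <- c(which(signs < 0)[order(-jvals[signs < 0])],
           which(signs > 0)[order(-jvals[signs > 0])])
  vals_o <- jvals[ord]; signs_o <- signs[ord]; vecs_o <- vecs[, ord, drop = FALSE]
  av <- sort(abs(vals_o))
  non_unique <- any(diff(av) <= 1e-9 * pmax(1, av[-length(av)]))
  structure(list(values = vals_o, signs = signs_o, vectors = vecs_o,
                 n_negative = n_neg, non_unique = non_unique, source = A),
            class = "j_eigen")
}

#' @export
print.j_eigen <- function(x, ...) {
  cat(sprintf("<j_eigen> %d pairs (%d negative)%s\n", length(x$values),
              x$n_negative, if (x$non_unique) " [non-unique: repeated |lambda|]" else ""))
  print(data.frame(value = x$values, sign = x$signs))
  invisible(x)
}
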
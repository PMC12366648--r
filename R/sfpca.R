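#' Second-moment matrix of ambient coordinates
#'
#' \eqn{C_x = \frac{1}{N}\sum_n x_n x_n^\top}; its (J-)eigenstructure drives
#' space form PCA.
#'
#' @param x Matrix of points, one per row, on one space form.
#' @param form Optional [space_form()] for validation.
#' @return List with `matrix` (symmetric PSD) and `n`.
#' @export
second_moment <- function(x, form = NULL) {
  x <- rbind(x)
  if (nrow(x) == 0L) stop("empty input")
  if (!is.null(form)) sf_check_points(form, x)
  list(matrix = crossprod(x) / nrow(x), n = nrow(x))
}

#' Space form PCA (SFPCA)
#'
#' Closed-form PCA on a sphere or hyperboloid. On the sphere the base point is
#' the leading eigenvector of the second-moment matrix \eqn{C_x} (scaled to the
#' sphere) and the tangent basis consists of the remaining eigenvectors in
#' descending eigenvalue order. On the hyperboloid the base point is the scaled
#' negative J-eigenvector of \eqn{C_x} and the tangent basis consists of the
#' positive J-eigenvectors by descending J-eigenvalue. Truncating the basis to
#' its first `K` entries yields the optimal K-dimensional Riemannian affine
#' subspace under the proper cost (sin\eqn{^2} / sinh\eqn{^2} distortion of the
#' projection distance); optima of different dimensions are nested and share
#' the base point, which is the induced space-form mean.
#'
#' @param x Matrix of points (rows) on the form.
#' @param form A [space_form()].
#' @param K Target subspace dimension used by [sf_subspace()] truncation and
#'   stored on the result; the full basis is always computed. `0 <= K <= D`.
#' @param repair If `TRUE`, renormalize invalid rows to the manifold (with a
#'   warning) instead of rejecting them.
#' @return Object of class `"sfpca"`: `form`, `base`, `tangent_basis`
#'   (D x (D+1), descending importance), `spectrum` (all D+1 (J-)eigenvalues;
#'   first entry belongs to the base), `signs` (hyperbolic only), `K`, `meta`
#'   (flags: `non_unique`, `base_tie`).
#' @examples
#' sph <- space_form(1, 3)
#' sub <- affine_subspace(sph, c(1, 0, 0, 0), rbind(c(0, 1, 0, 0)))
#' y <- cbind(cos(seq(0, 1, length = 20)), sin(seq(0, 1, length = 20)), 0, 0)
#' fit <- sfpca(y, sph, K = 1)
#' proj_distance(sf_subspace(fit, 1), y)  # ~ 0: data lie on a great circle
#' @export
sfpca <- function(x, form, K = form$dim, repair = FALSE) {
  x <- rbind(x)
  if (K < 0 || K > form$dim) stop("K must be in [0, D]")
  if (repair) {
    bad <- !sf_on_manifold(form, x)
    if (any(bad)) {
      warning("renormalized ", sum(bad), " row(s) to the manifold")
      x[bad, ] <- rbind(sf_normalize(form, x[bad, , drop = FALSE]))
    }
  }
  sf_check_points(form, x)
  Cx <- second_moment(x)$matrix
  if (is_sphere(form)) sfpca_sphere(x, form, K, Cx) else sfpca_hyper(x, form, K, Cx)
}

sfpca_sphere <- function(x, form, K, Cx) {
  e <- eigen(Cx, symmetric = TRUE)           # descending eigenvalues
  vals <- e$values
  vecs <- e$vectors
  base_tie <- length(vals) > 1L && abs(vals[1] - vals[2]) <= 1e-9 * max(1, vals[1])
  p <- vecs[, 1L] / sqrt(form$curvature)
  if (sum(x %*% vecs[, 1L]) < 0) p <- -p     # data-hemisphere sign choice
  basis <- t(vecs[, -1L, drop = FALSE])
  basis <- fix_row_signs(basis)
  res <- new_sfpca(form, p, basis, vals, signs = NULL, K = K,
                   meta = list(base_tie = base_tie,
                               non_unique = any(abs(diff(vals)) <=
                                                  1e-9 * max(1, vals[1]))))
  check_cost_identity(res, x)
  res
}

sfpca_hyper <- function(x, form, K, Cx) {
  je <- j_eigen(Cx)
  if (je$n_negative != 1L)
    stop("second moment of hyperboloid data must have exactly one negative ",
         "J-eigenpair (found ", je$n_negative, ")")
  p <- je$vectors[, 1L] / sqrt(abs(form$curvature))
  if (p[1L] < 0) p <- -p
  basis <- t(je$vectors[, -1L, drop = FALSE])  # positive pairs, descending
  res <- new_sfpca(form, p, basis, je$values, signs = je$signs, K = K,
                   meta = list(base_tie = FALSE, non_unique = je$non_unique))
  check_cost_identity(res, x)
  res
}

fix_row_signs <- function(B) {
  for (i in seq_len(nrow(B))) {
    j <- which.max(abs(B[i, ]))
    if (B[i, j] < 0) B[i, ] <- -B[i, ]
  }
  B
}

new_sfpca <- function(form, base, tangent_basis, spectrum, signs, K, meta,
                      method = "sfpca") {
  structure(list(form = form, base = base, tangent_basis = tangent_basis,
                 spectrum = spectrum, signs = signs, K = K, meta = meta,
                 method = method),
            class = "sfpca")
}

#' @export
print.sfpca <- function(x, ...) {
  cat(sprintf("<%s fit> %s C = %g, D = %d, K = %d\n", x$method, x$form$type,
              x$form$curvature, x$form$dim, x$K))
  cat("spectrum:", format(utils::head(x$spectrum, 6), digits = 4),
      if (length(x$spectrum) > 6) "...\n" else "\n")
  invisible(x)
}

# internal consistency: optimal cost equals the scaled sum of discarded
# (J-)eigenvalues (spectral identity of the proper cost)
check_cost_identity <- function(fit, x, tol = 1e-6) {
  D <- fit$form$dim
  K <- fit$K
  if (K >= D) return(invisible(TRUE))
  sub <- sf_subspace(fit, K)
  cost <- subspace_cost(sub, x)
  disc <- abs(fit$form$curvature) * sum(fit$spectrum[seq(K + 2L, D + 1L)])
  if (abs(cost - disc) > tol * max(1, abs(disc)))
    warning(sprintf("cost identity residual %.3g (cost %.6g vs discarded %.6g)",
                    cost - disc, cost, disc))
  invisible(TRUE)
}

#' Truncate a PCA fit to a K-dimensional affine subspace
#'
#' @param fit An `"sfpca"` object (from [sfpca()] or [pga()]).
#' @param K Dimension, `0 <= K <= D`; defaults to the fit's `K`.
#' @return An [affine_subspace()] through the fitted base point spanned by the
#'   first `K` tangent directions.
#' @export
sf_subspace <- function(fit, K = fit$K) {
  if (K < 0 || K > fit$form$dim) stop("K must be in [0, D]")
  affine_subspace(fit$form, fit$base,
                  if (K > 0L) fit$tangent_basis[seq_len(K), , drop = FALSE])
}

#' Proper cost of an affine subspace
#'
#' \eqn{E_N \sum_{k} g(x_n, h'_k)^2} over the complement basis in the paper
#' normalization (\eqn{g(h', h') = \pm C}); equals the average
#' sin\eqn{^2}/sinh\eqn{^2}-distorted projection distance, and vanishes exactly
#' when all points lie on the subspace.
#'
#' @param sub An [affine_subspace()].
#' @param x Points (rows) on the subspace's form.
#' @return Nonnegative scalar.
#' @export
subspace_cost <- function(sub, x) {
  form <- sub$form
  x <- sf_check_points(form, x)
  mean(rowSums(gmat(form, x, sub$complement)^2)) * abs(form$curvature)
}

#' Space form mean
#'
#' The zero-dimensional SFPCA optimum: the minimizer of the average
#' sin\eqn{^2}/sinh\eqn{^2}-distorted distance. On the sphere it is a scaled
#' leading eigenvector of \eqn{C_x} (defined up to sign; the data hemisphere
#' is chosen); on the hyperboloid the scaled negative J-eigenvector.
#'
#' @param x Points (rows).
#' @param form A [space_form()].
#' @return A point on the manifold.
#' @export
spaceform_mean <- function(x, form) {
  sfpca(x, form, K = 0L)$base
}
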
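#' Fréchet (intrinsic) mean by fixed-point iteration
#'
#' Minimizes the average squared geodesic distance by iterating
#' \eqn{p \leftarrow \exp_p(E_N[\log_p x_n])} from the normalized extrinsic
#' average, stopping when the mean-log step norm drops below `tol`.
#'
#' @param x Points (rows) on the form. Spherical data should lie in an open
#'   hemisphere for the mean to be well defined.
#' @param form A [space_form()].
#' @param tol Step-norm stopping threshold.
#' @param max_iter Iteration cap.
#' @return The mean point with attributes `converged`, `iterations`,
#'   `step_norm`.
#' @export
frechet_mean <- function(x, form, tol = 1e-9, max_iter = 1000L) {
  x <- sf_check_points(form, x)
  p <- init_mean(x, form)
  step <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    v <- colMeans(rbind(sf_log(form, p, x, validate = FALSE)))
    v <- sf_tangent_project(form, p, v)   # re-project against drift
    step <- sqrt(max(sf_norm2(form, v), 0))
    if (!is.finite(step)) stop("Frechet iteration diverged")
    if (step < tol) break
    p <- sf_exp(form, p, v, validate = FALSE)
    p <- sf_normalize(form, p)
  }
  attr(p, "converged") <- step < tol
  attr(p, "iterations") <- it
  attr(p, "step_norm") <- step
  p
}

init_mean <- function(x, form) {
  m <- colMeans(x)
  if (!is_sphere(form) && -sf_norm2(form, m) <= 0)
    m <- c(1, rep(0, form$dim))            # degenerate extrinsic mean: use pole
  if (is_sphere(form) && sum(m^2) < 1e-20) m <- x[1L, ]
  as.numeric(sf_normalize(form, m))
}

#' Principal geodesic analysis (PGA)
#'
#' The standard tangent-space baseline: the base point is the Fréchet mean,
#' and the tangent basis comes from Euclidean PCA of the log-mapped points in
#' a g-orthonormal tangent frame at the mean (uncentered: the tangent vectors
#' have mean approximately zero at a stationary point). Output has the same
#' shape as [sfpca()], so benchmarks consume both identically.
#'
#' @inheritParams frechet_mean
#' @param K Target subspace dimension.
#' @return An object of class `"sfpca"` with `method = "pga"`.
#' @export
pga <- function(x, form, K = form$dim, tol = 1e-9, max_iter = 1000L) {
  x <- sf_check_points(form, x)
  if (K < 0 || K > form$dim) stop("K must be in [0, D]")
  p <- frechet_mean(x, form, tol = tol, max_iter = max_iter)
  meanattrs <- attributes(p)
  p <- as.numeric(p)
  # g-orthonormal tangent frame at p (deterministic completion)
  frame <- complete_frame(form, p, matrix(numeric(0), 0L, form$dim + 1L))
  logs <- rbind(sf_log(form, p, x, validate = FALSE))
  tcoords <- gmat(form, logs, frame)                  # N x D tangent coordinates
  e <- eigen(crossprod(tcoords) / nrow(tcoords), symmetric = TRUE)
  basis <- t(e$vectors) %*% frame                     # rows: principal tangents
  basis <- fix_row_signs(basis)
  new_sfpca(form, p, basis, c(NA_real_, e$values), signs = NULL, K = K,
            meta = list(converged = isTRUE(meanattrs$converged),
                        iterations = meanattrs$iterations,
                        base_tie = FALSE, non_unique = FALSE),
            method = "pga")
}
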
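#' Constant-curvature space form
#'
#' A space form is a complete, simply connected Riemannian manifold of constant
#' curvature: the sphere \eqn{S^D} for curvature \eqn{C > 0} or the hyperboloid
#' (Lorentz) model of hyperbolic space \eqn{H^D} for \eqn{C < 0}. Points live in
#' ambient coordinates of length \eqn{D + 1}: the sphere is
#' \eqn{\{x : \langle x, x\rangle = 1/C\}} and the hyperboloid is the upper
#' sheet \eqn{\{x : [x, x] = 1/C,\ x_0 > 0\}} under the indefinite product
#' \eqn{[x, y] = x^\top J_D y}, \eqn{J_D = \mathrm{diag}(-1, I_D)}.
#'
#' @param curvature Nonzero real; positive selects the sphere, negative the
#'   hyperboloid.
#' @param dim Intrinsic dimension \eqn{D \ge 1}; ambient vectors have
#'   \eqn{D + 1} coordinates.
#' @return An object of class `"space_form"` with fields `curvature`, `dim`,
#'   and `type` (`"sphere"` or `"hyperbolic"`).
#' @examples
#' sphere <- space_form(1, 2)
#' hyp <- space_form(-1, 2)
#' sf_distance(sphere, c(1, 0, 0), c(0, 1, 0)) # pi / 2
#' @export
space_form <- function(curvature, dim) {
  stopifnot(is.numeric(curvature), length(curvature) == 1L, is.finite(curvature))
  if (curvature == 0) stop("curvature must be nonzero (use ordinary PCA for flat data)")
  dim <- as.integer(dim)
  if (dim < 1L) stop("dim must be >= 1")
  structure(
    list(curvature = curvature, dim = dim,
         type = if (curvature > 0) "sphere" else "hyperbolic"),
    class = "space_form"
  )
}

#' @export
print.space_form <- function(x, ...) {
  cat(sprintf("<space_form> %s, curvature C = %g, dim D = %d (ambient %d)\n",
              x$type, x$curvature, x$dim, x$dim + 1L))
  invisible(x)
}

is_sphere <- function(form) form$curvature > 0

#' Metric of a space form
#'
#' The ambient bilinear form: the Euclidean dot product on the sphere, the
#' Lorentzian product \eqn{[u, v] = u^\top J_D v} on the hyperboloid. Restricted
#' to a tangent space of the manifold, both are positive definite.
#'
#' @param form A [space_form()].
#' @param u,v Numeric vectors of length `form$dim + 1`, or matrices with that
#'   many columns (rows are paired).
#' @return Numeric scalar (or vector, for matrix input).
#' @export
sf_metric <- function(form, u, v) {
  u <- rbind(u); v <- rbind(v)
  if (ncol(u) != form$dim + 1L || ncol(v) != form$dim + 1L)
    stop("dimension mismatch: expected length ", form$dim + 1L)
  if (nrow(u) == 1L && nrow(v) > 1L) u <- u[rep(1L, nrow(v)), , drop = FALSE]
  if (nrow(v) == 1L && nrow(u) > 1L) v <- v[rep(1L, nrow(u)), , drop = FALSE]
  s <- unname(rowSums(u * v))
  if (is_sphere(form)) drop(s)
  else drop(s - 2 * unname(u[, 1L]) * unname(v[, 1L]))
}

# squared g-norm of (rows of) v; positive for tangent vectors in both geometries
sf_norm2 <- function(form, v) sf_metric(form, v, v)

#' Validate points on a space form
#'
#' Checks the quadratic-form constraint (`<x,x> = 1/C`, plus `x0 > 0` on the
#' hyperboloid) at a relative tolerance.
#'
#' @param form A [space_form()].
#' @param x Point (vector) or matrix of points (rows).
#' @param tol Relative tolerance on the constraint residual.
#' @return Logical vector, one entry per point.
#' @export
sf_on_manifold <- function(form, x, tol = 1e-6) {
  x <- rbind(x)
  q <- sf_metric(form, x, x)
  # relative tolerance: the indefinite form is evaluated with cancellation of
  # order |C| sum(x^2) for far-out hyperboloid points
  scale <- pmax(1, abs(form$curvature) * rowSums(x^2))
  ok <- abs(q * form$curvature - 1) <= tol * scale
  if (!is_sphere(form)) ok <- ok & x[, 1L] > 0
  ok
}

sf_check_points <- function(form, x, tol = 1e-6, what = "points") {
  x <- rbind(x)
  dimnames(x) <- NULL
  ok <- sf_on_manifold(form, x, tol)
  if (!all(ok))
    stop(sprintf("%s violate the %s constraint (rows %s)", what, form$type,
                 paste(utils::head(which(!ok), 5L), collapse = ", ")))
  invisible(x)
}

# clip with tolerance guard: values drifting slightly past the domain are
# clamped; real violations raise
clip_acos_arg <- function(z, tol = 1e-9) {
  if (any(z > 1 + tol | z < -1 - tol))
    stop("arccos argument outside [-1, 1] beyond tolerance: ", max(abs(z)) - 1)
  pmin(pmax(z, -1), 1)
}
clip_acosh_arg <- function(z, tol = 1e-9) {
  if (any(z < 1 - tol))
    stop("acosh argument below 1 beyond tolerance: ", 1 - min(z))
  pmax(z, 1)
}

#' Geodesic distance
#'
#' \eqn{d(x, y) = C^{-1/2}\arccos(C\langle x, y\rangle)} on the sphere and
#' \eqn{|C|^{-1/2}\,\mathrm{acosh}(C[x, y])} on the hyperboloid. Arguments of
#' arccos/acosh are clipped within a small tolerance to absorb floating-point
#' drift; larger violations raise an error.
#'
#' @param form A [space_form()].
#' @param x,y Points (vectors, or matrices of paired rows).
#' @param validate Check the manifold constraint first (default `TRUE`).
#' @return Nonnegative distance(s).
#' @export
sf_distance <- function(form, x, y, validate = TRUE) {
  if (validate) { sf_check_points(form, x); sf_check_points(form, y) }
  C <- form$curvature
  ip <- sf_metric(form, x, y)
  if (is_sphere(form)) acos(clip_acos_arg(C * ip)) / sqrt(C)
  else acosh(clip_acosh_arg(C * ip)) / sqrt(-C)
}

#' All pairwise geodesic distances
#'
#' @param form A [space_form()].
#' @param x Matrix of points, one per row.
#' @return Symmetric matrix of distances with zero diagonal.
#' @export
sf_pdist <- function(form, x) {
  x <- sf_check_points(form, x)
  C <- form$curvature
  G <- x %*% t(x)
  if (!is_sphere(form)) G <- G - 2 * tcrossprod(x[, 1L])
  D <- if (is_sphere(form)) acos(clip_acos_arg(C * G, tol = 1e-7)) / sqrt(C)
       else acosh(clip_acosh_arg(C * G, tol = 1e-7)) / sqrt(-C)
  diag(D) <- 0
  (D + t(D)) / 2
}

#' Project an ambient vector onto a tangent space
#'
#' Metric-orthogonal projection \eqn{w - (g(w, p) / g(p, p))\, p} onto
#' \eqn{T_p = p^\perp}. Idempotent; leaves tangent vectors unchanged.
#'
#' @param form A [space_form()].
#' @param p Base point on the manifold.
#' @param w Ambient vector (or matrix of rows).
#' @return Tangent vector(s) at `p`.
#' @export
sf_tangent_project <- function(form, p, w) {
  w <- rbind(w)
  coef <- sf_metric(form, w, p) / sf_metric(form, p, p)
  out <- w - outer(coef, as.numeric(p))
  if (nrow(out) == 1L) drop(out) else out
}

sf_check_tangent <- function(form, p, v, tol = 1e-6) {
  s <- max(abs(sf_metric(form, rbind(v), p)))
  scale <- max(1, max(abs(v)))
  if (s > tol * scale) stop("vector is not tangent at p (g(v, p) = ", s, ")")
  invisible(v)
}

#' Exponential map
#'
#' Follows the geodesic from `p` with initial velocity `v` for unit time:
#' \eqn{\cos(\sqrt{C}\|v\|)p + \sin(\sqrt{C}\|v\|)v / (\sqrt{C}\|v\|)} on the
#' sphere, cosh/sinh analogue with \eqn{\sqrt{|C|}} on the hyperboloid. A zero
#' velocity returns `p` exactly.
#'
#' @param form A [space_form()].
#' @param p Base point.
#' @param v Tangent vector at `p` (or matrix of rows).
#' @param validate Check tangency of `v` (default `TRUE`).
#' @return Point(s) on the manifold.
#' @export
sf_exp <- function(form, p, v, validate = TRUE) {
  if (validate) { sf_check_points(form, p); sf_check_tangent(form, p, v) }
  v <- rbind(v)
  sC <- sqrt(abs(form$curvature))
  nv <- sqrt(pmax(sf_norm2(form, v), 0))
  th <- sC * nv
  # sin(th)/th -> 1 as th -> 0: series guard keeps v = 0 exact
  sc <- ifelse(th < 1e-12, sC, ifelse(rep(is_sphere(form), length(th)),
                                      sin(th) / nv, sinh(th) / nv))
  a <- if (is_sphere(form)) cos(th) else cosh(th)
  out <- outer(a, as.numeric(p)) + v * (sc / sC)
  if (any(th < 1e-12))
    out[th < 1e-12, ] <- matrix(as.numeric(p), nrow = sum(th < 1e-12),
                                ncol = length(p), byrow = TRUE)
  if (nrow(out) == 1L) drop(out) else out
}

#' Logarithmic map
#'
#' Initial velocity of the unit-time geodesic from `p` to `x`; inverse of
#' [sf_exp()]. Undefined at the antipode on the sphere.
#'
#' @param form A [space_form()].
#' @param p Base point.
#' @param x Target point(s).
#' @param validate Check manifold membership (default `TRUE`).
#' @return Tangent vector(s) at `p` with \eqn{\|v\| = d(p, x)}.
#' @export
sf_log <- function(form, p, x, validate = TRUE) {
  if (validate) { sf_check_points(form, p); sf_check_points(form, x) }
  x <- rbind(x)
  th <- sf_distance(form, rbind(p)[rep(1, nrow(x)), , drop = FALSE], x,
                    validate = FALSE)
  if (is_sphere(form)) {
    anti <- abs(th - pi / sqrt(form$curvature)) < 1e-9
    if (any(anti)) stop("log map undefined at the antipode of p")
  }
  w <- sf_tangent_project(form, p, x)
  w <- rbind(w)
  nw <- sqrt(pmax(sf_norm2(form, w), 0))
  sc <- ifelse(nw < 1e-14, 0, th / nw)
  out <- w * sc
  if (nrow(out) == 1L) drop(out) else out
}

#' Lift spatial coordinates to the hyperboloid sheet
#'
#' Solves the 0-th coordinate from the sheet constraint
#' \eqn{-x_0^2 + \|z\|^2 = 1/C}, taking the upper (\eqn{x_0 > 0}) root.
#'
#' @param form A hyperbolic [space_form()].
#' @param z Spatial vector of length `form$dim` (or matrix of rows).
#' @return Point(s) on the hyperboloid.
#' @export
sf_lift <- function(form, z) {
  if (is_sphere(form)) stop("sf_lift applies to hyperbolic forms only")
  z <- rbind(z)
  x0 <- sqrt(rowSums(z^2) + 1 / abs(form$curvature))
  out <- cbind(x0, z, deparse.level = 0)
  if (nrow(out) == 1L) drop(out) else out
}

# map an arbitrary nonzero ambient vector to the manifold (used for
# initialization and base-point sampling)
sf_normalize <- function(form, w) {
  w <- rbind(w)
  if (is_sphere(form)) {
    out <- w / (sqrt(rowSums(w^2)) * sqrt(form$curvature))
  } else {
    q <- -sf_norm2(form, w)                     # need timelike input
    if (any(q <= 0)) stop("cannot normalize a non-timelike vector to the hyperboloid")
    out <- w / sqrt(q * abs(form$curvature))
    out[out[, 1L] < 0, ] <- -out[out[, 1L] < 0, ]
  }
  if (nrow(out) == 1L) drop(out) else out
}
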
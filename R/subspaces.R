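#' Riemannian affine subspace of a space form
#'
#' The affine subspace at base point \eqn{p} spanned by a tangent subspace
#' \eqn{H \subseteq T_p} is \eqn{\exp_p(H)}; equivalently the intersection of
#' the manifold with the linear span \eqn{p \oplus H}, or the set of points
#' whose log at \eqn{p} is g-orthogonal to the complement \eqn{H^\perp}.
#' Raw spanning vectors are tangent-projected and Gram--Schmidt orthonormalized
#' under the metric at `p`; bases are stored with unit g-norm (curvature scale
#' factors are applied inside each closed-form formula).
#'
#' @param form A [space_form()].
#' @param base Point on the manifold (the subspace passes through it).
#' @param vectors Matrix with `K` rows of ambient vectors spanning `H` (they
#'   are projected to the tangent space at `base` first), or `NULL` for a
#'   zero-dimensional subspace (a point).
#' @return Object of class `"affine_subspace"`: list with `form`, `base`,
#'   `basis` (K x (D+1), unit g-norm rows), `complement` ((D-K) x (D+1)),
#'   `K`.
#' @export
affine_subspace <- function(form, base, vectors = NULL) {
  base <- as.numeric(base)
  sf_check_points(form, base)
  D <- form$dim
  if (is.null(vectors) || NROW(vectors) == 0L) {
    basis <- matrix(numeric(0), 0L, D + 1L)
  } else {
    vectors <- rbind(vectors)
    if (ncol(vectors) != D + 1L) stop("vectors must have ", D + 1L, " columns")
    basis <- gram_schmidt(form, base, vectors, n_keep = nrow(vectors))
    if (nrow(basis) < nrow(vectors))
      stop("rank deficiency: achieved rank ", nrow(basis), " of ", nrow(vectors))
  }
  complement <- complete_frame(form, base, basis)
  structure(list(form = form, base = base, basis = basis,
                 complement = complement, K = nrow(basis)),
            class = "affine_subspace")
}

#' @export
print.affine_subspace <- function(x, ...) {
  cat(sprintf("<affine_subspace> K = %d on %s (C = %g, D = %d)\n",
              x$K, x$form$type, x$form$curvature, x$form$dim))
  invisible(x)
}

# n x m matrix of metric inner products between rows of x and rows of B
gmat <- function(form, x, B) {
  x <- rbind(x)
  if (NROW(B) == 0L) return(matrix(0, nrow(x), 0L))
  B <- rbind(B)
  out <- if (is_sphere(form)) x %*% t(B)
         else x %*% (lorentz_J(form$dim) %*% t(B))
  dimnames(out) <- NULL
  out
}

# g-orthonormalize rows of `vectors` against `base` and each other.
# Drops directions whose residual g-norm falls below tol * original norm.
gram_schmidt <- function(form, base, vectors, n_keep = Inf, tol = 1e-10) {
  kept <- matrix(numeric(0), 0L, length(base))
  for (i in seq_len(nrow(vectors))) {
    w <- sf_tangent_project(form, base, vectors[i, ])
    if (nrow(kept) > 0L)
      for (j in seq_len(nrow(kept)))
        w <- w - sf_metric(form, w, kept[j, ]) * kept[j, ]
    n2 <- sf_norm2(form, w)
    if (n2 > tol^2 * max(1, sum(vectors[i, ]^2))) {
      kept <- rbind(kept, w / sqrt(n2))
      if (nrow(kept) >= n_keep) break
    }
  }
  kept
}

# complete (base, basis) to a full g-orthonormal tangent frame using standard
# basis seeds in fixed index order (deterministic complements)
complete_frame <- function(form, base, basis) {
  D <- form$dim
  need <- D - nrow(basis)
  if (need == 0L) return(matrix(numeric(0), 0L, D + 1L))
  seeds <- diag(D + 1L)
  comp <- matrix(numeric(0), 0L, D + 1L)
  for (i in seq_len(D + 1L)) {
    w <- sf_tangent_project(form, base, seeds[i, ])
    all_prev <- rbind(basis, comp)
    if (nrow(all_prev) > 0L)
      for (j in seq_len(nrow(all_prev)))
        w <- w - sf_metric(form, w, all_prev[j, ]) * all_prev[j, ]
    n2 <- sf_norm2(form, w)
    if (n2 > 1e-20) {
      comp <- rbind(comp, w / sqrt(n2))
      if (nrow(comp) >= need) break
    }
  }
  if (nrow(comp) < need) stop("failed to complete the orthogonal frame")
  comp
}

#' Closed-form geodesic projection distance
#'
#' Distance from a point to its geodesic projection on the subspace, by the
#' closed-form arccos / acosh expressions. Both the complement-basis form and
#' the subspace-basis form are implemented and agree; `via` selects one.
#'
#' @param sub An [affine_subspace()].
#' @param x Point (or matrix of points, rows) on the subspace's form.
#' @param via `"complement"` (residual energy on \eqn{H^\perp}) or `"span"`
#'   (energy on \eqn{p \oplus H}).
#' @return Nonnegative distance(s).
#' @export
proj_distance <- function(sub, x, via = c("complement", "span")) {
  via <- match.arg(via)
  form <- sub$form
  x <- sf_check_points(form, x)
  C <- form$curvature
  if (via == "complement") {
    resid <- rowSums(gmat(form, x, sub$complement)^2)
    if (is_sphere(form)) {
      # unit-g-norm complement basis: energy rescales by C relative to the
      # <h',h'> = C convention of the closed form
      acos(clip_acos_arg(sqrt(pmax(1 - C * resid, 0)))) / sqrt(C)
    } else {
      acosh(clip_acosh_arg(sqrt(1 + abs(C) * resid))) / sqrt(-C)
    }
  } else {
    bp <- sf_metric(form, x, sub$base)
    span <- rowSums(gmat(form, x, sub$basis)^2)
    if (is_sphere(form)) {
      s2 <- C^2 * bp^2 + C * span          # squared cosine of the angle
      acos(clip_acos_arg(sqrt(pmax(s2, 0)))) / sqrt(C)
    } else {
      c2 <- C^2 * bp^2 - abs(C) * span     # squared cosh of the distance
      acosh(clip_acosh_arg(sqrt(pmax(c2, 1)))) / sqrt(-C)
    }
  }
}

#' Geodesic projection onto an affine subspace
#'
#' Projects ambient coordinates metric-orthogonally onto the linear span
#' \eqn{p \oplus H} and renormalizes to the manifold (valid because the
#' subspace is the manifold's intersection with that span). On the sphere,
#' points at distance \eqn{C^{-1/2}\pi/2} have no unique projection; a
#' deterministic perturbation along the first basis direction breaks the tie
#' with a warning.
#'
#' @param sub An [affine_subspace()].
#' @param x Point or matrix of points.
#' @return Projected point(s) on the subspace.
#' @export
proj_point <- function(sub, x) {
  form <- sub$form
  x <- sf_check_points(form, x)
  C <- form$curvature
  # g-orthonormal frame of the span: f0 = sqrt(|C|) p (g-norm +1 / -1), basis rows
  f0 <- sqrt(abs(C)) * sub$base
  a0 <- drop(gmat(form, x, f0))
  y <- if (is_sphere(form)) outer(a0, f0) else outer(-a0, f0)
  if (sub$K > 0L) y <- y + gmat(form, x, sub$basis) %*% sub$basis
  q <- sf_norm2(form, y)
  bad <- if (is_sphere(form)) q < 1e-18 else -q < 1e-18
  if (any(bad)) {
    warning("non-unique projection: input orthogonal to the subspace span; ",
            "tie broken by deterministic perturbation")
    dirv <- if (sub$K > 0L) sub$basis[1, ] else f0
    x[bad, ] <- x[bad, , drop = FALSE] + 1e-9 * matrix(dirv, sum(bad),
                                                       length(dirv), byrow = TRUE)
    return(proj_point(sub, sf_normalize(form, x)))
  }
  out <- sf_normalize(form, y)
  out <- rbind(out)
  if (nrow(out) == 1L) drop(out) else out
}

#' Membership test for an affine subspace
#'
#' @param sub An [affine_subspace()].
#' @param x Point(s).
#' @param tol Relative tolerance on the complement inner products.
#' @return Logical vector.
#' @export
on_subspace <- function(sub, x, tol = 1e-8) {
  x <- rbind(x)
  if (nrow(sub$complement) == 0L) return(rep(TRUE, nrow(x)))
  resid <- abs(gmat(sub$form, x, sub$complement))
  apply(resid, 1L, max) <= tol * sqrt(rowSums(x^2))
}

#' Isometry onto the low-dimensional model space
#'
#' Maps subspace points to \eqn{S^K} or \eqn{H^K} of the same curvature via
#' coordinates in the g-orthonormal frame \eqn{\{\sqrt{|C|}p, h_1, \dots,
#' h_K\}}; preserves all pairwise geodesic distances exactly and inverts via
#' [from_low_dim()].
#'
#' @param sub An [affine_subspace()] with `K >= 1`.
#' @param x Point(s) on the subspace.
#' @param tol Membership tolerance.
#' @return Point(s) on the K-dimensional model with the same curvature.
#' @export
to_low_dim <- function(sub, x, tol = 1e-6) {
  form <- sub$form
  x <- sf_check_points(form, x)
  if (!all(on_subspace(sub, x, tol)))
    stop("point is not on the subspace (within tolerance)")
  a0 <- drop(gmat(form, x, sqrt(abs(form$curvature)) * sub$base))
  if (!is_sphere(form)) a0 <- -a0
  out <- cbind(a0, gmat(form, x, sub$basis), deparse.level = 0)
  out <- rbind(out)
  if (nrow(out) == 1L) drop(out) else out
}

#' Inverse of the low-dimensional isometry
#'
#' @param sub An [affine_subspace()].
#' @param y Point(s) on the K-dimensional model space (same curvature).
#' @return Point(s) on the subspace in ambient coordinates.
#' @export
from_low_dim <- function(sub, y) {
  form <- sub$form
  low <- space_form(form$curvature, max(sub$K, 1L))
  y <- sf_check_points(low, y, what = "low-dimensional points")
  sC <- sqrt(abs(form$curvature))
  out <- outer(y[, 1L] * sC, sub$base)
  if (sub$K > 0L)
    for (k in seq_len(sub$K)) out <- out + outer(y[, k + 1L], sub$basis[k, ])
  out <- rbind(out)
  if (nrow(out) == 1L) drop(out) else out
}

#' Sliced (J-)unitary operator of a subspace
#'
#' The \eqn{(D+1)\times(K+1)} matrix \eqn{G = [\sqrt{|C|}\,p, h_1, \dots,
#' h_K]} maps the low-dimensional model onto the subspace pointwise
#' (`G %*% y == from_low_dim(sub, y)`), with \eqn{G^\top G = I_{K+1}} on the
#' sphere and \eqn{G^\top J_D G = J_K} on the hyperboloid.
#'
#' @param sub An [affine_subspace()].
#' @return Numeric matrix G.
#' @export
sliced_operator <- function(sub) {
  G <- cbind(sqrt(abs(sub$form$curvature)) * sub$base,
             if (sub$K > 0L) t(sub$basis))
  dimnames(G) <- NULL
  G
}

#' Principal angles between the linear spans of two subspaces
#'
#' Euclidean principal angles between `span(p1, H1)` and `span(p2, H2)` (or
#' between the tangent bases alone with `tangent_only = TRUE`); the standard
#' measure of subspace recovery.
#'
#' @param a,b Matrices whose rows span the subspaces, or
#'   [affine_subspace()] objects.
#' @param tangent_only For subspace objects: compare only tangent bases.
#' @return Vector of principal angles (radians), ascending.
#' @export
principal_angles <- function(a, b, tangent_only = FALSE) {
  span_of <- function(s) {
    if (inherits(s, "affine_subspace")) {
      if (tangent_only) s$basis else rbind(s$base, s$basis)
    } else rbind(s)
  }
  A <- qr.Q(qr(t(span_of(a))))
  B <- qr.Q(qr(t(span_of(b))))
  cosv <- svd(crossprod(A, B))$d
  ang <- acos(pmin(pmax(cosv, -1), 1))               # ascending angles
  # acos loses precision near 1; recompute small angles from sines
  # (Bjorck-Golub): singular values of (I - A A') B are the sines, descending
  sins <- sort(svd(B - A %*% crossprod(A, B))$d)[seq_along(ang)]  # ascending like ang
  small <- ang < 0.1
  ang[small] <- asin(pmin(pmax(sins[small], 0), 1))
  ang
}

# --- JSON serialization (used by the CLI fit/transform commands) ---

#' Serialize / deserialize an affine subspace as JSON
#'
#' @param sub An [affine_subspace()].
#' @param path File path.
#' @return `write_subspace` returns `path` invisibly; `read_subspace` returns
#'   the reconstructed subspace.
#' @export
write_subspace <- function(sub, path) {
  obj <- list(schema = "spaceform/affine_subspace/1",
              curvature = sub$form$curvature, dim = sub$form$dim,
              convention = "unit-gnorm-basis",
              base = sub$base, basis = sub$basis)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_subspace
#' @export
read_subspace <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  form <- space_form(obj$curvature, obj$dim)
  basis <- if (is.null(obj$basis) || length(obj$basis) == 0L) NULL else rbind(obj$basis)
  affine_subspace(form, as.numeric(obj$base), basis)
}
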
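#' Map a compositional table to the unit sphere
#'
#' Rows are closed to proportions and square-root transformed, placing each
#' sample on the unit sphere \eqn{S^{D-1}} (curvature 1): the standard
#' square-root geometry for compositional (e.g. microbiome) data.
#'
#' @param table Nonnegative matrix or data.frame, samples in rows, features in
#'   columns; no all-zero rows.
#' @return Matrix of unit-norm points, one per row, with a `"form"` attribute
#'   holding the [space_form()].
#' @export
comp_to_sphere <- function(table) {
  x <- as.matrix(table)
  if (any(x < 0)) stop("compositional table must be nonnegative")
  rs <- rowSums(x)
  if (any(rs == 0)) stop("all-zero row(s): ", paste(which(rs == 0), collapse = ", "))
  out <- sqrt(x / rs)
  attr(out, "form") <- space_form(1, ncol(x) - 1L)
  out
}

comp_close <- function(table) {
  x <- as.matrix(table)
  x / rowSums(x)
}

#' Distance matrices for compositional data
#'
#' Four metrics on the samples of a compositional table: spherical geodesic
#' (S, on the square-root sphere), Aitchison (AI, Euclidean distance of
#' clr-transformed rows after a multiplicative pseudocount of half the
#' smallest nonzero proportion per row), square-root Jensen--Shannon
#' divergence (JS, base-2 logs so values lie in [0, 1]), and total variation
#' (TV, half the L1 distance of proportions).
#'
#' @param table Nonnegative matrix, samples in rows.
#' @return Named list of symmetric zero-diagonal matrices `S`, `AI`, `JS`,
#'   `TV`.
#' @export
comp_distances <- function(table) {
  p <- comp_close(table)
  s <- comp_to_sphere(table)
  S <- sf_pdist(attr(s, "form"), s)
  # Aitchison: clr after per-row pseudocount on zeros
  pz <- t(apply(p, 1L, function(r) {
    if (any(r == 0)) {
      eps <- min(r[r > 0]) / 2
      r[r == 0] <- eps
      r <- r / sum(r)
    }
    r
  }))
  clr <- log(pz) - rowMeans(log(pz))
  AI <- as.matrix(stats::dist(clr))
  JS <- js_distance(p)
  TV <- as.matrix(stats::dist(p, method = "manhattan")) / 2
  lapply(list(S = S, AI = AI, JS = JS, TV = TV), function(m) {
    dimnames(m) <- NULL; diag(m) <- 0; (m + t(m)) / 2
  })
}

js_distance <- function(p) {
  n <- nrow(p)
  xlogx <- function(z) ifelse(z > 0, z * log2(z), 0)
  H <- function(r) -rowSums(xlogx(r))       # Shannon entropy, bits
  Hp <- H(p)
  out <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    m <- (p[rep(i, n - i), , drop = FALSE] + p[(i + 1L):n, , drop = FALSE]) / 2
    jsd <- H(m) - (Hp[i] + Hp[(i + 1L):n]) / 2
    out[i, (i + 1L):n] <- sqrt(pmax(jsd, 0))
  }
  out + t(out)
}

#' Denoise compositional data through spherical PCA
#'
#' Maps the table to the square-root sphere, fits a K-dimensional spherical
#' affine subspace (SFPCA or the PGA baseline), projects the samples onto it,
#' and maps back to compositions by squaring coordinates and re-closing
#' (projection can produce small negative coordinates; squaring drops their
#' sign, a documented approximation). Reports the relative Frobenius
#' distortion \eqn{\|D_m - \hat D_m\|_F / \|D_m\|_F} of each metric's distance
#' matrix; the spherical one is computed from the projected sphere points
#' directly.
#'
#' @param table Nonnegative matrix, samples in rows.
#' @param K Subspace dimension, `1 <= K <= D - 1` for `D` features.
#' @param method `"sfpca"` or `"pga"`.
#' @return List with `compositions` (denoised, rows sum to 1), `projected`
#'   (sphere points), `fit`, and `distortion` (named numeric: S, AI, JS, TV).
#' @export
comp_denoise <- function(table, K, method = c("sfpca", "pga")) {
  method <- match.arg(method)
  s <- comp_to_sphere(table)
  form <- attr(s, "form")
  fit <- if (method == "sfpca") sfpca(unclass(s), form, K = K)
         else pga(unclass(s), form, K = K)
  proj <- rbind(proj_point(sf_subspace(fit, K), unclass(s)))
  comps <- comp_close(proj^2)
  ref <- comp_distances(table)
  est <- comp_distances(comps)
  est$S <- sf_pdist(form, proj)             # distortion of the sphere metric
                                            # from the projected points themselves
  distortion <- vapply(names(ref), function(m) {
    norm(ref[[m]] - est[[m]], "F") / max(norm(ref[[m]], "F"), .Machine$double.eps)
  }, numeric(1))
  list(compositions = comps, projected = proj, fit = fit, distortion = distortion)
}
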
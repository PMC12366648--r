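#' Patristic distance matrix of a gene tree
#'
#' Reads a tree (Newick text, file, or an `ape` `phylo` object), computes
#' path-length (patristic) distances between all leaves, and rescales branch
#' lengths so the matrix diameter equals `diameter` (default 10), making trees
#' of different depths comparable.
#'
#' @param tree Newick string, path to a Newick file, or a `phylo` object.
#' @param diameter Target diameter after rescaling; `NULL` disables rescaling.
#' @return List with `labels`, `matrix` (symmetric, zero diagonal), and
#'   `diameter`.
#' @export
tree_distances <- function(tree, diameter = 10) {
  phy <- as_phylo(tree)
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (anyNA(phy$edge.length)) stop("tree has missing branch lengths")
  d <- ape::cophenetic.phylo(phy)
  labs <- rownames(d)
  dimnames(d) <- NULL
  dia <- max(d)
  if (!is.null(diameter)) {
    if (dia <= 0) stop("tree has zero diameter; cannot rescale")
    d <- d * (diameter / dia)
    dia <- diameter
  }
  list(labels = labs, matrix = (d + t(d)) / 2, diameter = dia)
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1L) {
    phy <- suppressWarnings(
      if (file.exists(tree)) ape::read.tree(tree) else ape::read.tree(text = tree))
    if (is.null(phy)) stop("malformed Newick input")
    if (inherits(phy, "multiPhylo")) stop("expected a single tree; got ", length(phy))
    return(phy)
  }
  stop("tree must be a phylo object or Newick text/path")
}

#' Embed a distance matrix into hyperbolic space
#'
#' Lorentzian multidimensional scaling by closed-form spectral factorization:
#' the target Lorentzian Gram matrix \eqn{G_{ij} = C^{-1}\cosh(\sqrt{|C|}
#' d_{ij})} is factored through its most negative eigenpair (the timelike
#' coordinate) and its `D` leading positive eigenpairs (spatial coordinates);
#' spatial parts are then lifted exactly back to the hyperboloid sheet. Exact
#' on distance matrices realizable in \eqn{H^D}; otherwise a low-distortion
#' approximation whose error shrinks with `D`.
#'
#' @param dist Symmetric nonnegative distance matrix (or the list returned by
#'   [tree_distances()]).
#' @param D Embedding dimension (>= 2).
#' @param curvature Negative curvature of the target space.
#' @return Matrix of points on \eqn{H^D} (rows), with attributes `form`,
#'   `distortion` (relative Frobenius error of realized vs target distances),
#'   and `labels` when available.
#' @export
hyper_embed <- function(dist, D = 20L, curvature = -1) {
  labels <- NULL
  if (is.list(dist) && !is.null(dist$matrix)) { labels <- dist$labels; dist <- dist$matrix }
  dist <- as.matrix(dist)
  n <- nrow(dist)
  if (curvature >= 0) stop("curvature must be negative")
  form <- space_form(curvature, D)
  G <- cosh(sqrt(-curvature) * dist) / curvature
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  if (min(e$values) >= -1e-12 * max(abs(e$values)))
    stop("Gram matrix has no negative direction; input is not hyperbolic-like")
  i_neg <- which.min(e$values)
  pos <- setdiff(order(e$values, decreasing = TRUE), i_neg)[seq_len(min(D, n - 1L))]
  Z <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(pmax(e$values[pos], 0)), nrow = length(pos))
  Z <- cbind(Z, matrix(0, n, D - length(pos)))
  x <- rbind(sf_lift(form, Z))              # exact sheet constraint; x0 from spatial part
  realized <- sf_pdist(form, x)
  attr(x, "form") <- form
  attr(x, "distortion") <- norm(realized - dist, "F") / max(norm(dist, "F"),
                                                            .Machine$double.eps)
  attr(x, "labels") <- labels
  x
}

#' Quartet topology by the four-point condition
#'
#' Among the three pairings of four taxa, the tree-induced split is the one
#' with the minimal within-pair distance sum; ties break lexicographically
#' (`ab|cd`, then `ac|bd`, then `ad|bc`).
#'
#' @param d_ab,d_ac,d_ad,d_bc,d_bd,d_cd The six pairwise distances.
#' @return One of `"ab|cd"`, `"ac|bd"`, `"ad|bc"` (vectorized).
#' @export
quartet_topology <- function(d_ab, d_ac, d_ad, d_bc, d_bd, d_cd) {
  sums <- cbind(d_ab + d_cd, d_ac + d_bd, d_ad + d_bc)
  c("ab|cd", "ac|bd", "ad|bc")[apply(sums, 1L, which.min)]
}

#' Quartet score of a candidate distance structure
#'
#' Fraction of sampled 4-leaf subsets whose four-point-condition topology in
#' the candidate distances matches the reference tree's. Subsets are sampled
#' uniformly without replacement (all subsets are enumerated when fewer than
#' `n_quartets` exist).
#'
#' @param candidate Distance matrix, points matrix with a `form` attribute, or
#'   [tree_distances()] list, over the same leaves as `truth` (same order).
#' @param truth Reference: a tree (anything [tree_distances()] accepts) or a
#'   distance matrix/list.
#' @param n_quartets Number of 4-subsets to sample (default 1e5, capped at the
#'   total count).
#' @param seed Integer seed for the subset sample.
#' @return Score in [0, 1] with attribute `n_used`.
#' @export
quartet_score <- function(candidate, truth, n_quartets = 1e5, seed = 1L) {
  dc <- as_distance_matrix(candidate)
  dt <- as_distance_matrix(truth)
  n <- nrow(dt)
  if (nrow(dc) != n) stop("candidate and truth must cover the same leaf set")
  if (n < 4L) stop("need at least 4 leaves")
  total <- choose(n, 4)
  if (total <= n_quartets) {
    quads <- t(utils::combn(n, 4L))
  } else {
    set.seed(as.integer(seed) %% 2147483647L)
    # sample distinct 4-subsets by rejection on an encoded key
    want <- as.integer(n_quartets)
    got <- matrix(integer(0), 0L, 4L)
    seen <- character(0)
    while (nrow(got) < want) {
      draw <- t(replicate(2L * (want - nrow(got)),
                          sort.int(sample.int(n, 4L))))
      key <- paste(draw[, 1L], draw[, 2L], draw[, 3L], draw[, 4L])
      fresh <- !duplicated(key) & !(key %in% seen)
      got <- rbind(got, draw[fresh, , drop = FALSE])
      seen <- c(seen, key[fresh])
    }
    quads <- got[seq_len(want), , drop = FALSE]
  }
  top_of <- function(d) quartet_topology(
    d[cbind(quads[, 1L], quads[, 2L])], d[cbind(quads[, 1L], quads[, 3L])],
    d[cbind(quads[, 1L], quads[, 4L])], d[cbind(quads[, 2L], quads[, 3L])],
    d[cbind(quads[, 2L], quads[, 4L])], d[cbind(quads[, 3L], quads[, 4L])])
  score <- mean(top_of(dc) == top_of(dt))
  attr(score, "n_used") <- nrow(quads)
  score
}

as_distance_matrix <- function(x) {
  if (is.list(x) && !is.null(x$matrix)) return(x$matrix)
  if (inherits(x, "phylo") || (is.character(x) && length(x) == 1L))
    return(tree_distances(x)$matrix)
  x <- as.matrix(x)
  form <- attr(x, "form")
  if (!is.null(form) && ncol(x) == form$dim + 1L) return(sf_pdist(form, x))
  if (nrow(x) != ncol(x)) stop("cannot interpret input as distances")
  x
}

#' Retained-energy spectrum profile and knee point
#'
#' From the J-spectrum of the second moment of hyperbolic points (negative
#' pair first, positive J-eigenvalues \eqn{\lambda_2 \ge \dots} descending),
#' plots normalized retained energy \eqn{\sum_{k=2}^{K}\lambda_k /
#' \sum_{d=2}^{D}\lambda_d} against the normalized dimension \eqn{x = K/D}
#' for \eqn{K = 1, \dots, D} (the K = 1 numerator is the empty sum, so the
#' curve rises from (1/D, 0) to (1, 1)). The knee is the first crossing of
#' this piecewise-linear curve with the line \eqn{y = 1 - x}; a curve that
#' starts above the line gets the first grid x. A dominant \eqn{\lambda_2}
#' (an outlier direction) drives the curve toward (0, 1) and the knee toward
#' 0.
#'
#' @param x Points on a hyperboloid (rows), with a `form` attribute or an
#'   explicit `form` argument.
#' @param form Optional [space_form()] (negative curvature).
#' @return List with `xs`, `ys`, `knee`, `spectrum` (full J-spectrum), and
#'   `flags` (e.g. negative positive-part eigenvalues, underdetermined moment).
#' @export
spectrum_profile <- function(x, form = attr(x, "form")) {
  if (is.null(form)) stop("supply the space form of the points")
  x <- rbind(x)
  D <- form$dim
  flags <- character(0)
  if (nrow(x) < D + 1L) flags <- c(flags, "fewer points than ambient dimension")
  je <- j_eigen(second_moment(x, form)$matrix)
  lam <- je$values                          # [1] negative pair, then descending
  pos <- lam[-1L]
  if (any(pos < -1e-9)) flags <- c(flags, "negative positive-part J-eigenvalues")
  # retained energy sum_{k=2}^{K} / sum_{d=2}^{D}; at K = 1 the numerator is
  # the empty sum, so the curve starts at (1/D, 0) and rises to (1, 1)
  denom <- sum(pos[seq_len(D - 1L)])        # lambda_2 .. lambda_D as printed
  ys <- c(0, cumsum(pos[seq_len(D - 1L)]) / denom)
  xs <- (1:D) / D
  knee <- knee_point(xs, ys)
  list(xs = xs, ys = ys, knee = knee, spectrum = lam, signs = je$signs,
       flags = flags)
}

# first crossing of the piecewise-linear (xs, ys) curve with y = 1 - x
knee_point <- function(xs, ys) {
  g <- ys - (1 - xs)
  if (g[1L] >= 0) return(xs[1L])
  for (i in seq_len(length(xs) - 1L)) {
    if (g[i] < 0 && g[i + 1L] >= 0) {
      t <- g[i] / (g[i] - g[i + 1L])
      return(xs[i] + t * (xs[i + 1L] - xs[i]))
    }
  }
  xs[length(xs)]
}

#' Rank trees by hyperbolic spectrum knee point
#'
#' Embeds each tree (or accepts pre-embedded point sets), computes the
#' retained-energy knee, and returns the trees ordered by knee value. Small
#' knees indicate a spectrum dominated by few directions — the signature of
#' outlier content; both orderings are returned because the preferred
#' direction depends on whether outlier-rich or outlier-free trees are wanted
#' first.
#'
#' @param trees List of inputs [tree_distances()] accepts, or of embedded
#'   point matrices (with `form` attributes).
#' @param D Embedding dimension for tree inputs.
#' @param curvature Negative curvature for tree inputs.
#' @param order `"asc"` (default) or `"desc"` ordering of the reported
#'   ranking.
#' @return List with `knee` (per tree, NA on failure), `ranking` (indices in
#'   the configured order; ties keep input order), `asc`, `desc`, and
#'   `failures` (messages per failed tree).
#' @export
rank_trees <- function(trees, D = 20L, curvature = -1, order = c("asc", "desc")) {
  order <- match.arg(order)
  knees <- rep(NA_real_, length(trees))
  failures <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    res <- tryCatch({
      pts <- trees[[i]]
      if (!(is.matrix(pts) && !is.null(attr(pts, "form"))))
        pts <- hyper_embed(tree_distances(pts), D = D, curvature = curvature)
      spectrum_profile(pts)$knee
    }, error = function(e) e)
    if (inherits(res, "error")) failures[[i]] <- conditionMessage(res)
    else knees[i] <- res
  }
  asc <- order(knees, seq_along(knees), na.last = TRUE)
  desc <- order(-knees, seq_along(knees), na.last = TRUE)
  list(knee = knees, ranking = if (order == "asc") asc else desc,
       asc = asc, desc = desc,
       failures = failures[!vapply(failures, is.null, logical(1))])
}
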
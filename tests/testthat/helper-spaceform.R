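# shared fixtures and small independent oracles

# random point on a form (uses the current RNG stream)
rand_point <- function(form, spread = 0.5) {
  if (form$curvature > 0) spaceform:::sf_normalize(form, stats::rnorm(form$dim + 1L))
  else sf_lift(form, spread * stats::rnorm(form$dim))
}

# random tangent vector at p with roughly unit scale
rand_tangent <- function(form, p, scale = 0.5) {
  v <- sf_tangent_project(form, p, scale * stats::rnorm(form$dim + 1L))
  as.numeric(v)
}

# dense matrix exponential by scaled series (tests only; keeps the J-unitary
# fixture construction independent of the code under test)
expm_series <- function(M, terms = 40L) {
  s <- max(1L, ceiling(log2(max(1, max(abs(M))))))
  A <- M / 2^s
  R <- diag(nrow(M)); Tm <- diag(nrow(M))
  for (i in seq_len(terms)) { Tm <- Tm %*% A / i; R <- R + Tm }
  for (i in seq_len(s)) R <- R %*% R
  R
}

# random J-unitary matrix as the exponential of a J-skew generator J %*% S
rand_j_unitary <- function(D, scale = 0.5) {
  S <- matrix(stats::rnorm((D + 1L)^2), D + 1L, D + 1L) * scale
  S <- S - t(S)
  expm_series(lorentz_J(D) %*% S)
}

# brute-force geodesic projection distance: minimize d(x, y) over the subspace
# chart y = from_low_dim(sub, exp_pole(t)), multi-start Nelder-Mead
brute_proj_distance <- function(sub, x, restarts = 6L) {
  form <- sub$form
  K <- sub$K
  low <- space_form(form$curvature, max(K, 1L))
  pole <- c(1 / sqrt(abs(form$curvature)), rep(0, max(K, 1L)))
  obj <- function(t) {
    v <- sf_tangent_project(low, pole, c(0, t))
    y <- from_low_dim(sub, sf_exp(low, pole, v, validate = FALSE))
    sf_distance(form, x, y, validate = FALSE)
  }
  vals <- vapply(seq_len(restarts), function(i) {
    suppressWarnings(stats::optim(stats::rnorm(K) * 0.7, obj,
                                  control = list(maxit = 500,
                                                 reltol = 1e-12))$value)
  }, numeric(1))
  min(vals)
}

# small fixed compositional table used across compositional tests
fixture_composition <- function(n = 24L, d = 6L, seed = 42L) {
  withr::with_seed(seed, matrix(stats::rexp(n * d), n, d))
}
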
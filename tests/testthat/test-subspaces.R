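test_that("constructor orthonormalizes, preserves orthonormal input, flags rank", {
  set.seed(301)
  s3 <- space_form(1, 3)
  p <- c(1, 0, 0, 0)
  ortho <- rbind(c(0, 1, 0, 0), c(0, 0, 1, 0))
  sub <- affine_subspace(s3, p, ortho)
  expect_equal(sub$basis, ortho, tolerance = 1e-12)
  v <- c(0, 1, 1, 0)
  expect_error(affine_subspace(s3, p, rbind(v, 2 * v)), "rank")
  for (form in list(space_form(1, 5), space_form(-1, 5), space_form(-0.4, 4))) {
    q <- rand_point(form)
    raw <- matrix(rnorm(3 * (form$dim + 1)), 3)
    sub <- affine_subspace(form, q, raw)
    # basis Gram = identity under g; complement g-orthogonal to basis and base
    B <- rbind(sub$basis, sub$complement)
    G <- spaceform:::gmat(form, B, B)
    expect_lt(max(abs(G - diag(form$dim))), 1e-10)
    expect_lt(max(abs(spaceform:::gmat(form, B, q))), 1e-10)
    expect_equal(nrow(sub$complement), form$dim - 3L)
  }
})

test_that("closed-form projection distances match examples and each other", {
  s2 <- space_form(1, 2)
  equator <- affine_subspace(s2, c(1, 0, 0), rbind(c(0, 1, 0)))
  x <- c(cos(0.3), 0, sin(0.3))
  expect_equal(proj_distance(equator, x), 0.3, tolerance = 1e-12)
  h2 <- space_form(-1, 2)
  geod <- affine_subspace(h2, c(1, 0, 0), rbind(c(0, 1, 0)))
  xh <- c(cosh(0.3), 0, sinh(0.3))
  expect_equal(proj_distance(geod, xh), 0.3, tolerance = 1e-12)
  # on-subspace points are at distance zero
  expect_equal(proj_distance(equator, c(cos(1), sin(1), 0)), 0, tolerance = 1e-9)
  # complement-basis and span-basis forms agree on random instances
  set.seed(302)
  for (form in list(space_form(1, 5), space_form(-1, 5), space_form(2, 4),
                    space_form(-0.5, 4))) {
    sub <- random_subspace(form, 2)
    x <- synth_points(sub, 25, sigma = 0.4)$points
    expect_lt(max(abs(proj_distance(sub, x, via = "complement") -
                      proj_distance(sub, x, via = "span"))), 1e-9)
  }
})

test_that("closed-form distances equal the brute-force geodesic minimum", {
  set.seed(303)
  for (form in list(space_form(1, 3), space_form(-1, 4))) {
    sub <- random_subspace(form, 2)
    x <- synth_points(sub, 8, sigma = 0.4)$points
    for (i in seq_len(nrow(x))) {
      expect_equal(proj_distance(sub, x[i, ]),
                   brute_proj_distance(sub, x[i, ]), tolerance = 1e-4)
    }
  }
})

test_that("projection is idempotent, lands on the subspace, attains the distance", {
  s2 <- space_form(1, 2)
  equator <- affine_subspace(s2, c(1, 0, 0), rbind(c(0, 1, 0)))
  expect_equal(proj_point(equator, c(cos(0.3), 0, sin(0.3))), c(1, 0, 0),
               tolerance = 1e-12)
  on_it <- c(cos(0.7), sin(0.7), 0)
  expect_equal(proj_point(equator, on_it), on_it, tolerance = 1e-12)
  set.seed(304)
  for (form in list(space_form(1, 4), space_form(-1, 4))) {
    sub <- random_subspace(form, 2)
    x <- synth_points(sub, 20, sigma = 0.5)$points
    y <- rbind(proj_point(sub, x))
    expect_true(all(on_subspace(sub, y)))
    expect_true(all(sf_on_manifold(form, y)))
    expect_lt(max(abs(sf_distance(form, x, y) - proj_distance(sub, x))), 1e-8)
    expect_lt(max(abs(rbind(proj_point(sub, y)) - y)), 1e-9)
    # geodesics between projected points stay on the subspace
    g <- sf_exp(form, y[1, ], outer(c(0.25, 0.5, 0.75), sf_log(form, y[1, ], y[2, ])))
    expect_true(all(on_subspace(sub, g, tol = 1e-6)))
  }
})

test_that("non-unique spherical projection is tie-broken with a warning", {
  s2 <- space_form(1, 2)
  equator <- affine_subspace(s2, c(1, 0, 0), rbind(c(0, 1, 0)))
  expect_warning(y <- proj_point(equator, c(0, 0, 1)), "non-unique")
  expect_true(on_subspace(equator, y))
})

test_that("low-dimensional isometry preserves distances and round-trips", {
  set.seed(305)
  for (form in list(space_form(1, 5), space_form(-1, 5), space_form(-2, 4))) {
    sub <- random_subspace(form, 2)
    low <- space_form(form$curvature, 2)
    x <- rbind(proj_point(sub, synth_points(sub, 15, sigma = 0.3)$points))
    y <- to_low_dim(sub, x)
    expect_true(all(sf_on_manifold(low, y)))
    expect_lt(max(abs(sf_pdist(low, y) - sf_pdist(form, x))), 1e-9)
    expect_lt(max(abs(rbind(from_low_dim(sub, y)) - x)), 1e-10)
    # base point maps to the pole of the low-dimensional model
    pole <- to_low_dim(sub, sub$base)
    expect_equal(pole, c(1 / sqrt(abs(form$curvature)), 0, 0), tolerance = 1e-10)
    expect_equal(from_low_dim(sub, pole), sub$base, tolerance = 1e-10)
  }
  s3 <- space_form(1, 3)
  sub <- affine_subspace(s3, c(1, 0, 0, 0), rbind(c(0, 1, 0, 0)))
  expect_error(to_low_dim(sub, c(0, 0, 1, 0)), "not on the subspace")
  expect_error(from_low_dim(sub, c(2, 0)), "constraint")
})

test_that("sliced operator satisfies its constraint and reproduces from_low_dim", {
  s3 <- space_form(1, 3)
  triv <- affine_subspace(s3, c(1, 0, 0, 0), rbind(c(0, 1, 0, 0), c(0, 0, 1, 0)))
  expect_equal(sliced_operator(triv), diag(4)[, 1:3])
  set.seed(306)
  for (form in list(space_form(1, 5), space_form(-1, 5), space_form(-0.3, 4))) {
    sub <- random_subspace(form, 2)
    G <- sliced_operator(sub)
    if (form$curvature > 0) {
      expect_lt(max(abs(t(G) %*% G - diag(3))), 1e-10)
    } else {
      expect_lt(max(abs(t(G) %*% lorentz_J(form$dim) %*% G - lorentz_J(2))), 1e-10)
    }
    low <- space_form(form$curvature, 2)
    y <- rbind(t(replicate(5, rand_point(low))))
    expect_lt(max(abs(y %*% t(G) - rbind(from_low_dim(sub, y)))), 1e-10)
  }
})

test_that("subspace JSON serialization round-trips", {
  set.seed(307)
  form <- space_form(-1, 4)
  sub <- random_subspace(form, 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_subspace(sub, path)
  back <- read_subspace(path)
  expect_equal(back$base, sub$base, tolerance = 1e-12)
  expect_equal(back$basis, sub$basis, tolerance = 1e-12)
  expect_equal(back$form$curvature, form$curvature)
})
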
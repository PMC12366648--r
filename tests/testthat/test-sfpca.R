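test_that("second moment is the average outer product with the right trace", {
  s2 <- space_form(1, 2)
  x <- c(1, 0, 0)
  expect_equal(second_moment(rbind(x))$matrix, tcrossprod(x))
  expect_equal(second_moment(rbind(x, -x))$matrix, tcrossprod(x))
  set.seed(401)
  for (C in c(1, 2)) {
    form <- space_form(C, 3)
    pts <- t(replicate(20, rand_point(form)))
    expect_equal(sum(diag(second_moment(pts, form)$matrix)), 1 / C,
                 tolerance = 1e-10)
  }
  expect_error(second_moment(matrix(numeric(0), 0, 3)), "empty")
})

test_that("noiseless data on a planted subspace is recovered exactly", {
  set.seed(402)
  for (form in list(space_form(1, 6), space_form(-1, 6))) {
    for (K in c(1, 3)) {
      truth <- random_subspace(form, K)
      x <- synth_points(truth, 120, sigma = 0)$points
      fit <- sfpca(x, form, K = K)
      est <- sf_subspace(fit, K)
      expect_lt(max(principal_angles(truth, est)), 1e-6)
      expect_lt(subspace_cost(est, x), 1e-12)
    }
  }
})

test_that("identical points give the point itself as base with zero cost", {
  sph <- space_form(1, 3)
  x0 <- c(0.5, 0.5, 0.5, 0.5)
  fit <- sfpca(rbind(x0, x0, x0), sph, K = 1)
  expect_lt(min(sum((fit$base - x0)^2), sum((fit$base + x0)^2)), 1e-18)
  expect_equal(fit$spectrum, c(1, 0, 0, 0), tolerance = 1e-12)
  hyp <- space_form(-1, 3)
  xh <- sf_lift(hyp, c(0.3, -0.2, 0.1))
  fith <- sfpca(rbind(xh, xh), hyp, K = 1)
  expect_equal(fith$base, as.numeric(xh), tolerance = 1e-9)
  expect_lt(max(abs(fith$spectrum[-1])), 1e-10)
})

test_that("fitted subspace cost beats many random subspaces (optimality)", {
  set.seed(403)
  for (form in list(space_form(1, 5), space_form(-1, 5))) {
    truth <- random_subspace(form, 2)
    x <- synth_points(truth, 60, sigma = 0.4)$points
    best <- subspace_cost(sf_subspace(sfpca(x, form, K = 2), 2), x)
    rand_costs <- replicate(300, subspace_cost(random_subspace(form, 2), x))
    expect_lte(best, min(rand_costs) + 1e-12)
  }
})

test_that("cost equals the curvature-scaled sum of discarded eigenvalues", {
  set.seed(404)
  for (form in list(space_form(1, 5), space_form(-1.5, 5), space_form(0.7, 4))) {
    x <- synth_points(random_subspace(form, 2), 40, sigma = 0.5)$points
    fit <- sfpca(x, form, K = 2)
    disc <- abs(form$curvature) * sum(fit$spectrum[seq(4, form$dim + 1)])
    expect_equal(subspace_cost(sf_subspace(fit, 2), x), disc, tolerance = 1e-8)
  }
})

test_that("cost agrees with the distortion-of-distance identity", {
  # cost = E[f(d(x, proj x))] with f = sin^2(sqrt(C) d) or sinh^2(sqrt(|C|) d)
  s2 <- space_form(1, 2)
  equator <- affine_subspace(s2, c(1, 0, 0), rbind(c(0, 1, 0)))
  t <- 0.77
  expect_equal(subspace_cost(equator, rbind(c(cos(t), 0, sin(t)))), sin(t)^2,
               tolerance = 1e-12)
  set.seed(405)
  for (form in list(space_form(1, 4), space_form(-1, 4), space_form(-2, 4))) {
    sub <- random_subspace(form, 2)
    x <- synth_points(sub, 30, sigma = 0.4)$points
    d <- proj_distance(sub, x)
    f <- if (form$curvature > 0) sin(sqrt(form$curvature) * d)^2
         else sinh(sqrt(-form$curvature) * d)^2
    expect_equal(subspace_cost(sub, x), mean(f), tolerance = 1e-9)
  }
})

test_that("optima are nested, share the base point, and K=0 is the mean", {
  set.seed(406)
  for (form in list(space_form(1, 6), space_form(-1, 6))) {
    x <- synth_points(random_subspace(form, 3), 80, sigma = 0.3)$points
    fit <- sfpca(x, form)
    for (K1 in 1:4) {
      s1 <- sf_subspace(fit, K1)
      s2 <- sf_subspace(fit, K1 + 1)
      expect_lt(max(principal_angles(s1$basis, s2$basis)), 1e-8)
      expect_identical(s1$base, s2$base)
    }
    expect_equal(spaceform_mean(x, form), fit$base, tolerance = 1e-12)
  }
})

test_that("the space-form mean minimizes the distortion cost locally", {
  set.seed(407)
  for (form in list(space_form(1, 3), space_form(-1, 3))) {
    x <- synth_points(random_subspace(form, 1), 50, sigma = 0.3)$points
    m <- spaceform_mean(x, form)
    fcost <- function(p) {
      d <- sf_distance(form, rbind(p)[rep(1, nrow(x)), ], x, validate = FALSE)
      if (form$curvature > 0) mean(sin(sqrt(form$curvature) * d)^2)
      else mean(sinh(sqrt(-form$curvature) * d)^2)
    }
    base_cost <- fcost(m)
    # oracle: no random candidate point does better
    cand <- replicate(300, fcost(rand_point(form)))
    expect_lte(base_cost, min(cand) + 1e-12)
    # and no small perturbation of the mean does better
    pert <- replicate(50, {
      v <- rand_tangent(form, m, scale = 0.05)
      fcost(as.numeric(sf_exp(form, m, v, validate = FALSE)))
    })
    expect_lte(base_cost, min(pert) + 1e-10)
  }
})

test_that("K edge cases and input validation behave as documented", {
  set.seed(408)
  form <- space_form(1, 4)
  x <- synth_points(random_subspace(form, 2), 30, sigma = 0.2)$points
  fit0 <- sfpca(x, form, K = 0)
  expect_equal(sf_subspace(fit0, 0)$K, 0L)
  fitD <- sfpca(x, form, K = 4)
  expect_lt(subspace_cost(sf_subspace(fitD, 4), x), 1e-12)
  expect_error(sfpca(x, form, K = 5), "K must be")
  bad <- x; bad[3, ] <- bad[3, ] * 1.5
  expect_error(sfpca(bad, form), "constraint")
  expect_warning(fitr <- sfpca(bad, form, K = 2, repair = TRUE), "renormalized")
  expect_s3_class(fitr, "sfpca")
})

test_that("antipodal spherical pair flags the base-point tie", {
  x <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  fit <- suppressWarnings(sfpca(x, space_form(1, 2), K = 1))
  expect_true(fit$meta$base_tie)
})
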
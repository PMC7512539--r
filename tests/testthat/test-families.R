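test_that("square-root density evaluates correctly and enforces bounds", {
  fam <- family_normal1d()
  expect_equal(sqrt_density(fam, c(0, 1), 0), (2 * pi)^(-1 / 4),
               tolerance = 1e-12)
  # normalization of s^2 for several parameter values
  for (th in list(c(0, 1), c(2, 0.5), c(-3, 4))) {
    gr <- make_grid(th[1] + c(-12, 12) * th[2])
    expect_equal(sum(gr$weights * sqrt_density(fam, th, gr$nodes)^2), 1,
                 tolerance = 1e-8)
  }
  expect_error(sqrt_density(fam, c(0, -1), 0), "sigma")
  expect_error(sqrt_density(fam, c(0, 0), 0), "sigma")  # open bound
})

test_that("analytic sqrt-density derivatives match finite differences", {
  fam <- family_normal1d()
  theta <- c(0.3, 1.7)
  x <- seq(-5, 7, length.out = 41)
  an <- sqrt_density_derivatives(fam, theta, mode = "analytic")
  fd <- sqrt_density_derivatives(fam, theta, mode = "fd", h_rel = 1e-5)
  expect_identical(an$mode, "analytic")
  expect_lt(max(abs(an$sdot(x) - fd$sdot(x))), 1e-6)
  expect_lt(max(abs(an$sddot(x) - fd$sddot(x))), 1e-4)
  # central differences converge at second order: error slope ~ 2 in log h
  hs <- c(1e-2, 1e-3)
  errs <- vapply(hs, function(h) {
    fdh <- sqrt_density_derivatives(fam, theta, mode = "fd", h_rel = h)
    max(abs(an$sdot(x) - fdh$sdot(x)))
  }, numeric(1))
  slope <- diff(log(errs)) / diff(log(hs))
  expect_gt(slope, 1.7)
  expect_lt(slope, 2.3)
  expect_error(sqrt_density_derivatives(fam, c(0, 0)), "sigma")
})

test_that("location-family derivative identity and score centering hold", {
  fam <- family_normal1d()
  theta <- c(1.5, 1)
  bun <- sqrt_density_derivatives(fam, theta)
  gr <- make_grid(theta[1] + c(-12, 12))
  x <- gr$nodes
  # d/dmu of sqrt normal density is ((x - mu)/2) * s at sigma = 1
  expect_equal(bun$sdot(x)[, 1], (x - theta[1]) / 2 * bun$s(x),
               tolerance = 1e-12)
  # first-order optimality of T at the model: integral of sdot * s = 0
  for (j in 1:2)
    expect_lt(abs(sum(gr$weights * bun$sdot(x)[, j] * bun$s(x))), 1e-8)
})

test_that("Fisher information: closed forms, quadrature, invariance", {
  fam <- family_normal1d()
  expect_equal(fisher_information(fam, c(0, 2)), diag(c(1 / 4, 2 / 4)),
               tolerance = 1e-12)
  # quadrature of 4 * int sdot sdot' agrees with the closed form
  Iq <- fisher_information(fam, c(0.5, 1.3), force_quadrature = TRUE)
  expect_equal(Iq, diag(c(1 / 1.3^2, 2 / 1.3^2)), tolerance = 1e-6)
  # translation invariance of a location-scale family
  expect_equal(fisher_information(fam, c(-7, 1.3)),
               fisher_information(fam, c(4, 1.3)), tolerance = 1e-12)
  # 2-D: analytic information matches quadrature with FD derivatives
  fam2 <- family_normal2d()
  th2 <- c(0, 0, 1, 0.3, 2)
  Ia <- fisher_information(fam2, th2)
  g2 <- make_grid(rbind(c(-8, 8), c(-11, 11)), order = 8)
  Iq2 <- fisher_information(fam2, th2, grid = g2, force_quadrature = TRUE)
  expect_equal(Ia, Iq2, tolerance = 1e-4)
})

test_that("efficient influence function reduces to scaled score at the model", {
  fam <- family_normal1d()
  theta <- c(2, 1.5)
  g0 <- normal_density(2, 1.5)
  gr <- make_grid(theta[1] + c(-12, 12) * theta[2], order = 12)
  infl <- efficient_influence(fam, theta, g0, grid = gr)
  x <- seq(-4, 8, length.out = 25)
  v <- infl(x)
  # location coordinate: x - mu
  expect_equal(v[, 1], x - theta[1], tolerance = 1e-8)
  # centering under g0
  g0v <- eval_density(g0, gr$nodes)
  iv <- infl(gr$nodes)
  for (j in 1:2)
    expect_lt(abs(sum(gr$weights * iv[, j] * g0v)), 1e-8)
  # squared L-norm equals inverse Fisher information (diagonal here)
  ln <- l_norm(infl, g0, gr)
  expect_equal(ln^2, diag(solve(fisher_information(fam, theta))),
               tolerance = 1e-4)
})

test_that("arctan compactification is a faithful bijection for T", {
  fam <- family_normal1d()
  cf <- compactify(fam)
  expect_equal(cf$compactify_theta(c(0, 1)), c(0, pi / 4), tolerance = 1e-12)
  for (th in list(c(0, 1), c(-5, 0.2), c(100, 30)))
    expect_equal(uncompactify_theta(cf, cf$compactify_theta(th)), th,
                 tolerance = 1e-10)
  # T computed in compactified coordinates maps back to T in the original
  g <- random_histogram(4, seed = 11)
  gr <- make_grid(c(0, 1), breakpoints = (1:3) / 4)
  t_orig <- minimize_hellinger(fam, g, gr,
                               starts = list(c(0.5, 0.3)))$theta_hat
  t_comp <- minimize_hellinger(cf, g, gr,
                               starts = list(cf$compactify_theta(c(0.5, 0.3))))
  expect_equal(uncompactify_theta(cf, t_comp$theta_hat), t_orig,
               tolerance = 1e-4)
})
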
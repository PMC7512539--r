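test_that("binning follows the half-open convention with right-closed last bin", {
  expect_identical(bin_counts(c(0.1, 0.2, 0.7), 2), c(2L, 1L))
  expect_identical(bin_counts(1.0, 4), c(0L, 0L, 0L, 1L))
  expect_identical(bin_counts(numeric(0), 3), integer(3))
  expect_identical(bin_counts(c(0, 0.25, 0.5), 4), c(1L, 1L, 1L, 0L))
  expect_error(bin_counts(c(0.5, 1.2), 2), "1.2")
})

test_that("Dirichlet-multinomial conjugacy: update, mean, marginal", {
  spec <- histogram_spec(2, alpha = 1)
  expect_equal(posterior_update(spec, c(2, 1)), c(3, 2))
  expect_equal(posterior_update(spec, c(0, 0)), spec$alpha)
  expect_error(posterior_update(spec, c(-1, 2)), "negative")
  # posterior mean weights
  ap <- posterior_update(spec, c(2, 1))
  expect_equal(ap / sum(ap), c(0.6, 0.4))
  # k = 1 is the uniform density: marginal likelihood 1
  expect_equal(log_marginal_k(histogram_spec(1), 5L), 0)
  # hand-computed two-bin case: 2 * B((2,1)) / B((1,1)) = 1
  expect_equal(log_marginal_k(histogram_spec(2), c(1L, 0L)), 0,
               tolerance = 1e-12)
})

test_that("closed-form marginal likelihood matches prior-predictive Monte Carlo", {
  spec <- histogram_spec(3, alpha = c(0.5, 1, 2))
  x01 <- c(0.05, 0.35, 0.36, 0.8, 0.95)
  counts <- bin_counts(x01, 3)
  lm <- log_marginal_k(spec, counts)
  set.seed(42)
  B <- 1e5
  om <- matrix(rgamma(3 * B, shape = rep(spec$alpha, each = B)), B, 3)
  om <- om / rowSums(om)
  j <- pmin(floor(x01 * 3) + 1, 3)
  lik <- apply(om, 1, function(w) prod(3 * w[j]))
  mc <- mean(lik); se <- sd(lik) / sqrt(B)
  expect_lt(abs(exp(lm) - mc), 3 * se)
})

test_that("posterior fitting composes counts, conjugacy and k-weights", {
  post <- suppressWarnings(
    fit_histogram_posterior(c(0.1, 0.2, 0.7), k_prior_dirac(2),
                            data_map = "identity"))
  expect_length(post$records, 1)
  expect_equal(post$records[[1]]$alpha_post, c(3, 2))
  expect_equal(post$k_weights, 1)
  expect_error(fit_histogram_posterior(numeric(0)), "at least one")
  # two-component k prior: weights proportional to p(k) m(X | k)
  kp <- k_prior_pmf(c(0.3, 0.7), support = c(1L, 2L))
  post2 <- suppressWarnings(
    fit_histogram_posterior(c(0.1, 0.2, 0.7), kp, data_map = "identity"))
  m1 <- exp(log_marginal_k(histogram_spec(1), 3L))
  m2 <- exp(log_marginal_k(histogram_spec(2), c(2L, 1L)))
  expect_equal(post2$k_weights,
               c(0.3 * m1, 0.7 * m2) / (0.3 * m1 + 0.7 * m2),
               tolerance = 1e-12)
})

test_that("the expected posterior density is the exact conjugate closed form", {
  post <- suppressWarnings(
    fit_histogram_posterior(c(0.1, 0.2, 0.7), k_prior_dirac(2),
                            data_map = "identity"))
  g <- expected_posterior_density(post)
  expect_equal(eval_density(g, c(0.25, 0.75)), c(1.2, 0.8),
               tolerance = 1e-14)
  # integrates to one exactly (piecewise-constant closed form)
  gr <- make_grid(c(0, 1), breakpoints = 0.5)
  expect_equal(grid_integrate(gr, g), 1, tolerance = 1e-14)
})

test_that("the density EAP is Hellinger-consistent as n grows", {
  truth <- normal_density(0.5, 0.1)
  h <- numeric(3)
  ns <- c(100, 1000, 10000)
  set.seed(7)
  for (i in seq_along(ns)) {
    x <- rnorm(ns[i], 0.5, 0.1)
    x <- x[x > 0 & x < 1]  # the truth has negligible mass outside (0,1)
    post <- fit_histogram_posterior(x, k_prior_dirac(round(2 * ns[i]^(1 / 3))),
                                    alpha = function(k) rep(1 / k, k),
                                    data_map = "identity")
    g <- expected_posterior_density(post)
    gr <- make_grid(c(0, 1), breakpoints = g$breakpoints)
    h[i] <- hellinger_distance(truth, g, gr, mass_tol = 1)
  }
  expect_true(all(diff(h) < 0))
})

test_that("posterior density draws have the right law and are reproducible", {
  post <- suppressWarnings(
    fit_histogram_posterior(c(0.1, 0.2, 0.7, 0.8, 0.9), k_prior_dirac(2),
                            data_map = "identity"))
  draws <- sample_posterior_density(post, 2000, seed = 5)
  w1 <- vapply(draws, function(d) d$omega[1], numeric(1))
  expect_true(all(abs(vapply(draws, function(d) sum(d$omega), numeric(1)) - 1)
                  < 1e-12))
  ap <- post$records[[1]]$alpha_post
  m <- ap[1] / sum(ap)
  v <- ap[1] * (sum(ap) - ap[1]) / (sum(ap)^2 * (sum(ap) + 1))
  expect_lt(abs(mean(w1) - m), 3 * sqrt(v / 2000))
  draws2 <- sample_posterior_density(post, 2000, seed = 5)
  expect_identical(vapply(draws2, function(d) d$omega[1], numeric(1)), w1)
  expect_error(sample_posterior_density(post, 0), "positive")
})

test_that("L2 projection onto histograms is exact and monotone in k", {
  # uniform density is a fixed point for every k
  u <- density_fn(function(x) rep(1, length(x)), support = c(0, 1),
                  label = "uniform")
  for (k in c(1, 3, 5))
    expect_equal(project_density(u, k)$omega, rep(1 / k, k),
                 tolerance = 1e-12)
  # f(x) = 2x at k = 2: bin masses (1/4, 3/4), values (1/2, 3/2)
  f <- density_fn(function(x) 2 * x, support = c(0, 1), label = "2x")
  pr <- project_density(f, 2)
  expect_equal(pr$omega, c(0.25, 0.75), tolerance = 1e-10)
  expect_equal(eval_density(pr, c(0.2, 0.9)), c(0.5, 1.5), tolerance = 1e-10)
  # L2 error of the projection decreases monotonically in k
  l2err <- vapply(c(1, 2, 4, 8), function(k) {
    pk <- project_density(f, k)
    gr <- make_grid(c(0, 1), breakpoints = if (k > 1) (1:(k - 1)) / k)
    sqrt(grid_integrate(gr, (eval_density(f, gr$nodes) -
                               eval_density(pk, gr$nodes))^2))
  }, numeric(1))
  expect_true(all(diff(l2err) < 0))
})

test_that("k-prior constructors and the deterministic rate are sound", {
  kp <- k_prior_poisson(10, n = 500)
  expect_equal(sum(kp$pmf), 1, tolerance = 1e-12)
  expect_equal(max(kp$support), floor(500 / log(500)^2))
  expect_warning(default_Kn(66), "clamping")
  expect_identical(suppressWarnings(default_Kn(66)), 1L)
  expect_identical(default_Kn(1e6), 5L)
  expect_error(histogram_spec(3, alpha = c(1, -1, 1)), "positive")
  expect_warning(histogram_spec(4, alpha = 10, a = 1, c1 = 1, c2 = 2),
                 "bracket")
})

test_that("the automatic data map pads the observed range", {
  x <- c(-3, 7)
  dm <- auto_data_map(x, padding = 0.05)
  expect_equal(dm$to01(-3), 0.05 / 1.1, tolerance = 1e-12)
  expect_equal(dm$to01(dm$from01(0.3)), 0.3, tolerance = 1e-12)
  # histogram densities carry the Jacobian: total mass 1 on the data scale
  hd <- histogram_density(4, c(0.1, 0.4, 0.3, 0.2), dm)
  gr <- make_grid(hd$support, breakpoints = hd$breakpoints)
  expect_equal(grid_integrate(gr, hd), 1, tolerance = 1e-12)
})
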
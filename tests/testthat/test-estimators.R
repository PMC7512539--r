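test_that("MHB returns the exact parameter when fed a family member", {
  fam <- family_normal1d()
  g <- normal_density(0.7, 1.3)
  res <- mhb(data = numeric(0), fam, g, make_grid(c(-13, 15)))
  expect_equal(res$theta_hat, c(0.7, 1.3), tolerance = 1e-4)
  expect_identical(res$provenance$estimator, "mhb")
})

test_that("MHB with a histogram posterior is consistent on clean normal data", {
  set.seed(20)
  x <- rnorm(500)
  post <- fit_histogram_posterior(x, k_prior_dirac(25),
                                  alpha = function(k) rep(1 / k, k))
  g <- expected_posterior_density(post)
  res <- mhb(x, family_normal1d(), g)
  expect_lt(abs(res$theta_hat[1]), 0.15)
  expect_lt(abs(res$theta_hat[2] - 1), 0.15)
})

test_that("BMH on a degenerate density posterior reduces to MHB", {
  fam <- family_normal1d()
  g <- histogram_density(4, c(0.15, 0.35, 0.3, 0.2))
  gr <- make_grid(c(0, 1), breakpoints = (1:3) / 4)
  point <- mhb(numeric(0), fam, g, gr)
  post <- suppressWarnings(
    bmh(numeric(0), fam, rep(list(g), 60), gr))
  expect_equal(post$eap, point$theta_hat, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(unname(post$post_sd), c(0, 0), tolerance = 1e-5)
  expect_identical(post$n_failed, 0L)
  expect_true(post$valid)
})

test_that("BMH posterior from histogram draws covers the truth", {
  set.seed(21)
  x <- rnorm(500)
  post <- fit_histogram_posterior(x, k_prior_dirac(25),
                                  alpha = function(k) rep(1 / k, k))
  g <- expected_posterior_density(post)
  gr <- make_grid(g$support, breakpoints = g$breakpoints)
  draws <- sample_posterior_density(post, 150, seed = 22)
  tp <- bmh(x, family_normal1d(), draws, gr)
  expect_true(tp$valid)
  expect_lt(abs(tp$eap[1] - 0) / tp$post_sd[1], 3)
  expect_lt(abs(tp$eap[2] - 1) / tp$post_sd[2], 3)
})

test_that("the centered L2 norm has its closed-form special cases", {
  g0 <- normal_density(2, 1.5)
  gr <- make_grid(2 + c(-12, 12) * 1.5, order = 12)
  expect_equal(l_norm(function(x) rep(4.2, length(x)), g0, gr), 0,
               tolerance = 1e-10)
  expect_equal(l_norm(function(x) x - 2, g0, gr), 1.5, tolerance = 1e-8)
  # shift invariance of the centered norm
  expect_equal(l_norm(function(x) x + 100, g0, gr), 1.5, tolerance = 1e-6)
})

test_that("BvM diagnostic passes its null case and flags heavy tails", {
  fam <- family_normal1d()
  n <- 500
  I <- fisher_information(fam, c(0, 1))
  set.seed(23)
  draws <- cbind(rnorm(500, 0, sqrt(1 / (I[1, 1] * n))),
                 rnorm(500, 1, sqrt(1 / (I[2, 2] * n))))
  tp <- structure(list(draws = draws, eap = colMeans(draws),
                       post_sd = apply(draws, 2, sd),
                       n_failed = 0L, n_draws = 500L, valid = TRUE,
                       family = "normal1d",
                       param_names = c("mu", "sigma")),
                  class = "theta_posterior")
  rep1 <- bvm_diagnostic(tp, fam, n)
  expect_identical(rep1$verdict, "pass")
  expect_true(all(rep1$sd_ratio > 0.8 & rep1$sd_ratio < 1.2))
  # grossly heavy-tailed draws: normality test must reject
  draws2 <- draws
  draws2[, 1] <- 0 + rt(500, df = 2) * 0.05
  tp2 <- tp; tp2$draws <- draws2
  tp2$eap <- colMeans(draws2); tp2$post_sd <- apply(draws2, 2, sd)
  rep2 <- bvm_diagnostic(tp2, fam, n)
  expect_lt(rep2$normality$mu$p_value, 0.01)
  expect_identical(rep2$verdict, "fail")
})

test_that("BMH draws are invariant to the compactifying reparametrization", {
  fam <- family_normal1d()
  cf <- compactify(fam)
  post <- suppressWarnings(
    fit_histogram_posterior(c(0.2, 0.3, 0.45, 0.5, 0.62, 0.8),
                            k_prior_dirac(4), data_map = "identity"))
  draws <- sample_posterior_density(post, 10, seed = 31)
  gr <- make_grid(c(0, 1), breakpoints = (1:3) / 4)
  t_orig <- suppressWarnings(bmh(numeric(0), fam, draws, gr))
  t_comp <- suppressWarnings(bmh(numeric(0), cf, draws, gr,
                                 warm_start = FALSE))
  back <- t(apply(t_comp$draws, 1, function(t) uncompactify_theta(cf, t)))
  expect_equal(back, unname(t_orig$draws), tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("bootstrap standard errors for MHB are finite and sane", {
  set.seed(24)
  x <- rnorm(150, 5, 2)
  fit_density <- function(xx) expected_posterior_density(
    fit_histogram_posterior(xx, k_prior_dirac(12),
                            alpha = function(k) rep(1 / k, k)))
  bs <- mhb_bootstrap(x, family_normal1d(), fit_density, B = 25, seed = 25)
  expect_length(bs$se, 2)
  # close to the parametric rates sigma/sqrt(n), sigma/sqrt(2n)
  expect_lt(abs(bs$se[1] - 2 / sqrt(150)), 0.12)
  expect_lt(bs$se[2], 0.4)
})
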
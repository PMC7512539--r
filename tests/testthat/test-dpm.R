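test_that("a single tight cluster is recognized as one component", {
  set.seed(3)
  x <- rnorm(50, 0, 0.1)
  ch <- dpm_gibbs(x, n_iter = 500, burnin = 100, thin = 4, seed = 13)
  occ <- vapply(ch$states, function(s) length(s$cluster_params), numeric(1))
  expect_identical(as.integer(names(which.max(table(occ)))), 1L)
})

test_that("well-separated clusters are recovered with high purity", {
  set.seed(4)
  truth <- rep(1:2, each = 50)
  x <- c(rnorm(50, 0, 1), rnorm(50, 20, 1))
  ch <- dpm_gibbs(x, n_iter = 500, burnin = 100, thin = 4, seed = 21)
  st <- ch$states[[length(ch$states)]]
  tab <- table(st$assignments, truth)
  # each fitted cluster votes for its majority component; transient splits
  # within one component do not count against purity
  purity <- sum(apply(tab, 1, max)) / length(x)
  expect_gt(purity, 0.95)
})

test_that("chains are deterministic given the seed", {
  set.seed(5)
  x <- rnorm(40, 2, 1)
  ch1 <- dpm_gibbs(x, n_iter = 200, burnin = 50, thin = 5, seed = 99)
  ch2 <- dpm_gibbs(x, n_iter = 200, burnin = 50, thin = 5, seed = 99)
  expect_identical(ch1$states[[10]]$assignments,
                   ch2$states[[10]]$assignments)
  expect_identical(ch1$states[[10]]$cluster_params,
                   ch2$states[[10]]$cluster_params)
  expect_error(dpm_gibbs(x[1], seed = 1), "two observations")
  expect_error(dpm_gibbs(x, n_iter = 10, burnin = 10), "exceed")
})

test_that("state densities are proper and collapse to one normal when alpha -> 0", {
  set.seed(6)
  x <- rnorm(80, 1, 2)
  hyper <- dpm_hyper(dim = 1L, alpha = 1e-8)
  ch <- dpm_gibbs(x, hyper, n_iter = 300, burnin = 100, thin = 10, seed = 7)
  st <- ch$states[[length(ch$states)]]
  g <- density_draw(st, hyper, n = length(x))
  gr <- make_grid(c(1 - 20, 1 + 20))
  expect_equal(grid_integrate(gr, g), 1, tolerance = 1e-3)
  # the one-cluster state with negligible alpha is a single normal
  if (length(st$cluster_params) == 1) {
    p <- st$cluster_params[[1]]
    ref <- normal_density(p$mu, sqrt(p$Sigma[1, 1]))
    l1 <- grid_integrate(gr, abs(eval_density(g, gr$nodes) -
                                   eval_density(ref, gr$nodes)))
    expect_lt(l1, 0.05)
  }
})

test_that("the chain-averaged density estimates the truth", {
  set.seed(8)
  x <- rnorm(200, 3, 2)
  ch <- dpm_gibbs(x, n_iter = 800, burnin = 200, thin = 6, seed = 31)
  g <- eap_density(ch)
  gr <- make_grid(c(3 - 14, 3 + 14))
  # the diffuse multivariate-t base component carries a few tenths of a
  # percent of mass beyond any practical window
  expect_equal(grid_integrate(gr, g), 1, tolerance = 5e-3)
  truth <- normal_density(3, 2)
  l1 <- grid_integrate(gr, abs(eval_density(g, gr$nodes) -
                                 eval_density(truth, gr$nodes)))
  expect_lt(l1, 0.1)
})

test_that("occupied-cluster counts are exchangeable under permutation", {
  set.seed(9)
  x <- c(rnorm(40, 0, 1), rnorm(20, 6, 1))
  occ_of <- function(xx, sd)
    vapply(dpm_gibbs(xx, n_iter = 400, burnin = 100, thin = 3,
                     seed = sd)$states,
           function(s) length(s$cluster_params), numeric(1))
  o1 <- occ_of(x, 11)
  o2 <- occ_of(x[sample(length(x))], 11)
  expect_lt(abs(mean(o1) - mean(o2)), 1)
})

test_that("with almost no data the concentration reproduces its prior", {
  set.seed(10)
  x <- c(-0.1, 0.1)
  hyper <- dpm_hyper(dim = 1L, a0 = 2, b0 = 4, update_alpha = TRUE,
                     s2 = diag(1000, 1))
  ch <- dpm_gibbs(x, hyper, n_iter = 3000, burnin = 500, thin = 5, seed = 17)
  a <- vapply(ch$states, `[[`, numeric(1), "alpha_dp")
  # prior mean a0/b0 = 0.5; n = 2 adds very little information
  ess <- length(a) / 10  # conservative effective sample size
  expect_lt(abs(mean(a) - 0.5), 3 * sd(a) / sqrt(ess) + 0.15)
})

test_that("a bivariate run with an independent second coordinate agrees with
           the univariate reduction on the first coordinate", {
  set.seed(12)
  x1 <- rnorm(120, 1, 1)
  x2 <- rnorm(120, 0, 1)
  ch1 <- dpm_gibbs(x1, n_iter = 600, burnin = 200, thin = 4, seed = 41)
  ch2 <- dpm_gibbs(cbind(x1, x2), n_iter = 600, burnin = 200, thin = 4,
                   seed = 41)
  g1 <- eap_density(ch1)
  g2 <- eap_density(ch2)
  fam1 <- family_normal1d()
  fam2 <- family_normal2d()
  gr1 <- make_grid(range(x1) + c(-4, 4))
  gr2 <- make_grid(rbind(range(x1) + c(-4, 4), range(x2) + c(-4, 4)),
                   order = 6)
  t1 <- minimize_hellinger(fam1, g1, gr1, mass_tol = 0.05)$theta_hat
  t2 <- minimize_hellinger(fam2, g2, gr2, mass_tol = 0.05)$theta_hat
  expect_lt(abs(t1[1] - t2[1]), 0.15)       # mean of the first coordinate
  expect_lt(abs(t1[2]^2 - t2[3]), 0.35)     # its variance
})
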
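# Shared fixtures: small densities and grids built in code.

normal_density <- function(mu = 0, sigma = 1) {
  density_fn(function(x) stats::dnorm(x, mu, sigma), dim = 1L,
             label = sprintf("N(%g, %g^2)", mu, sigma))
}

# equal-mix of two unit normals
bimodal_density <- function(m = 3) {
  density_fn(function(x) 0.5 * dnorm(x, -m) + 0.5 * dnorm(x, m), dim = 1L,
             label = "bimodal")
}

# random histogram density on [0,1] with k bins
random_histogram <- function(k, seed) {
  set.seed(seed)
  w <- rgamma(k, shape = 2)
  histogram_density(k, w / sum(w))
}

# normal location family with fixed unit sd (exercises custom registration)
location_family <- function(sigma = 1) {
  parametric_family(
    name = "normal_loc", param_dim = 1L, param_names = "mu", dim = 1L,
    pdf = function(theta, x) dnorm(x, theta[1], sigma),
    param_bounds = matrix(c(-Inf, Inf), 1),
    mle = function(x) mean(x),
    sampler = function(theta, n) rnorm(n, theta[1], sigma),
    scale_at = function(theta) sigma,
    default_window = function(theta) theta[1] + c(-10, 10) * sigma,
    auto_starts = function(gv, grid) {
      m <- sum(grid$weights * gv * grid$nodes) / sum(grid$weights * gv)
      list(m, m + 1, m - 1)
    }
  )
}

# dense grid-search oracle for T over (mu, sigma) on a lattice
grid_search_T <- function(g, grid, mu_range, sigma_range, n_lattice = 200) {
  mus <- seq(mu_range[1], mu_range[2], length.out = n_lattice)
  sigmas <- seq(sigma_range[1], sigma_range[2], length.out = n_lattice)
  sqg <- sqrt(eval_density(g, grid$nodes))
  w <- grid$weights
  best <- c(NA, NA); best_aff <- -Inf
  for (s in sigmas) {
    # vectorize over mu: affinity(mu) for fixed sigma
    aff <- vapply(mus, function(m)
      sum(w * sqrt(dnorm(grid$nodes, m, s)) * sqg), numeric(1))
    i <- which.max(aff)
    if (aff[i] > best_aff) { best_aff <- aff[i]; best <- c(mus[i], s) }
  }
  list(theta = best, affinity = best_aff,
       resolution = c(diff(mu_range), diff(sigma_range)) / (n_lattice - 1))
}
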
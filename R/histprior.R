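#' Affine map between the data scale and the unit interval
#'
#' The random histogram prior lives on `[0, 1]`; raw data are carried there
#' by an affine map and densities are mapped back with the Jacobian
#' correction `1 / scale`.
#'
#' @param offset,scale the map is `x01 = (x - offset) / scale`.
#' @return object of class `affine_map` with `to01`, `from01`, `scale`.
#' @export
affine_map <- function(offset, scale) {
  stopifnot(is.finite(offset), is.finite(scale), scale > 0)
  structure(list(offset = offset, scale = scale,
                 to01 = function(x) (x - offset) / scale,
                 from01 = function(u) offset + scale * u),
            class = "affine_map")
}

#' Data-driven affine map with padding
#'
#' Maps `[min - p * range, max + p * range]` onto `[0, 1]`; the padding `p`
#' keeps boundary observations strictly inside the unit interval.
#'
#' @param x numeric data.
#' @param padding fraction of the data range added on each side
#'   (default 0.05).
#' @return an [affine_map()].
#' @export
auto_data_map <- function(x, padding = 0.05) {
  r <- range(x)
  width <- diff(r)
  if (width == 0) width <- max(abs(r[1]), 1)
  affine_map(offset = r[1] - padding * width,
             scale = width * (1 + 2 * padding))
}

#' Histogram prior specification for fixed k
#'
#' `k` equal bins on `[0, 1]` with a Dirichlet prior on the bin weights.
#' When `(a, c1, c2)` are supplied, the concentration vector is checked
#' against the bracket `c1 * k^(-a) <= alpha_j <= c2` (warning if violated).
#'
#' @param k number of bins (>= 1).
#' @param alpha Dirichlet concentration: scalar (broadcast) or length-k
#'   positive vector; default 1 (uniform Dirichlet).
#' @param a,c1,c2 optional bracket constants for the concentration check.
#' @return object of class `histogram_spec`.
#' @export
histogram_spec <- function(k, alpha = 1, a = NULL, c1 = NULL, c2 = NULL) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  if (length(alpha) == 1L) alpha <- rep(alpha, k)
  stopifnot(length(alpha) == k)
  if (any(alpha <= 0)) stop("all Dirichlet concentrations must be positive")
  if (!is.null(a) && !is.null(c1) && !is.null(c2)) {
    if (any(alpha < c1 * k^(-a)) || any(alpha > c2))
      warning("concentration vector violates the bracket c1*k^(-a) <= ",
              "alpha_j <= c2")
  }
  structure(list(k = k, alpha = as.numeric(alpha)),
            class = "histogram_spec")
}

#' Priors on the number of histogram bins
#'
#' `k_prior_dirac(k)` puts all mass on one bin count.
#' `k_prior_poisson(lambda, n)` is the zero-truncated Poisson restricted to
#' `{1, ..., floor(n / log(n)^2)}` and renormalized; the Poisson satisfies
#' the required tail envelope `exp(-b k log k)`.
#'
#' @param k fixed bin count.
#' @return object of class `k_prior` (`kind`, and either `k_fixed` or a
#'   normalized `pmf` with its integer `support`).
#' @export
k_prior_dirac <- function(k) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  structure(list(kind = "dirac", k_fixed = k), class = "k_prior")
}

#' @param lambda Poisson mean (default 10).
#' @param n sample size, which bounds the support at `floor(n / log(n)^2)`.
#' @rdname k_prior_dirac
#' @export
k_prior_poisson <- function(lambda = 10, n) {
  kmax <- max(1L, as.integer(floor(n / log(max(n, 3))^2)))
  support <- seq_len(kmax)
  p <- stats::dpois(support, lambda)
  if (sum(p) <= 0) p <- rep(1, kmax)
  k_prior_pmf(p / sum(p), support)
}

#' @param pmf probabilities over `support` (normalized internally).
#' @param support integer bin counts.
#' @rdname k_prior_dirac
#' @export
k_prior_pmf <- function(pmf, support = seq_along(pmf)) {
  stopifnot(length(pmf) == length(support), all(pmf >= 0), sum(pmf) > 0,
            all(support >= 1))
  pmf <- pmf / sum(pmf)
  structure(list(kind = "pmf", pmf = pmf, support = as.integer(support)),
            class = "k_prior")
}

#' Default deterministic bin count
#'
#' The rate-optimal deterministic choice `Kn = n^(1/2) / log(n)^2`, clamped
#' below at 1 (with a warning, since for practically small `n` the formula
#' falls under one bin and a user-chosen `k` is more useful).
#'
#' @param n sample size.
#' @return integer bin count.
#' @export
default_Kn <- function(n) {
  k <- round(sqrt(n) / log(max(n, 3))^2)
  if (k < 1) {
    warning("Kn(n) < 1 at n = ", n, "; clamping to 1 bin. ",
            "Consider supplying k explicitly.")
    k <- 1
  }
  as.integer(k)
}

#' Bin counts on the unit interval
#'
#' Bins are `I_j = [(j-1)/k, j/k)` with the last bin right-closed.
#'
#' @param data01 points in `[0, 1]`.
#' @param k number of bins.
#' @return integer vector of length `k` summing to `length(data01)`.
#' @export
bin_counts <- function(data01, k) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  if (length(data01) == 0) return(integer(k))
  bad <- which(data01 < 0 | data01 > 1)
  if (length(bad))
    stop("point ", signif(data01[bad[1]], 8), " (index ", bad[1],
         ") lies outside [0, 1]")
  j <- pmin(floor(data01 * k) + 1L, k)  # x = 1 falls in bin k
  tabulate(j, nbins = k)
}

#' Conjugate Dirichlet update of the bin weights
#'
#' @param spec a [histogram_spec()].
#' @param counts bin counts of length `spec$k`.
#' @return posterior concentration vector `alpha + counts`.
#' @export
posterior_update <- function(spec, counts) {
  stopifnot(inherits(spec, "histogram_spec"), length(counts) == spec$k)
  if (any(counts < 0)) stop("negative bin counts")
  spec$alpha + counts
}

#' Log marginal likelihood of the data under one bin count
#'
#' The histogram likelihood is multinomial in the bin weights, so the
#' marginal is available in closed form:
#' `n log k + log B(alpha + counts) - log B(alpha)` with `B` the Dirichlet
#' normalizer.
#'
#' @param spec a [histogram_spec()].
#' @param counts bin counts of length `spec$k`.
#' @return log marginal likelihood (finite real).
#' @export
log_marginal_k <- function(spec, counts) {
  stopifnot(inherits(spec, "histogram_spec"), length(counts) == spec$k)
  if (any(counts < 0)) stop("negative bin counts")
  n <- sum(counts)
  lB <- function(a) sum(lgamma(a)) - lgamma(sum(a))
  n * log(spec$k) + lB(spec$alpha + counts) - lB(spec$alpha)
}

#' Fit the random-histogram posterior
#'
#' Conjugate posterior over bin weights for every bin count in the support
#' of the k-prior, with posterior weights over k proportional to
#' `p_k(k) * m(X | k)`.
#'
#' @param data raw numeric sample (any scale).
#' @param k_prior a [k_prior_dirac()] / [k_prior_poisson()] /
#'   [k_prior_pmf()]; default: Dirac at [default_Kn()].
#' @param alpha Dirichlet concentration per bin, scalar or per-k rule
#'   (a function `k -> alpha vector`); default 1.
#' @param data_map `"auto"` (see [auto_data_map()]), `"identity"` (data
#'   already in `[0, 1]`), or an [affine_map()].
#' @param padding padding used by the automatic data map.
#' @return object of class `histogram_posterior`: `records` (one per k:
#'   `k`, `alpha`, `counts`, `alpha_post`, `log_marginal`), `k_weights`,
#'   `data_map`, `n`.
#' @export
fit_histogram_posterior <- function(data, k_prior = NULL, alpha = 1,
                                    data_map = "auto", padding = 0.05) {
  data <- as.numeric(data)
  n <- length(data)
  if (n < 1) stop("need at least one observation")
  if (is.null(k_prior)) k_prior <- k_prior_dirac(default_Kn(n))
  stopifnot(inherits(k_prior, "k_prior"))
  dm <- if (identical(data_map, "auto")) auto_data_map(data, padding)
  else if (identical(data_map, "identity")) affine_map(0, 1)
  else data_map
  stopifnot(inherits(dm, "affine_map"))
  x01 <- dm$to01(data)
  if (any(x01 < 0 | x01 > 1))
    stop("data fall outside the unit interval under the supplied data map")
  ks <- if (k_prior$kind == "dirac") k_prior$k_fixed else k_prior$support
  logp <- if (k_prior$kind == "dirac") 0 else log(k_prior$pmf)
  if (!length(ks)) stop("k prior has empty support")
  alpha_rule <- if (is.function(alpha)) alpha else function(k) rep(alpha, k)
  records <- vector("list", length(ks))
  logpost <- numeric(length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    spec <- histogram_spec(k, alpha_rule(k))
    if (sum(spec$alpha) > n / 10)
      warning("sum of concentrations (", signif(sum(spec$alpha), 4),
              ") is large relative to n = ", n,
              " at k = ", k, "; the prior may dominate")
    counts <- bin_counts(x01, k)
    lm <- log_marginal_k(spec, counts)
    records[[i]] <- list(k = k, alpha = spec$alpha, counts = counts,
                         alpha_post = posterior_update(spec, counts),
                         log_marginal = lm)
    logpost[i] <- logp[min(i, length(logp))] + lm
  }
  kw <- exp(logpost - log_sum_exp(logpost))
  kw <- kw / sum(kw)
  structure(list(records = records, k_weights = kw, data_map = dm, n = n),
            class = "histogram_posterior")
}

#' @export
print.histogram_posterior <- function(x, ...) {
  ks <- vapply(x$records, `[[`, numeric(1), "k")
  cat("<histogram_posterior> n = ", x$n, ", k in {",
      paste(ks, collapse = ", "), "}\n  k weights: ",
      paste(signif(x$k_weights, 3), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' A histogram density on the data scale
#'
#' Piecewise-constant density with value `k * omega_j` on bin `j` of the
#' unit interval, mapped to the original scale with the Jacobian of the
#' data map.
#'
#' @param k number of bins.
#' @param omega simplex weight vector of length `k`.
#' @param data_map an [affine_map()] (identity for densities on `[0,1]`).
#' @return a [density_fn()] of subclass `histogram_density` with fields
#'   `k`, `omega`, `data_map`.
#' @export
histogram_density <- function(k, omega, data_map = affine_map(0, 1)) {
  k <- as.integer(k)
  stopifnot(length(omega) == k, all(omega >= -1e-12))
  omega <- pmax(omega, 0)
  if (abs(sum(omega) - 1) > 1e-9)
    stop("histogram weights must sum to 1")
  omega <- omega / sum(omega)
  vals01 <- k * omega
  pdf <- function(x) {
    u <- data_map$to01(x)
    out <- numeric(length(u))
    inside <- u >= 0 & u <= 1
    j <- pmin(floor(u[inside] * k) + 1L, k)
    out[inside] <- vals01[j] / data_map$scale
    out
  }
  d <- density_fn(pdf, dim = 1L,
                  support = c(data_map$from01(0), data_map$from01(1)),
                  breakpoints = data_map$from01((1:(k - 1)) / k),
                  label = sprintf("histogram k=%d", k))
  d$k <- k; d$omega <- omega; d$data_map <- data_map
  class(d) <- c("histogram_density", class(d))
  d
}

#' Expected posterior density (the density EAP)
#'
#' The posterior expectation of the random density: a mixture over k of
#' histograms with posterior-mean weights
#' `(alpha_j + n_j) / (sum(alpha) + n)`.  Closed form; integrates to 1
#' exactly.
#'
#' @param post a [fit_histogram_posterior()] result.
#' @return a [density_fn()]; when a single k carries all posterior weight
#'   the result is the corresponding [histogram_density()].
#' @export
expected_posterior_density <- function(post) {
  stopifnot(inherits(post, "histogram_posterior"))
  means <- lapply(post$records, function(r) r$alpha_post / sum(r$alpha_post))
  if (length(post$records) == 1L)
    return(histogram_density(post$records[[1]]$k, means[[1]], post$data_map))
  kw <- post$k_weights
  dens <- Map(function(r, m) histogram_density(r$k, m, post$data_map),
              post$records, means)
  bps <- sort(unique(unlist(lapply(dens, function(d) d$breakpoints))))
  pdf <- function(x) {
    v <- 0
    for (i in seq_along(dens)) v <- v + kw[i] * dens[[i]]$pdf(x)
    v
  }
  density_fn(pdf, dim = 1L, support = dens[[1]]$support, breakpoints = bps,
             label = "histogram posterior mean")
}

#' Draw densities from the histogram posterior
#'
#' Each draw samples `k` from the posterior over bin counts and then
#' `omega ~ Dirichlet(alpha_post(k))`.
#'
#' @param post a [fit_histogram_posterior()] result.
#' @param n_draws number of density draws (> 0).
#' @param seed RNG seed (optional).
#' @return list of [histogram_density()] objects.
#' @export
sample_posterior_density <- function(post, n_draws, seed = NULL) {
  stopifnot(inherits(post, "histogram_posterior"))
  n_draws <- as.integer(n_draws)
  if (n_draws <= 0) stop("n_draws must be positive")
  with_seed(seed, {
    ki <- sample.int(length(post$records), n_draws, replace = TRUE,
                     prob = post$k_weights)
    lapply(ki, function(i) {
      ap <- post$records[[i]]$alpha_post
      gam <- stats::rgamma(length(ap), shape = ap)
      while (sum(gam) == 0) gam <- stats::rgamma(length(ap), shape = ap)
      histogram_density(post$records[[i]]$k, gam / sum(gam), post$data_map)
    })
  })
}

#' L2 projection of a density onto the k-bin histograms
#'
#' `f[k] = k * sum_j 1(I_j) * integral_{I_j} f`, computed by per-bin
#' Gauss--Legendre quadrature.
#'
#' @param f a [density_fn()] on `[0, 1]`.
#' @param k number of bins.
#' @param order quadrature order per bin.
#' @return a [histogram_density()] on `[0, 1]`.
#' @export
project_density <- function(f, k, order = 16) {
  stopifnot(inherits(f, "density_fn"), f$dim == 1L)
  k <- as.integer(k)
  edges <- (0:k) / k
  masses <- vapply(seq_len(k), function(j) {
    g <- make_grid(c(edges[j], edges[j + 1]),
                   breakpoints = f$breakpoints, order = order)
    v <- eval_density(f, g$nodes)
    if (any(!is.finite(v))) stop("quadrature failure on bin ", j)
    sum(g$weights * v)
  }, numeric(1))
  tot <- sum(masses)
  if (!is.finite(tot) || tot <= 0) stop("density has no mass on [0, 1]")
  if (abs(tot - 1) > 1e-6)
    warning("density mass on [0,1] is ", signif(tot, 8),
            "; projection renormalized")
  histogram_density(k, masses / tot)
}
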
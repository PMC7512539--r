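#' Finite mixture specification with exact component counts
#'
#' @param weights component weights (sum to 1).
#' @param means list of mean vectors.
#' @param covs list of covariance matrices (symmetric positive definite).
#' @param exact_counts optional integer counts per component; when set, the
#'   generator draws exactly these many points from each component (never
#'   merely in expectation).
#' @return object of class `mixture_spec`.
#' @export
mixture_spec <- function(weights, means, covs, exact_counts = NULL) {
  stopifnot(abs(sum(weights) - 1) < 1e-8,
            length(means) == length(weights),
            length(covs) == length(weights))
  covs <- lapply(covs, as.matrix)
  stopifnot(all(vapply(covs, is_square_pd, logical(1))))
  if (!is.null(exact_counts))
    stopifnot(length(exact_counts) == length(weights),
              all(exact_counts >= 0))
  structure(list(weights = weights, means = lapply(means, as.numeric),
                 covs = covs, exact_counts = exact_counts),
            class = "mixture_spec")
}

#' Sample a finite normal mixture
#'
#' @param spec a [mixture_spec()].
#' @param n sample size; with `exact_counts` set it must equal their sum.
#' @param seed RNG seed.
#' @param labels also return the component label of each row.
#' @return `n x d` matrix (or numeric vector for d = 1), rows shuffled;
#'   with `labels = TRUE`, attribute `"labels"` carries component indices.
#' @export
gen_mixture <- function(spec, n, seed = NULL, labels = FALSE) {
  stopifnot(inherits(spec, "mixture_spec"))
  d <- length(spec$means[[1]])
  counts <- spec$exact_counts
  with_seed(seed, {
    if (is.null(counts))
      counts <- as.vector(stats::rmultinom(1, n, spec$weights))
    stopifnot(sum(counts) == n)
    xs <- vector("list", length(counts))
    for (i in seq_along(counts)) {
      if (counts[i] == 0) { xs[[i]] <- matrix(0, 0, d); next }
      L <- chol(spec$covs[[i]])
      z <- matrix(stats::rnorm(counts[i] * d), counts[i], d) %*% L
      xs[[i]] <- sweep(z, 2, spec$means[[i]], `+`)
    }
    x <- do.call(rbind, xs)
    lab <- rep(seq_along(counts), counts)
    ord <- sample.int(n)
    x <- x[ord, , drop = FALSE]
    lab <- lab[ord]
    if (d == 1) x <- drop(x)
    if (labels) attr(x, "labels") <- lab
    x
  })
}

#' Contaminated bivariate normal demonstration sample
#'
#' 90% of the points come from `N((10, 5), [[3, 1], [1, 2]])` and exactly
#' 5% each from two contaminating Gaussians at `(-2, 5)` and `(10, 14)`
#' (covariances `[[0.5, 0.1], [0.1, 0.5]]` and `[[0.4, -0.1], [-0.1, 0.4]]`).
#' Counts are exact, scaled proportionally when `n != 100`.
#'
#' @param n sample size (default 100, minimum 10).
#' @param seed RNG seed.
#' @param labels attach component labels as an attribute.
#' @return `n x 2` matrix, rows shuffled.
#' @export
gen_bivariate_demo <- function(n = 100, seed = NULL, labels = FALSE) {
  stopifnot(n >= 10)
  n_out <- round(0.05 * n)
  counts <- c(n - 2 * n_out, n_out, n_out)
  spec <- mixture_spec(
    weights = c(0.9, 0.05, 0.05),
    means = list(c(10, 5), c(-2, 5), c(10, 14)),
    covs = list(matrix(c(3, 1, 1, 2), 2),
                matrix(c(0.5, 0.1, 0.1, 0.5), 2),
                matrix(c(0.4, -0.1, -0.1, 0.4), 2)),
    exact_counts = counts)
  gen_mixture(spec, n, seed = seed, labels = labels)
}

#' Synthetic light-speed-style sample with gross negative outliers
#'
#' A synthetic stand-in for the historical 66-observation light-speed data:
#' 64 inliers from `N(27.75, 5.08^2)` plus two fixed gross negative
#' outliers at -44 and -2.  It exercises the same code path as the real
#' (external) data without making numeric claims about it.
#'
#' @param seed RNG seed.
#' @return numeric vector of length 66 (shuffled).
#' @export
gen_newcomb_like <- function(seed = NULL) {
  with_seed(seed, {
    x <- c(stats::rnorm(64, 27.75, 5.08), -44, -2)
    x[sample.int(66)]
  })
}

#' Clean parametric sample
#'
#' @param family a [parametric_family()].
#' @param theta parameter vector.
#' @param n sample size (>= 1).
#' @param seed RNG seed.
#' @return i.i.d. sample from `f_theta`.
#' @export
gen_parametric <- function(family, theta, n, seed = NULL) {
  stopifnot(n >= 1)
  theta <- check_theta(family, theta)
  with_seed(seed, family$sampler(theta, n))
}
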
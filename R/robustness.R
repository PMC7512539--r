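#' Gross-error contamination model
#'
#' The mixture \eqn{f_{\theta,\alpha,z} = (1-\alpha) f_\theta + \alpha
#' \delta_z} where \eqn{\delta_z} is the uniform density on
#' \eqn{(z-\epsilon, z+\epsilon)}: a fraction `alpha` of the observations
#' are gross errors located near `z`.
#'
#' @param family a univariate [parametric_family()].
#' @param theta parameter of the uncontaminated component.
#' @param alpha contamination fraction in `[0, 1)`.
#' @param z outlier location.
#' @param eps half-width of the uniform spike (default
#'   `0.01 * scale_at(theta)`).
#' @return object of class `gross_error_model`.
#' @export
gross_error_model <- function(family, theta, alpha, z, eps = NULL) {
  stopifnot(inherits(family, "parametric_family"), family$dim == 1L,
            alpha >= 0, alpha < 1)
  theta <- check_theta(family, theta)
  if (is.null(eps)) eps <- 0.01 * family$scale_at(theta)
  stopifnot(eps > 0)
  structure(list(family = family, theta = theta, alpha = alpha,
                 z = z, eps = eps),
            class = "gross_error_model")
}

#' Density of the gross-error model
#'
#' @param model a [gross_error_model()].
#' @param x evaluation points.
#' @return `(1-alpha) f_theta(x) + alpha * 1(|x-z| < eps) / (2 eps)`.
#' @export
contaminated_pdf <- function(model, x) {
  spike <- as.numeric(abs(x - model$z) < model$eps) / (2 * model$eps)
  (1 - model$alpha) * model$family$pdf(model$theta, x) + model$alpha * spike
}

#' The gross-error model as an evaluable density
#'
#' @param model a [gross_error_model()].
#' @return a [density_fn()] whose breakpoints include the spike edges.
#' @export
contaminated_density_fn <- function(model) {
  density_fn(function(x) contaminated_pdf(model, x), dim = 1L,
             breakpoints = c(model$z - model$eps, model$z + model$eps),
             label = sprintf("gross-error (alpha=%g, z=%g)",
                             model$alpha, model$z))
}

#' Sample from the gross-error model
#'
#' @param model a [gross_error_model()].
#' @param n sample size.
#' @param exact_counts if TRUE (default), exactly `round(alpha * n)` points
#'   come from the spike; otherwise each point is contaminated independently
#'   with probability `alpha`.
#' @param seed RNG seed.
#' @return numeric sample of length `n` (shuffled).
#' @export
sample_contaminated <- function(model, n, exact_counts = TRUE, seed = NULL) {
  stopifnot(n >= 1)
  with_seed(seed, {
    n_out <- if (exact_counts) round(model$alpha * n)
    else stats::rbinom(1, n, model$alpha)
    n_in <- n - n_out
    x <- c(model$family$sampler(model$theta, n_in),
           stats::runif(n_out, model$z - model$eps, model$z + model$eps))
    x[sample.int(n)]
  })
}

#' Robustness curve over outlier locations
#'
#' For each `z` in `z_grid`: draw a fresh contaminated sample (sub-seeded
#' from `seed`), fit the requested estimator, and record the estimate and
#' its absolute error; the maximum-likelihood estimate on the same sample is
#' always included for contrast.  As `z` grows the minimum-Hellinger
#' estimators reject the outliers while the MLE drifts linearly
#' (location slope about `alpha`).
#'
#' @param family a univariate [parametric_family()].
#' @param theta0 true parameter of the clean component.
#' @param alpha contamination fraction.
#' @param z_grid sorted outlier locations.
#' @param estimator `"mhb"`, `"bmh-eap"` or `"mle"`.
#' @param n sample size per `z`.
#' @param seed master seed; each `z` uses a derived sub-seed.
#' @param prior_config list: `k` (bins, default 100), `alpha` (concentration
#'   rule, default total prior mass one: `alpha_j = 1/k`), `padding`,
#'   `n_draws` (BMH draws, default 100), `eps`.
#' @return data.frame with columns `z`, one `est_*` and `abserr_*` per
#'   coordinate, the same for the MLE contrast, `estimator`, `seed`.
#' @export
robustness_curve <- function(family, theta0, alpha, z_grid,
                             estimator = c("mhb", "bmh-eap", "mle"),
                             n = 400, seed = 1, prior_config = list()) {
  estimator <- match.arg(estimator)
  if (is.unsorted(z_grid)) stop("z_grid must be sorted")
  cfg <- utils::modifyList(
    list(k = 100, alpha = function(k) rep(1 / k, k), padding = 0.05,
         n_draws = 100, eps = NULL), prior_config)
  p <- family$param_dim
  rows <- vector("list", length(z_grid))
  for (iz in seq_along(z_grid)) {
    z <- z_grid[iz]
    sub <- derive_seed(seed, iz)
    model <- gross_error_model(family, theta0, alpha, z, eps = cfg$eps)
    x <- sample_contaminated(model, n, exact_counts = TRUE, seed = sub)
    mle_est <- family$mle(x)
    est <- rep(NA_real_, p)
    fit <- tryCatch({
      if (estimator == "mle") mle_est
      else {
        post <- fit_histogram_posterior(x, k_prior_dirac(cfg$k),
                                        alpha = cfg$alpha,
                                        padding = cfg$padding)
        gstar <- expected_posterior_density(post)
        grid <- make_grid(gstar$support, breakpoints = gstar$breakpoints)
        if (estimator == "mhb") {
          mhb(x, family, gstar, grid)$theta_hat
        } else {
          gdraws <- sample_posterior_density(post, cfg$n_draws,
                                             seed = derive_seed(sub, 1))
          bmh(x, family, gdraws, grid)$eap
        }
      }
    }, error = function(e) NULL)
    if (!is.null(fit)) est <- fit
    row <- data.frame(z = z)
    for (j in seq_len(p)) {
      row[[paste0("est_", family$param_names[j])]] <- est[j]
      row[[paste0("abserr_", family$param_names[j])]] <- abs(est[j] - theta0[j])
    }
    for (j in seq_len(p)) {
      row[[paste0("mle_", family$param_names[j])]] <- mle_est[j]
      row[[paste0("mle_abserr_", family$param_names[j])]] <-
        abs(mle_est[j] - theta0[j])
    }
    row$estimator <- estimator
    row$seed <- sub
    rows[[iz]] <- row
  }
  do.call(rbind, rows)
}
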
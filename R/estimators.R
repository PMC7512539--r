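#' MHB: minimum Hellinger distance with a Bayesian nonparametric density
#'
#' The point estimator \eqn{\hat\theta_1 = \arg\min_\theta h(f_\theta,
#' g^*_n)} where \eqn{g^*_n} is a Bayesian nonparametric expected posterior
#' density (histogram posterior mean or DPM density EAP).
#'
#' @param data the observed sample (kept for provenance; the estimator is a
#'   function of the density estimate).
#' @param family a [parametric_family()].
#' @param density_estimate a [density_fn()]: the expected posterior density.
#' @param grid a [make_grid()]; defaults to the estimate's support when
#'   finite, else the data-driven window.
#' @param starts passed to [minimize_hellinger()].
#' @return a [minimize_hellinger()] `tresult` with a `provenance` field.
#' @export
mhb <- function(data, family, density_estimate, grid = NULL, starts = "auto") {
  if (is.null(grid))
    grid <- make_grid(default_window_for(density_estimate, data),
                      breakpoints = density_estimate$breakpoints)
  res <- minimize_hellinger(family, density_estimate, grid, starts = starts)
  res$provenance <- list(estimator = "mhb", n = NROW(data),
                         density = density_estimate$label)
  res
}

#' BMH: the posterior over parameters induced by the Hellinger functional
#'
#' Applies the minimum-Hellinger functional `T` to every draw from the
#' nonparametric posterior over densities, yielding draws from the
#' parameter posterior \eqn{\pi(\theta | X_n) = \pi(T(g) | X_n)}.
#' Successive optimizations are warm-started at the previous draw's optimum
#' (plus one fresh automatic start, to avoid locking onto one mode).
#'
#' @param data observed sample (provenance only).
#' @param family a [parametric_family()].
#' @param density_draws list of [density_fn()] draws from the posterior
#'   over densities ([sample_posterior_density()] or [density_draws()]).
#' @param grid a [make_grid()] shared by all draws.
#' @param warm_start warm-start each optimization at the previous optimum
#'   (default TRUE).
#' @param max_fail_frac runs with more than this fraction of non-converged
#'   draws are flagged invalid (default 0.05).
#' @param mass_tol window-coverage warning threshold per draw (default 0.05:
#'   heavy-tailed base components may leave a little mass outside the
#'   window without affecting the optimum).
#' @param control simplex-search control passed through to
#'   [minimize_hellinger()]; the default relaxes the tolerance slightly,
#'   appropriate for hundreds of warm-started optimizations.
#' @return object of class `theta_posterior`: `draws` (matrix, one row per
#'   converged draw), `eap`, `post_sd`, `n_failed`, `valid`, `provenance`.
#' @export
bmh <- function(data, family, density_draws, grid, warm_start = TRUE,
                max_fail_frac = 0.05, mass_tol = 0.05,
                control = list(reltol = 1e-9, maxit = 2000)) {
  m <- length(density_draws)
  if (m < 1) stop("need at least one density draw")
  if (m < 50)
    warning("only ", m, " density draws; posterior summaries will be noisy")
  draws <- matrix(NA_real_, m, family$param_dim)
  hell <- rep(NA_real_, m)
  prev <- NULL
  for (i in seq_len(m)) {
    g <- density_draws[[i]]
    st <- "auto"
    if (warm_start && !is.null(prev)) {
      auto1 <- tryCatch({
        gv <- eval_density(g, grid$nodes)
        family$auto_starts(gv, grid)[[1]]
      }, error = function(e) NULL)
      st <- c(list(prev), if (!is.null(auto1)) list(auto1))
    }
    res <- tryCatch(
      minimize_hellinger(family, g, grid, starts = st, mass_tol = mass_tol,
                         control = control),
      error = function(e) NULL)
    if (!is.null(res) && res$converged) {
      draws[i, ] <- res$theta_hat
      hell[i] <- res$hellinger
      prev <- res$theta_hat
    }
  }
  ok <- !is.na(draws[, 1])
  n_failed <- sum(!ok)
  if (!any(ok)) stop("no density draw produced a converged optimum")
  dok <- draws[ok, , drop = FALSE]
  colnames(dok) <- family$param_names
  structure(list(
    draws = dok,
    eap = colMeans(dok),
    post_sd = apply(dok, 2, stats::sd),
    hellinger = hell[ok],
    n_failed = n_failed,
    n_draws = m,
    valid = n_failed / m <= max_fail_frac,
    family = family$name,
    param_names = family$param_names,
    provenance = list(estimator = "bmh", n = NROW(data),
                      n_draws = m, warm_start = warm_start)
  ), class = "theta_posterior")
}

#' @export
print.theta_posterior <- function(x, ...) {
  cat("<theta_posterior> family ", x$family, ", ", nrow(x$draws),
      " converged draws (", x$n_failed, " failed",
      if (!x$valid) "; RUN FLAGGED INVALID" else "", ")\n", sep = "")
  out <- rbind(eap = x$eap, post_sd = x$post_sd)
  print(signif(out, 5))
  invisible(x)
}

#' Centered L2(g0) norm
#'
#' \eqn{\|f\|_L = [\int (f - \int f g_0)^2 g_0]^{1/2}}, the norm in which
#' the efficient influence function's squared length equals the optimal
#' asymptotic variance.
#'
#' @param fn function mapping points to a numeric vector (or to an
#'   `n x p` matrix, in which case one norm per column is returned).
#' @param g0 a [density_fn()].
#' @param grid a [make_grid()].
#' @return nonnegative real (or vector of length `p`).
#' @export
l_norm <- function(fn, g0, grid) {
  gv <- eval_density(g0, grid$nodes)
  v <- fn(grid$nodes)
  if (is.null(dim(v))) v <- matrix(v, ncol = 1)
  apply(v, 2, function(col) {
    m <- sum(grid$weights * col * gv)
    sqrt(max(0, sum(grid$weights * (col - m)^2 * gv)))
  })
}

#' Bernstein--von-Mises diagnostic for a BMH posterior
#'
#' Compares the posterior spread of the `theta` draws with the efficient
#' asymptotic scale `sqrt(diag(I(eap)^{-1}) / n)` and tests per-coordinate
#' normality of the draws (one-sample Kolmogorov--Smirnov against
#' `N(eap, post_sd^2)`).  The posterior is centered at the EAP, the
#' observable stand-in for the theoretical centering sequence.
#'
#' @param post a [bmh()] result.
#' @param family the [parametric_family()] used.
#' @param n sample size behind the posterior.
#' @param sd_band acceptable band for `post_sd / asymptotic sd`
#'   (default `c(0.7, 1.4)`).
#' @param p_floor minimum acceptable normality p-value (default 0.01).
#' @return object of class `bvm_report` with `theta_ref`, `asympt_sd`,
#'   `sd_ratio`, `normality` (statistic + p per coordinate), per-coordinate
#'   and overall `verdict`.
#' @export
bvm_diagnostic <- function(post, family, n, sd_band = c(0.7, 1.4),
                           p_floor = 0.01) {
  stopifnot(inherits(post, "theta_posterior"), n >= 2)
  theta_ref <- post$eap
  I <- tryCatch(fisher_information(family, theta_ref), error = function(e) e)
  if (inherits(I, "error")) {
    return(structure(list(theta_ref = theta_ref, asympt_sd = NULL,
                          sd_ratio = NULL, normality = NULL,
                          verdict = "indeterminate",
                          reason = conditionMessage(I)),
                     class = "bvm_report"))
  }
  asympt_sd <- sqrt(diag(solve(I)) / n)
  sd_ratio <- post$post_sd / asympt_sd
  normality <- lapply(seq_len(ncol(post$draws)), function(j) {
    ks <- suppressWarnings(
      stats::ks.test(post$draws[, j], "pnorm",
                     mean = theta_ref[j], sd = post$post_sd[j]))
    list(statistic = unname(ks$statistic), p_value = ks$p.value)
  })
  names(normality) <- family$param_names
  pvals <- vapply(normality, `[[`, numeric(1), "p_value")
  coord_pass <- sd_ratio >= sd_band[1] & sd_ratio <= sd_band[2] &
    pvals >= p_floor
  structure(list(theta_ref = theta_ref, asympt_sd = asympt_sd,
                 sd_ratio = sd_ratio, normality = normality,
                 coord_pass = coord_pass,
                 verdict = if (all(coord_pass)) "pass" else "fail",
                 sd_band = sd_band, p_floor = p_floor, n = n),
            class = "bvm_report")
}

#' @export
print.bvm_report <- function(x, ...) {
  cat("<bvm_report> verdict:", x$verdict, "\n")
  if (!is.null(x$sd_ratio)) {
    out <- rbind(theta_ref = x$theta_ref, asympt_sd = x$asympt_sd,
                 sd_ratio = x$sd_ratio,
                 ks_p = vapply(x$normality, `[[`, numeric(1), "p_value"))
    print(signif(out, 4))
  } else cat("  reason:", x$reason, "\n")
  invisible(x)
}

#' Nonparametric bootstrap standard errors for MHB
#'
#' Resamples the data with replacement, refits the nonparametric density
#' (histogram posterior) and re-applies the Hellinger functional.
#'
#' @param data numeric sample.
#' @param family a [parametric_family()].
#' @param fit_density function `sample -> density_fn` (e.g. histogram
#'   posterior mean with the caller's settings).
#' @param B number of bootstrap replicates (default 200).
#' @param seed RNG seed.
#' @return list with `se` (per-coordinate standard errors) and `estimates`
#'   (B x p matrix).
#' @export
mhb_bootstrap <- function(data, family, fit_density, B = 200, seed = NULL) {
  with_seed(seed, {
    est <- matrix(NA_real_, B, family$param_dim)
    for (b in seq_len(B)) {
      xb <- sample(data, length(data), replace = TRUE)
      g <- fit_density(xb)
      r <- tryCatch(mhb(xb, family, g), error = function(e) NULL)
      if (!is.null(r)) est[b, ] <- r$theta_hat
    }
    ok <- stats::complete.cases(est)
    list(se = apply(est[ok, , drop = FALSE], 2, stats::sd),
         estimates = est[ok, , drop = FALSE])
  })
}
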
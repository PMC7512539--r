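#' Hyperparameters for the Dirichlet-process mixture of normals
#'
#' The model is
#' \deqn{y_i | \mu_i, \Sigma_i \sim N(\mu_i, \Sigma_i), \quad
#'   (\mu_i, \Sigma_i) | G \sim G, \quad G \sim DP(\alpha G_0)}
#' with conjugate normal--inverse-Wishart base
#' \eqn{G_0 = N(\mu | m_1, \Sigma/k_0)\, IW(\Sigma | \nu_1, \psi_1)} and
#' independent hyperpriors \eqn{m_1 \sim N(m_2, s_2)},
#' \eqn{k_0 \sim Gamma(\tau_1/2, \tau_2/2)} and a conjugate prior on
#' \eqn{\psi_1} with parameters \eqn{(\nu_2, \psi_2)}.  In one dimension the
#' inverse Wishart reduces to an inverse gamma.  The DP concentration
#' `alpha` is fixed by default (the demonstration uses `alpha = 1`); supply
#' `a0, b0` and set `update_alpha = TRUE` for the usual Gamma hyperprior
#' with the auxiliary-variable update.
#'
#' @param dim sample dimension (1 or 2).
#' @param alpha DP concentration (fixed unless `update_alpha`).
#' @param a0,b0 Gamma hyperprior for `alpha` (used when `update_alpha`).
#' @param m2,s2 normal hyperprior for the base mean `m1`.
#' @param tau1,tau2 `k0 ~ Gamma(tau1/2, tau2/2)` (shape, rate).
#' @param nu1 base inverse-Wishart degrees of freedom (default `dim + 2`,
#'   the smallest weakly-informative choice with a finite prior mean).
#' @param nu2,psi2 parameters of the conjugate hyperprior on `psi1`.
#' @param psi1 optional fixed / initial value for `psi1` (e.g. the
#'   empirical covariance of the data); default: updated from `(nu2, psi2)`.
#' @param update_m1,update_k0,update_psi1,update_alpha which hyperparameters
#'   are resampled.
#' @return object of class `dpm_hyper`.
#' @export
dpm_hyper <- function(dim = 1L, alpha = 1, a0 = NULL, b0 = NULL,
                      m2 = rep(0, dim), s2 = diag(1000, dim),
                      tau1 = 1, tau2 = 100,
                      nu1 = dim + 2, nu2 = 2, psi2 = diag(1, dim),
                      psi1 = NULL,
                      update_m1 = TRUE, update_k0 = TRUE,
                      update_psi1 = is.null(psi1), update_alpha = FALSE) {
  dim <- as.integer(dim)
  stopifnot(dim %in% c(1L, 2L), alpha > 0, tau1 > 0, tau2 > 0,
            nu1 > dim - 1, nu2 > dim - 1)
  m2 <- as.numeric(m2); stopifnot(length(m2) == dim)
  s2 <- as.matrix(s2); psi2 <- as.matrix(psi2)
  stopifnot(is_square_pd(s2), is_square_pd(psi2))
  if (!is.null(psi1)) {
    psi1 <- as.matrix(psi1)
    stopifnot(is_square_pd(psi1))
  }
  if (update_alpha && (is.null(a0) || is.null(b0)))
    stop("update_alpha = TRUE requires a0 and b0")
  structure(list(dim = dim, alpha = alpha, a0 = a0, b0 = b0,
                 m2 = m2, s2 = s2, tau1 = tau1, tau2 = tau2,
                 nu1 = nu1, nu2 = nu2, psi2 = psi2, psi1 = psi1,
                 update_m1 = update_m1, update_k0 = update_k0,
                 update_psi1 = update_psi1, update_alpha = update_alpha),
            class = "dpm_hyper")
}

# log predictive density of single points under the NIW posterior with
# "prior" (m1, k0v, nu, psi entries) and per-cluster sufficient statistics;
# all arguments vectorized over clusters.  d = 1.
logpred1 <- function(x, nvec, s1, s2q, k0, m1, nu1, psi) {
  kn <- k0 + nvec
  mn <- (k0 * m1 + s1) / kn
  vn <- nu1 + nvec
  within <- s2q - ifelse(nvec > 0, s1^2 / nvec, 0)
  yb <- ifelse(nvec > 0, s1 / nvec, 0)
  pn <- psi + within + (k0 * nvec / kn) * (yb - m1)^2
  df <- vn
  sc2 <- pn * (kn + 1) / (kn * df)
  lgamma((df + 1) / 2) - lgamma(df / 2) - 0.5 * log(df * pi * sc2) -
    ((df + 1) / 2) * log1p((x - mn)^2 / (df * sc2))
}

# d = 2 version; psi is c(p11, p12, p22) for the prior scale.
logpred2 <- function(x1, x2, nvec, s1, s2, s11, s12, s22,
                     k0, m1, nu1, psi11, psi12, psi22) {
  kn <- k0 + nvec
  mn1 <- (k0 * m1[1] + s1) / kn
  mn2 <- (k0 * m1[2] + s2) / kn
  vn <- nu1 + nvec
  pos <- nvec > 0
  yb1 <- ifelse(pos, s1 / nvec, 0); yb2 <- ifelse(pos, s2 / nvec, 0)
  w11 <- s11 - ifelse(pos, s1^2 / nvec, 0)
  w12 <- s12 - ifelse(pos, s1 * s2 / nvec, 0)
  w22 <- s22 - ifelse(pos, s2^2 / nvec, 0)
  cf <- k0 * nvec / kn
  d1 <- yb1 - m1[1]; d2 <- yb2 - m1[2]
  p11 <- psi11 + w11 + cf * d1 * d1
  p12 <- psi12 + w12 + cf * d1 * d2
  p22 <- psi22 + w22 + cf * d2 * d2
  df <- vn - 1
  fac <- (kn + 1) / (kn * df)
  detp <- pmax(p11 * p22 - p12^2, .Machine$double.xmin)
  dx <- x1 - mn1; dy <- x2 - mn2
  q <- (p22 * dx^2 - 2 * p12 * dx * dy + p11 * dy^2) / (detp * fac)
  lgamma((df + 2) / 2) - lgamma(df / 2) - log(df * pi) -
    0.5 * (log(detp) + 2 * log(fac)) - ((df + 2) / 2) * log1p(q / df)
}

# NIW posterior draw of (mu, Sigma) for one cluster given its members.
draw_cluster_params <- function(y, m1, k0, nu1, psi1, d) {
  nc <- nrow(y)
  yb <- colMeans(y)
  S <- if (nc > 1) crossprod(sweep(y, 2, yb)) else matrix(0, d, d)
  kn <- k0 + nc
  mn <- (k0 * m1 + nc * yb) / kn
  vn <- nu1 + nc
  pn <- psi1 + S + (k0 * nc / kn) * tcrossprod(yb - m1)
  if (!is_square_pd(pn)) {
    warning("non-positive-definite scatter in cluster update; jittering")
    pn <- pn + diag(1e-8, d)
  }
  Sig <- solve(stats::rWishart(1, vn, solve(pn))[, , 1])
  Sig <- (Sig + t(Sig)) / 2
  mu <- mn + drop(stats::rnorm(d) %*% chol(Sig / kn))
  list(mu = mu, Sigma = Sig)
}

#' Collapsed Gibbs sampler for the DP mixture of normals
#'
#' Cluster assignments are updated by the collapsed (marginal) conjugate
#' scheme: the cluster parameters are integrated out and each observation is
#' reassigned from its multivariate-t predictive probabilities.  After each
#' sweep, explicit `(mu_c, Sigma_c)` are drawn from their
#' normal--inverse-Wishart full conditionals, and the base-measure
#' hyperparameters `m1`, `k0`, `psi1` (and optionally the concentration
#' `alpha`, by the auxiliary-variable scheme) are refreshed from their
#' conjugate full conditionals.
#'
#' @param data numeric vector (1-D) or `n x 2` matrix.
#' @param hyper a [dpm_hyper()]; default is built from the data dimension.
#' @param n_iter total sweeps (default 6000).
#' @param burnin discarded sweeps (default 1000).
#' @param thin keep every `thin`-th state after burn-in (default 10).
#' @param seed RNG seed.
#' @return object of class `dpm_chain`: `states` (each with `assignments`,
#'   `cluster_params`, `alpha_dp`, `m1`, `k0`, `psi1`, `iteration`), plus
#'   `hyper`, `n`, `dim`.
#' @export
dpm_gibbs <- function(data, hyper = NULL, n_iter = 6000, burnin = 1000,
                      thin = 10, seed = NULL) {
  y <- if (is.matrix(data)) data else matrix(as.numeric(data), ncol = 1)
  n <- nrow(y); d <- ncol(y)
  stopifnot(d %in% c(1L, 2L))
  if (n < 2) stop("need at least two observations")
  if (n_iter <= burnin) stop("n_iter must exceed burnin")
  if (is.null(hyper)) hyper <- dpm_hyper(dim = d)
  stopifnot(inherits(hyper, "dpm_hyper"), hyper$dim == d)
  with_seed(seed, dpm_gibbs_run(y, hyper, n_iter, burnin, thin))
}

dpm_gibbs_run <- function(y, hyper, n_iter, burnin, thin) {
  n <- nrow(y); d <- ncol(y)
  x1 <- y[, 1]; x2 <- if (d == 2) y[, 2] else NULL
  # current hyper state
  m1 <- colMeans(y)
  k0 <- hyper$tau1 / hyper$tau2              # prior mean of Gamma(tau1/2, tau2/2)
  psi1 <- if (!is.null(hyper$psi1)) hyper$psi1 else {
    v <- stats::cov(y)
    if (!is_square_pd(v)) v <- v + diag(1e-6, d)
    v
  }
  alpha <- hyper$alpha
  s2inv <- solve(hyper$s2)
  psi2inv <- solve(hyper$psi2)
  # single initial cluster
  z <- rep(1L, n)
  C <- 1L
  nvec <- n
  cs1 <- sum(x1); css11 <- sum(x1^2)
  if (d == 2) {
    cs2 <- sum(x2); css12 <- sum(x1 * x2); css22 <- sum(x2^2)
  }
  states <- vector("list", floor((n_iter - burnin) / thin))
  si <- 0L
  for (iter in seq_len(n_iter)) {
    # prior-predictive (empty-cluster) log density for every observation,
    # fixed within a sweep because the hyper state is fixed
    if (d == 1) {
      logt0 <- logpred1(x1, 0, 0, 0, k0, m1, hyper$nu1, psi1[1, 1])
    } else {
      logt0 <- logpred2(x1, x2, 0, 0, 0, 0, 0, 0, k0, m1, hyper$nu1,
                        psi1[1, 1], psi1[1, 2], psi1[2, 2])
    }
    for (i in seq_len(n)) {
      ci <- z[i]
      # remove observation i from its cluster
      nvec[ci] <- nvec[ci] - 1
      cs1[ci] <- cs1[ci] - x1[i]; css11[ci] <- css11[ci] - x1[i]^2
      if (d == 2) {
        cs2[ci] <- cs2[ci] - x2[i]
        css12[ci] <- css12[ci] - x1[i] * x2[i]
        css22[ci] <- css22[ci] - x2[i]^2
      }
      if (nvec[ci] == 0) {  # drop empty cluster, move last into its slot
        if (ci != C) {
          z[z == C] <- ci
          nvec[ci] <- nvec[C]; cs1[ci] <- cs1[C]; css11[ci] <- css11[C]
          if (d == 2) {
            cs2[ci] <- cs2[C]; css12[ci] <- css12[C]; css22[ci] <- css22[C]
          }
        }
        nvec <- nvec[-C]; cs1 <- cs1[-C]; css11 <- css11[-C]
        if (d == 2) { cs2 <- cs2[-C]; css12 <- css12[-C]; css22 <- css22[-C] }
        C <- C - 1L
      }
      lw <- if (d == 1) {
        logpred1(x1[i], nvec, cs1, css11, k0, m1, hyper$nu1, psi1[1, 1])
      } else {
        logpred2(x1[i], x2[i], nvec, cs1, cs2, css11, css12, css22,
                 k0, m1, hyper$nu1, psi1[1, 1], psi1[1, 2], psi1[2, 2])
      }
      lw <- c(log(nvec) + lw, log(alpha) + logt0[i])
      p <- exp(lw - max(lw))
      pick <- sample.int(C + 1L, 1L, prob = p)
      if (pick == C + 1L) {
        C <- C + 1L
        nvec <- c(nvec, 0); cs1 <- c(cs1, 0); css11 <- c(css11, 0)
        if (d == 2) { cs2 <- c(cs2, 0); css12 <- c(css12, 0); css22 <- c(css22, 0) }
      }
      z[i] <- pick
      nvec[pick] <- nvec[pick] + 1
      cs1[pick] <- cs1[pick] + x1[i]; css11[pick] <- css11[pick] + x1[i]^2
      if (d == 2) {
        cs2[pick] <- cs2[pick] + x2[i]
        css12[pick] <- css12[pick] + x1[i] * x2[i]
        css22[pick] <- css22[pick] + x2[i]^2
      }
    }
    # explicit cluster parameters from the NIW full conditionals
    params <- lapply(seq_len(C), function(cc)
      draw_cluster_params(y[z == cc, , drop = FALSE], m1, k0, hyper$nu1,
                          psi1, d))
    mus <- do.call(rbind, lapply(params, `[[`, "mu"))
    sig_inv <- lapply(params, function(p) solve(p$Sigma))
    # m1 | rest
    if (hyper$update_m1) {
      P <- s2inv
      b <- s2inv %*% hyper$m2
      for (cc in seq_len(C)) {
        P <- P + k0 * sig_inv[[cc]]
        b <- b + k0 * sig_inv[[cc]] %*% mus[cc, ]
      }
      V <- solve(P)
      m1 <- drop(V %*% b) + drop(stats::rnorm(d) %*% chol((V + t(V)) / 2))
    }
    # k0 | rest
    if (hyper$update_k0) {
      quad <- sum(vapply(seq_len(C), function(cc) {
        dd <- mus[cc, ] - m1
        drop(t(dd) %*% sig_inv[[cc]] %*% dd)
      }, numeric(1)))
      k0 <- stats::rgamma(1, shape = (hyper$tau1 + C * d) / 2,
                          rate = (hyper$tau2 + quad) / 2)
      k0 <- max(k0, 1e-8)
    }
    # psi1 | rest (conjugate Wishart full conditional)
    if (hyper$update_psi1) {
      Ssum <- psi2inv
      for (cc in seq_len(C)) Ssum <- Ssum + sig_inv[[cc]]
      psi1 <- stats::rWishart(1, hyper$nu2 + C * hyper$nu1,
                              solve(Ssum))[, , 1, drop = TRUE]
      psi1 <- matrix(psi1, d, d)
      psi1 <- (psi1 + t(psi1)) / 2
    }
    # alpha | rest (auxiliary-variable scheme)
    if (hyper$update_alpha) {
      eta <- stats::rbeta(1, alpha + 1, n)
      odds <- (hyper$a0 + C - 1) / (n * (hyper$b0 - log(eta)))
      shp <- hyper$a0 + C - if (stats::runif(1) < odds / (1 + odds)) 0 else 1
      alpha <- stats::rgamma(1, shape = shp, rate = hyper$b0 - log(eta))
      alpha <- max(alpha, 1e-8)
    }
    if (iter > burnin && (iter - burnin) %% thin == 0) {
      si <- si + 1L
      states[[si]] <- list(assignments = z, cluster_params = params,
                           alpha_dp = alpha, m1 = m1, k0 = k0, psi1 = psi1,
                           iteration = iter)
    }
  }
  structure(list(states = states[seq_len(si)], hyper = hyper, n = n,
                 dim = d), class = "dpm_chain")
}

#' @export
print.dpm_chain <- function(x, ...) {
  occ <- vapply(x$states, function(s) length(s$cluster_params), numeric(1))
  cat("<dpm_chain> ", length(x$states), " retained states, n = ", x$n,
      ", dim = ", x$dim, "\n  occupied clusters: median ",
      stats::median(occ), " (range ", min(occ), "-", max(occ), ")\n",
      sep = "")
  invisible(x)
}

#' Density associated with one posterior state
#'
#' The conditional mixture
#' \eqn{\sum_c \frac{n_c}{n+\alpha} N(\cdot | \mu_c, \Sigma_c) +
#'   \frac{\alpha}{n+\alpha} p_0(\cdot)},
#' where \eqn{p_0} is the heavy-tailed multivariate-t predictive induced by
#' the normal--inverse-Wishart base at the state's hyperparameters.  This is
#' the finite, evaluable surrogate for a draw from the posterior over
#' densities, used as input to the Hellinger functional.
#'
#' @param state one element of `dpm_chain$states`.
#' @param hyper the [dpm_hyper()] used for the chain.
#' @param n number of observations (taken from the chain when using
#'   [density_draws()]).
#' @return a [density_fn()].
#' @export
density_draw <- function(state, hyper, n) {
  d <- hyper$dim
  nc <- tabulate(state$assignments, nbins = length(state$cluster_params))
  a <- state$alpha_dp
  tot <- n + a
  comps <- lapply(seq_along(state$cluster_params), function(cc) {
    p <- state$cluster_params[[cc]]
    list(w = nc[cc] / tot,
         mu = p$mu,
         Sigma = if (d == 1) p$Sigma[1, 1] else p$Sigma)
  })
  df0 <- hyper$nu1 - d + 1
  sc0 <- state$psi1 * (state$k0 + 1) / (state$k0 * df0)
  comps[[length(comps) + 1]] <- list(
    w = a / tot, mu = state$m1,
    Sigma = if (d == 1) sc0[1, 1] else sc0, df = df0)
  mixture_density_fn(comps, dim = d, label = "DPM posterior state")
}

#' All density draws of a chain
#'
#' @param chain a [dpm_gibbs()] result.
#' @return list of [density_fn()] objects, one per retained state.
#' @export
density_draws <- function(chain) {
  stopifnot(inherits(chain, "dpm_chain"))
  lapply(chain$states, density_draw, hyper = chain$hyper, n = chain$n)
}

#' Expected a posteriori density of a DPM chain
#'
#' The pointwise average of the per-state conditional mixture densities
#' across retained states: the nonparametric density EAP used by the MHB
#' estimator when the DP mixture replaces the histogram prior.
#'
#' @param chain a [dpm_gibbs()] result.
#' @return a [density_fn()].
#' @export
eap_density <- function(chain) {
  stopifnot(inherits(chain, "dpm_chain"))
  if (!length(chain$states)) stop("empty chain")
  draws <- density_draws(chain)
  m <- length(draws)
  pdf <- function(x) {
    v <- 0
    for (g in draws) v <- v + g$pdf(x)
    v / m
  }
  density_fn(pdf, dim = chain$dim, label = "DPM posterior mean density")
}
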
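#' Parametric families for minimum Hellinger distance estimation
#'
#' A `parametric_family` packages everything the Hellinger functional needs
#' about a family \eqn{\{f_\theta\}}: the density, open per-coordinate
#' parameter bounds, square-root-density derivatives (analytic where known,
#' central finite differences otherwise), Fisher information, a sampler, a
#' maximum-likelihood map used for optimizer starts and benchmarking, and an
#' unconstrained internal parametrization used by the optimizer (log standard
#' deviation in 1-D; Cholesky coordinates of the covariance in 2-D, which
#' keeps iterates positive definite).
#'
#' @param name identifier, e.g. `"normal1d"`.
#' @param param_dim number of parameters.
#' @param param_names character vector of parameter names.
#' @param dim dimension of the sample space.
#' @param pdf function `(theta, x) -> density values`.
#' @param param_bounds `param_dim x 2` matrix of open bounds.
#' @param mle function `sample -> theta`.
#' @param sampler function `(theta, n) -> sample`.
#' @param ... optional components: `logf_grad`, `logf_hess` (analytic score
#'   and Hessian of `log f` in `theta`), `fisher` (analytic information),
#'   `to_internal`/`from_internal` (unconstrained reparametrization),
#'   `scale_at` (typical scale of the family at `theta`),
#'   `default_window` (function `theta -> window`), `auto_starts`
#'   (function `(g, grid) -> list of theta`).
#' @return An object of class `parametric_family`.
#' @export
parametric_family <- function(name, param_dim, param_names, dim, pdf,
                              param_bounds, mle, sampler, ...) {
  extras <- list(...)
  param_bounds <- matrix(as.numeric(param_bounds), ncol = 2)
  stopifnot(nrow(param_bounds) == param_dim,
            all(param_bounds[, 1] < param_bounds[, 2]))
  fam <- c(list(name = name, param_dim = as.integer(param_dim),
                param_names = param_names, dim = as.integer(dim),
                pdf = pdf, param_bounds = param_bounds,
                mle = mle, sampler = sampler),
           extras)
  if (is.null(fam$to_internal)) {
    fam$to_internal <- identity
    fam$from_internal <- identity
  }
  if (is.null(fam$scale_at)) fam$scale_at <- function(theta) 1
  structure(fam, class = "parametric_family")
}

#' @export
print.parametric_family <- function(x, ...) {
  cat("<parametric_family> ", x$name, ": ", x$param_dim, " parameters (",
      paste(x$param_names, collapse = ", "), "), sample dim ", x$dim, "\n",
      sep = "")
  invisible(x)
}

check_theta <- function(family, theta, interior = FALSE) {
  theta <- as.numeric(theta)
  if (length(theta) != family$param_dim)
    stop("theta must have length ", family$param_dim)
  b <- family$param_bounds
  for (i in seq_along(theta)) {
    # bounds are open: boundary values are rejected (derivatives and the
    # optimizer are undefined there)
    if (!(theta[i] > b[i, 1] && theta[i] < b[i, 2]))
      stop("parameter '", family$param_names[i], "' = ", theta[i],
           " is outside its open bounds (", b[i, 1], ", ", b[i, 2], ")")
  }
  theta
}

#' Univariate normal family (mean, standard deviation)
#'
#' Parameters `theta = (mu, sigma)` with `sigma` the standard deviation.
#' Square-root-density derivatives and Fisher information are analytic.
#'
#' @return a [parametric_family()].
#' @export
family_normal1d <- function() {
  parametric_family(
    name = "normal1d", param_dim = 2L, param_names = c("mu", "sigma"),
    dim = 1L,
    pdf = function(theta, x) stats::dnorm(x, theta[1], theta[2]),
    param_bounds = rbind(c(-Inf, Inf), c(0, Inf)),
    mle = function(x) {
      n <- length(x)
      c(mean(x), sqrt(stats::var(x) * (n - 1) / n))
    },
    sampler = function(theta, n) stats::rnorm(n, theta[1], theta[2]),
    logf_grad = function(theta, x) {
      mu <- theta[1]; s <- theta[2]
      cbind((x - mu) / s^2, (x - mu)^2 / s^3 - 1 / s)
    },
    logf_hess = function(theta, x) {
      mu <- theta[1]; s <- theta[2]
      n <- length(x)
      H <- array(0, c(n, 2, 2))
      H[, 1, 1] <- -1 / s^2
      H[, 1, 2] <- H[, 2, 1] <- -2 * (x - mu) / s^3
      H[, 2, 2] <- -3 * (x - mu)^2 / s^4 + 1 / s^2
      H
    },
    fisher = function(theta) diag(c(1 / theta[2]^2, 2 / theta[2]^2)),
    to_internal = function(theta) c(theta[1], log(theta[2])),
    from_internal = function(p) c(p[1], exp(p[2])),
    scale_at = function(theta) theta[2],
    default_window = function(theta) theta[1] + c(-10, 10) * theta[2],
    auto_starts = function(gv, grid) {
      # moment-matched, robust (median/IQR), and a dispersed start
      w <- grid$weights * gv
      m <- sum(w * grid$nodes) / sum(w)
      v <- sum(w * (grid$nodes - m)^2) / sum(w)
      ord <- order(grid$nodes)
      cw <- cumsum(w[ord]) / sum(w)
      qf <- function(p) grid$nodes[ord][which.max(cw >= p)]
      med <- qf(0.5); iqr <- qf(0.75) - qf(0.25)
      list(c(m, sqrt(max(v, 1e-12))),
           c(med, max(iqr / 1.349, 1e-6)),
           c(med, sqrt(max(v, 1e-12)) * 2))
    }
  )
}

#' Bivariate normal family
#'
#' Parameters `theta = (mu1, mu2, Sigma11, Sigma12, Sigma22)`.  The optimizer
#' works in Cholesky coordinates of `Sigma` so iterates stay positive
#' definite.  Square-root-density derivatives use central finite differences;
#' Fisher information is analytic (`Sigma^{-1}` for the mean block and
#' `I_{ab} = tr(Sigma^{-1} D_a Sigma^{-1} D_b)/2` for the covariance block).
#'
#' @return a [parametric_family()].
#' @export
family_normal2d <- function() {
  sigma_of <- function(theta) {
    matrix(c(theta[3], theta[4], theta[4], theta[5]), 2, 2)
  }
  cov_basis <- list(matrix(c(1, 0, 0, 0), 2), matrix(c(0, 1, 1, 0), 2),
                    matrix(c(0, 0, 0, 1), 2))
  parametric_family(
    name = "normal2d", param_dim = 5L,
    param_names = c("mu1", "mu2", "Sigma11", "Sigma12", "Sigma22"),
    dim = 2L,
    pdf = function(theta, x) {
      S <- sigma_of(theta)
      if (S[1, 1] * S[2, 2] - S[1, 2]^2 <= 0) return(rep(0, nrow(x)))
      dmvnorm2(x, theta[1:2], S)
    },
    param_bounds = rbind(c(-Inf, Inf), c(-Inf, Inf),
                         c(0, Inf), c(-Inf, Inf), c(0, Inf)),
    mle = function(x) {
      n <- nrow(x)
      S <- stats::cov(x) * (n - 1) / n
      c(colMeans(x), S[1, 1], S[1, 2], S[2, 2])
    },
    sampler = function(theta, n) {
      L <- chol(sigma_of(theta))
      z <- matrix(stats::rnorm(2 * n), n, 2) %*% L
      sweep(z, 2, theta[1:2], `+`)
    },
    fisher = function(theta) {
      S <- sigma_of(theta)
      P <- solve(S)
      I <- matrix(0, 5, 5)
      I[1:2, 1:2] <- P
      for (a in 1:3) for (b in 1:3)
        I[2 + a, 2 + b] <- 0.5 * sum(diag(P %*% cov_basis[[a]] %*%
                                            P %*% cov_basis[[b]]))
      I
    },
    to_internal = function(theta) {
      L <- t(chol(sigma_of(theta)))  # lower triangular
      c(theta[1:2], log(L[1, 1]), L[2, 1], log(L[2, 2]))
    },
    from_internal = function(p) {
      l11 <- exp(p[3]); l21 <- p[4]; l22 <- exp(p[5])
      c(p[1], p[2], l11^2, l11 * l21, l21^2 + l22^2)
    },
    scale_at = function(theta) sqrt(max(theta[3], theta[5])),
    default_window = function(theta) {
      rbind(theta[1] + c(-10, 10) * sqrt(theta[3]),
            theta[2] + c(-10, 10) * sqrt(theta[5]))
    },
    auto_starts = function(gv, grid) {
      w <- grid$weights * gv
      w <- w / sum(w)
      m <- colSums(w * grid$nodes)
      cx <- sweep(grid$nodes, 2, m)
      S <- t(cx) %*% (w * cx)
      S <- S + diag(1e-8, 2)
      list(c(m, S[1, 1], S[1, 2], S[2, 2]),
           c(m, S[1, 1], 0, S[2, 2]))
    }
  )
}

#' Look up a built-in family by name
#'
#' @param name `"normal1d"` or `"normal2d"`.
#' @return a [parametric_family()].
#' @export
get_family <- function(name) {
  switch(name,
         normal1d = family_normal1d(),
         normal2d = family_normal2d(),
         stop("unknown family '", name, "'"))
}

#' Square root of the family density
#'
#' @param family a [parametric_family()].
#' @param theta parameter vector inside the family's open bounds.
#' @param x points.
#' @return `sqrt(f_theta(x))`, zero off the support.
#' @export
sqrt_density <- function(family, theta, x) {
  theta <- check_theta(family, theta)
  x <- as_point_matrix(x, family$dim)
  sqrt(pmax(family$pdf(theta, x), 0))
}

#' Derivatives of the square-root density in the parameter
#'
#' Returns the bundle \eqn{(s, \dot s, \ddot s)} with
#' \eqn{s_\theta(x) = f_\theta(x)^{1/2}}.  Where the family carries an
#' analytic score and Hessian of `log f` the derivatives are assembled from
#' \eqn{\dot s_i = \tfrac12 \ell_i s} and
#' \eqn{\ddot s_{ij} = (\tfrac12 \ell_{ij} + \tfrac14 \ell_i \ell_j) s};
#' otherwise central finite differences with per-coordinate step
#' `h_i = h_rel * (1 + |theta_i|)` are used.
#'
#' @param family a [parametric_family()].
#' @param theta parameter vector strictly inside the bounds.
#' @param h_rel relative finite-difference step (default `1e-5`).
#' @param mode `"auto"`, `"analytic"` or `"fd"`.
#' @return list with functions `s(x)`, `sdot(x)` (`n x p` matrix),
#'   `sddot(x)` (`n x p x p` array) and the `mode` used.
#' @export
sqrt_density_derivatives <- function(family, theta, h_rel = 1e-5,
                                     mode = c("auto", "analytic", "fd")) {
  mode <- match.arg(mode)
  theta <- check_theta(family, theta, interior = TRUE)
  p <- family$param_dim
  s_fun <- function(x) sqrt_density(family, theta, x)
  analytic_ok <- !is.null(family$logf_grad) && !is.null(family$logf_hess)
  if (mode == "analytic" && !analytic_ok)
    stop("family '", family$name, "' has no analytic derivatives")
  use_analytic <- analytic_ok && mode != "fd"
  if (use_analytic) {
    sdot <- function(x) {
      s <- s_fun(x)
      g <- family$logf_grad(theta, x)
      0.5 * g * s
    }
    sddot <- function(x) {
      s <- s_fun(x)
      g <- family$logf_grad(theta, x)
      H <- family$logf_hess(theta, x)
      out <- array(0, c(length(s), p, p))
      for (i in seq_len(p)) for (j in seq_len(p))
        out[, i, j] <- (0.5 * H[, i, j] + 0.25 * g[, i] * g[, j]) * s
      out
    }
    return(list(s = s_fun, sdot = sdot, sddot = sddot, mode = "analytic",
                theta = theta))
  }
  h <- h_rel * (1 + abs(theta))
  shift <- function(i, d) {
    th <- theta; th[i] <- th[i] + d
    th
  }
  s_at <- function(th, x) sqrt(pmax(family$pdf(th, x), 0))
  sdot <- function(x) {
    x <- as_point_matrix(x, family$dim)
    vapply(seq_len(p), function(i)
      (s_at(shift(i, h[i]), x) - s_at(shift(i, -h[i]), x)) / (2 * h[i]),
      numeric(if (family$dim == 1L) length(x) else nrow(x)))
  }
  sddot <- function(x) {
    x <- as_point_matrix(x, family$dim)
    n <- if (family$dim == 1L) length(x) else nrow(x)
    out <- array(0, c(n, p, p))
    s0 <- s_at(theta, x)
    for (i in seq_len(p)) {
      out[, i, i] <- (s_at(shift(i, h[i]), x) - 2 * s0 +
                        s_at(shift(i, -h[i]), x)) / h[i]^2
      for (j in seq_len(p)) if (j > i) {
        thpp <- theta; thpp[c(i, j)] <- thpp[c(i, j)] + c(h[i], h[j])
        thpm <- theta; thpm[c(i, j)] <- thpm[c(i, j)] + c(h[i], -h[j])
        thmp <- theta; thmp[c(i, j)] <- thmp[c(i, j)] + c(-h[i], h[j])
        thmm <- theta; thmm[c(i, j)] <- thmm[c(i, j)] - c(h[i], h[j])
        v <- (s_at(thpp, x) - s_at(thpm, x) - s_at(thmp, x) + s_at(thmm, x)) /
          (4 * h[i] * h[j])
        out[, i, j] <- out[, j, i] <- v
      }
    }
    out
  }
  list(s = s_fun, sdot = sdot, sddot = sddot, mode = "fd", theta = theta)
}

#' Fisher information matrix
#'
#' Analytic where the family provides it, otherwise computed as
#' \eqn{4\int \dot s_\theta \dot s_\theta^\top dx} by quadrature.
#'
#' @param family a [parametric_family()].
#' @param theta parameter vector strictly inside the bounds.
#' @param grid optional [make_grid()]; defaults to the family's own window.
#' @param force_quadrature compute by quadrature even when an analytic form
#'   exists (used for cross-checks).
#' @return symmetric positive-definite `p x p` matrix.
#' @export
fisher_information <- function(family, theta, grid = NULL,
                               force_quadrature = FALSE) {
  theta <- check_theta(family, theta, interior = TRUE)
  if (!is.null(family$fisher) && !force_quadrature) {
    I <- family$fisher(theta)
  } else {
    if (is.null(grid)) {
      w <- family$default_window(theta)
      grid <- make_grid(w, order = 12)
    }
    bun <- sqrt_density_derivatives(family, theta)
    sd <- bun$sdot(grid$nodes)
    p <- family$param_dim
    I <- matrix(0, p, p)
    for (i in seq_len(p)) for (j in i:p) {
      I[i, j] <- I[j, i] <- 4 * sum(grid$weights * sd[, i] * sd[, j])
    }
  }
  ev <- eigen(I, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10 * max(ev))
    stop("Fisher information is numerically singular at theta = ",
         paste(signif(theta, 4), collapse = ", "),
         "; consider reparametrizing the family")
  I
}

#' Efficient influence function of the minimum-Hellinger functional
#'
#' Implements
#' \deqn{\tilde T(x) = -\left[\int \ddot s_\theta(x)\, g_0^{1/2}(x)\,dx
#'   \right]^{-1} \frac{\dot s_\theta(x)}{2\, g_0^{1/2}(x)},}
#' the influence function of the functional `T` at `g0`, with the vanishing
#' remainder term set to zero.  At the model (`g0 = f_theta`) this reduces to
#' the score scaled by the inverse Fisher information, and its squared
#' centered `L2(g0)` norm equals `I(theta)^{-1}`.
#'
#' @param family a [parametric_family()].
#' @param theta the parameter value `T(g0)` (the caller's responsibility).
#' @param g0 a [density_fn()].
#' @param grid a [make_grid()] used for the matrix integral; defaults to the
#'   family window at `theta`.
#' @return function mapping points to an `n x p` matrix of influence values.
#' @export
efficient_influence <- function(family, theta, g0, grid = NULL) {
  theta <- check_theta(family, theta, interior = TRUE)
  if (is.null(grid)) grid <- make_grid(family$default_window(theta), order = 12)
  bun <- sqrt_density_derivatives(family, theta)
  sqg_nodes <- sqrt(eval_density(g0, grid$nodes))
  sdd <- bun$sddot(grid$nodes)
  p <- family$param_dim
  M <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p))
    M[i, j] <- sum(grid$weights * sdd[, i, j] * sqg_nodes)
  Minv <- solve(M)
  function(x) {
    x <- as_point_matrix(x, family$dim)
    sqg <- sqrt(eval_density(g0, x))
    sd <- bun$sdot(x)
    if (is.null(dim(sd))) sd <- matrix(sd, ncol = p)
    bad <- sqg == 0 & rowSums(abs(sd)) > 0
    if (any(bad)) {
      xb <- if (family$dim == 1L) x[which(bad)[1]] else x[which(bad)[1], ]
      stop("influence function unbounded at x = ",
           paste(signif(xb, 6), collapse = ", "),
           " (g0 vanishes where the family score does not)")
    }
    out <- -(sd / (2 * pmax(sqg, .Machine$double.xmin))) %*% t(Minv)
    out[sqg == 0, ] <- 0
    out
  }
}

#' Compactifying reparametrization
#'
#' Re-indexes an unbounded family by coordinate-wise arctangent maps so the
#' new parameter lives in a bounded rectangle: unbounded coordinates become
#' `t = atan(theta)`, coordinates bounded below at `L` become
#' `t = atan(theta - L)`; already-bounded coordinates are left alone.  The
#' returned family carries `compactify_theta` / `uncompactify_theta` maps and
#' optimum locations correspond under the bijection.
#'
#' @param family a [parametric_family()].
#' @return a [parametric_family()] on the bounded parameter rectangle.
#' @export
compactify <- function(family) {
  b <- family$param_bounds
  p <- family$param_dim
  fwd1 <- vector("list", p); inv1 <- vector("list", p)
  newb <- b
  for (i in seq_len(p)) {
    lo <- b[i, 1]; hi <- b[i, 2]
    if (is.finite(lo) && is.finite(hi)) {
      fwd1[[i]] <- identity; inv1[[i]] <- identity
    } else if (is.finite(lo)) {
      force(lo)
      fwd1[[i]] <- local({l <- lo; function(v) atan(v - l)})
      inv1[[i]] <- local({l <- lo; function(t) tan(t) + l})
      newb[i, ] <- c(0, pi / 2)
    } else if (is.finite(hi)) {
      fwd1[[i]] <- local({h <- hi; function(v) atan(v - h)})
      inv1[[i]] <- local({h <- hi; function(t) tan(t) + h})
      newb[i, ] <- c(-pi / 2, 0)
    } else {
      fwd1[[i]] <- atan
      inv1[[i]] <- tan
      newb[i, ] <- c(-pi / 2, pi / 2)
    }
  }
  fwd <- function(theta) vapply(seq_len(p), function(i) fwd1[[i]](theta[i]),
                                numeric(1))
  inv <- function(t) vapply(seq_len(p), function(i) inv1[[i]](t[i]),
                            numeric(1))
  base <- family
  out <- parametric_family(
    name = paste0(family$name, "_compact"),
    param_dim = p,
    param_names = paste0("t_", family$param_names),
    dim = family$dim,
    pdf = function(t, x) base$pdf(inv(t), x),
    param_bounds = newb,
    mle = function(x) fwd(base$mle(x)),
    sampler = function(t, n) base$sampler(inv(t), n),
    scale_at = function(t) base$scale_at(inv(t)),
    default_window = if (is.null(base$default_window)) NULL else
      function(t) base$default_window(inv(t)),
    auto_starts = if (is.null(base$auto_starts)) NULL else
      function(gv, grid) lapply(base$auto_starts(gv, grid), fwd),
    compactify_theta = fwd,
    uncompactify_theta = inv,
    parent = family
  )
  out
}

#' Map a compactified parameter back to the original coordinates
#'
#' @param cfamily a family returned by [compactify()].
#' @param t parameter vector in the compactified coordinates.
#' @return the parameter in the original coordinates.
#' @export
uncompactify_theta <- function(cfamily, t) {
  if (is.null(cfamily$uncompactify_theta))
    stop("family is not a compactified family")
  cfamily$uncompactify_theta(as.numeric(t))
}
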
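#' Evaluable probability density
#'
#' The common currency of the Hellinger machinery: a probability density on a
#' stated support that can be evaluated at arbitrary points.  Histogram
#' posterior means, Dirichlet-process mixture draws and parametric family
#' members are all represented this way before being fed to
#' [hellinger_distance()] or [minimize_hellinger()].
#'
#' @param pdf function; for `dim = 1` maps a numeric vector to density values,
#'   for `dim = 2` maps an `n x 2` matrix of points to density values.
#' @param dim dimension of the sample space (1 or 2).
#' @param support for `dim = 1` a length-2 numeric (may be infinite); for
#'   `dim = 2` a `2 x 2` matrix with one row `(lo, hi)` per coordinate.
#' @param breakpoints optional sorted interior quadrature breakpoints
#'   (1-D only); callers holding piecewise densities (histograms) must supply
#'   their bin edges here so quadrature panels never straddle a discontinuity.
#' @param label short description used in error messages and printing.
#' @return An object of class `density_fn`.
#' @export
density_fn <- function(pdf, dim = 1L, support = NULL, breakpoints = NULL,
                       label = "density") {
  stopifnot(is.function(pdf), dim %in% c(1L, 2L))
  if (is.null(support)) {
    support <- if (dim == 1L) c(-Inf, Inf) else
      matrix(c(-Inf, Inf, -Inf, Inf), nrow = 2, byrow = TRUE)
  }
  if (dim == 1L) {
    support <- as.numeric(support)
    stopifnot(length(support) == 2L, support[1] < support[2])
  } else {
    support <- matrix(as.numeric(support), nrow = 2)
    stopifnot(all(support[, 1] < support[, 2]))
  }
  if (!is.null(breakpoints)) breakpoints <- sort(unique(as.numeric(breakpoints)))
  structure(list(pdf = pdf, dim = as.integer(dim), support = support,
                 breakpoints = breakpoints, label = label),
            class = "density_fn")
}

#' Evaluate a density at points
#'
#' @param f a [density_fn()].
#' @param x numeric vector (1-D) or `n x 2` matrix (2-D) of points.
#' @return numeric vector of nonnegative density values.
#' @export
eval_density <- function(f, x) {
  stopifnot(inherits(f, "density_fn"))
  x <- as_point_matrix(x, f$dim)
  v <- f$pdf(x)
  v <- as.numeric(v)
  if (anyNA(v)) stop("density '", f$label, "' returned NA values")
  if (any(v < 0)) {
    bad <- if (f$dim == 1L) x[which(v < 0)[1]] else x[which(v < 0)[1], ]
    stop("density '", f$label, "' is negative at x = ",
         paste(signif(bad, 6), collapse = ", "))
  }
  v
}

#' @export
print.density_fn <- function(x, ...) {
  cat("<density_fn> ", x$label, " (dim ", x$dim, ")\n", sep = "")
  invisible(x)
}

# Finite normal mixture as a density_fn (internal); comps is a list of
# list(w, mu, sigma) for dim 1 or list(w, mu, Sigma) for dim 2; optional
# t-components carry df (multivariate t with scale matrix Sigma).
mixture_density_fn <- function(comps, dim, label = "mixture") {
  w <- vapply(comps, `[[`, numeric(1), "w")
  stopifnot(abs(sum(w) - 1) < 1e-8)
  pdf <- function(x) {
    x <- as_point_matrix(x, dim)
    v <- 0
    for (cm in comps) {
      vi <- if (is.null(cm$df)) {
        if (dim == 1L) stats::dnorm(x, cm$mu, sqrt(cm$Sigma))
        else dmvnorm2(x, cm$mu, cm$Sigma)
      } else {
        if (dim == 1L) dt_loc_scale(x, cm$mu, cm$Sigma, cm$df)
        else dmvt2(x, cm$mu, cm$Sigma, cm$df)
      }
      v <- v + cm$w * vi
    }
    v
  }
  density_fn(pdf, dim = dim, label = label)
}

# Bivariate normal density, scalar arithmetic (fast, no per-call solve()).
dmvnorm2 <- function(x, mu, Sigma) {
  a <- Sigma[1, 1]; b <- Sigma[1, 2]; d <- Sigma[2, 2]
  det <- a * d - b * b
  if (det <= 0) return(rep(0, nrow(x)))
  dx <- x[, 1] - mu[1]; dy <- x[, 2] - mu[2]
  q <- (d * dx * dx - 2 * b * dx * dy + a * dy * dy) / det
  exp(-0.5 * q) / (2 * pi * sqrt(det))
}

# Univariate location-scale t with scale^2 parameter s2.
dt_loc_scale <- function(x, mu, s2, df) {
  s <- sqrt(s2)
  stats::dt((x - mu) / s, df = df) / s
}

# Bivariate t density with scale matrix S.
dmvt2 <- function(x, mu, S, df) {
  a <- S[1, 1]; b <- S[1, 2]; d <- S[2, 2]
  det <- a * d - b * b
  dx <- x[, 1] - mu[1]; dy <- x[, 2] - mu[2]
  q <- (d * dx * dx - 2 * b * dx * dy + a * dy * dy) / det
  lc <- lgamma((df + 2) / 2) - lgamma(df / 2) - log(df * pi) - 0.5 * log(det)
  exp(lc - ((df + 2) / 2) * log1p(q / df))
}
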
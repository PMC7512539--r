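#' Hellinger affinity between two densities
#'
#' The Bhattacharyya coefficient \eqn{\int \sqrt{f g}}, computed on a fixed
#' quadrature grid.  Warns when either density places less than
#' `1 - mass_tol` of its mass inside the grid window.
#'
#' @param f,g [density_fn()] objects of the same dimension.
#' @param grid a [make_grid()] object.
#' @param mass_tol window-coverage tolerance (default `1e-6`).
#' @return affinity in `[0, 1]` (up to quadrature error).
#' @export
hellinger_affinity <- function(f, g, grid, mass_tol = 1e-6) {
  vf <- eval_density(f, grid$nodes)
  vg <- eval_density(g, grid$nodes)
  for (dd in list(list(d = f, v = vf), list(d = g, v = vg))) {
    m <- sum(grid$weights * dd$v)
    if (m < 1 - mass_tol)
      warning("density '", dd$d$label, "' has mass ", signif(m, 6),
              " inside the quadrature window")
  }
  sum(grid$weights * sqrt(vf * vg))
}

#' Hellinger distance between two densities
#'
#' \eqn{h(f,g) = [\int (\sqrt f - \sqrt g)^2]^{1/2}
#'   = \sqrt{2 - 2\int\sqrt{fg}}}, bounded by \eqn{\sqrt 2}.
#'
#' @inheritParams hellinger_affinity
#' @return nonnegative real, at most `sqrt(2)`.
#' @export
hellinger_distance <- function(f, g, grid, mass_tol = 1e-6) {
  a <- hellinger_affinity(f, g, grid, mass_tol)
  sqrt(max(0, 2 - 2 * a))
}

#' Minimum Hellinger distance functional T
#'
#' Finds the member of a parametric family closest in Hellinger distance to a
#' given density, by maximizing the affinity \eqn{\int \sqrt{f_\theta g}}
#' with a derivative-free simplex search from several starting points.
#' Optimization runs in the family's unconstrained internal coordinates
#' (log-sd / Cholesky), so iterates respect the bounds.  The functional may
#' be multi-valued; distinct local optima found are reported, ties in
#' distance (within `tie_tol`) are broken by the lexicographically smallest
#' parameter vector.
#'
#' @param family a [parametric_family()].
#' @param g a [density_fn()] on the same sample space.
#' @param grid a [make_grid()] whose window carries (essentially) all of
#'   `g`'s mass; for histogram `g`, its bin edges must be among the grid
#'   breakpoints.
#' @param starts `"auto"` (moment-matched, robust and dispersed starts from
#'   `g`) or a list of parameter vectors.
#' @param tie_tol distances within this of the best are treated as ties.
#' @param control passed to [stats::optim()] (Nelder--Mead).
#' @param mass_tol warn when `g` has less than `1 - mass_tol` of its mass
#'   inside the window (heavy-tailed posterior draws legitimately leave a
#'   little mass outside a data-driven window).
#' @return object of class `tresult`: fields `theta_hat`, `hellinger`,
#'   `affinity`, `n_starts`, `converged`, `all_local_optima`.
#' @export
minimize_hellinger <- function(family, g, grid, starts = "auto",
                               tie_tol = 1e-8, control = list(),
                               mass_tol = 1e-4) {
  stopifnot(inherits(family, "parametric_family"), inherits(g, "density_fn"),
            family$dim == g$dim)
  gv <- eval_density(g, grid$nodes)
  gmass <- sum(grid$weights * gv)
  if (gmass < 1 - mass_tol)
    warning("density '", g$label, "' has mass ", signif(gmass, 6),
            " inside the quadrature window; T may be biased")
  sqg <- sqrt(gv)
  w <- grid$weights
  negaff <- function(p) {
    th <- family$from_internal(p)
    fv <- family$pdf(th, grid$nodes)
    if (anyNA(fv) || any(fv < 0)) return(2)
    -sum(w * sqrt(fv) * sqg)
  }
  if (identical(starts, "auto")) {
    if (is.null(family$auto_starts))
      stop("family '", family$name, "' has no auto starts; supply `starts`")
    starts <- family$auto_starts(gv, grid)
  }
  starts <- lapply(starts, function(th) check_theta(family, th))
  ctl <- utils::modifyList(list(reltol = 1e-12, maxit = 3000), control)
  opts <- list()
  simplex <- function(par) {
    # Nelder-Mead is fine in one dimension too; silence R's advisory
    if (length(par) == 1L)
      suppressWarnings(stats::optim(par, negaff, method = "Nelder-Mead",
                                    control = ctl))
    else stats::optim(par, negaff, method = "Nelder-Mead", control = ctl)
  }
  for (th0 in starts) {
    fit <- tryCatch(simplex(family$to_internal(th0)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    opts[[length(opts) + 1]] <- list(
      theta = family$from_internal(fit$par),
      affinity = -fit$value,
      converged = fit$convergence == 0)
  }
  if (!length(opts) || !any(vapply(opts, `[[`, logical(1), "converged")))
    stop("minimize_hellinger: no start converged (", length(starts),
         " starts tried on family '", family$name, "')")
  aff <- vapply(opts, `[[`, numeric(1), "affinity")
  hd <- sqrt(pmax(0, 2 - 2 * aff))
  best <- min(hd)
  tied <- which(hd <= best + tie_tol)
  # lexicographic tie-break
  if (length(tied) > 1) {
    thmat <- do.call(rbind, lapply(opts[tied], `[[`, "theta"))
    ord <- do.call(order, as.data.frame(thmat))
    pick <- tied[ord[1]]
  } else pick <- tied
  # deduplicate local optima for reporting
  uniq <- list()
  for (o in opts) {
    dup <- any(vapply(uniq, function(u)
      max(abs(u$theta - o$theta)) < 1e-5, logical(1)))
    if (!dup) uniq[[length(uniq) + 1]] <- o
  }
  structure(list(
    theta_hat = opts[[pick]]$theta,
    hellinger = hd[pick],
    affinity = aff[pick],
    n_starts = length(starts),
    converged = opts[[pick]]$converged,
    all_local_optima = lapply(uniq, function(o)
      list(theta = o$theta, hellinger = sqrt(max(0, 2 - 2 * o$affinity)))),
    family = family$name,
    param_names = family$param_names
  ), class = "tresult")
}

#' @export
print.tresult <- function(x, ...) {
  cat("<tresult> family ", x$family, "\n  theta_hat: ",
      paste(sprintf("%s = %.5g", x$param_names, x$theta_hat),
            collapse = ", "),
      "\n  hellinger = ", signif(x$hellinger, 6),
      " (affinity ", signif(x$affinity, 6), "), ",
      length(x$all_local_optima), " local optimum/a from ", x$n_starts,
      " starts\n", sep = "")
  invisible(x)
}
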
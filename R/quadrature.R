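#' Composite Gauss--Legendre quadrature grid
#'
#' Builds the fixed quadrature rule on which all Hellinger affinities are
#' computed.  In one dimension the window is split into panels at the supplied
#' breakpoints and an `order`-point Gauss--Legendre rule is placed on each
#' panel; in two dimensions the rule is the tensor product of two such 1-D
#' rules.  Callers integrating piecewise densities (histograms) must pass the
#' bin edges as breakpoints so that no panel straddles a discontinuity.
#'
#' @param window length-2 numeric `(lo, hi)` for 1-D, or a `2 x 2` matrix with
#'   rows `(lo, hi)` per coordinate for 2-D.
#' @param breakpoints sorted interior breakpoints (1-D), or a list of two such
#'   vectors (2-D); points outside the window are dropped.
#' @param order number of Gauss--Legendre nodes per panel (default 10; exact
#'   for polynomials of degree `2*order - 1` on each panel).
#' @param max_panel_width panels wider than this are subdivided, so that a
#'   breakpoint-free window still resolves smooth densities (default:
#'   window width / 16 per axis).
#' @return An object of class `quadrature_grid` with fields `dimension`,
#'   `nodes`, `weights`, `window`, `breakpoints`.
#' @export
make_grid <- function(window, breakpoints = NULL, order = 10,
                      max_panel_width = NULL) {
  if (is.matrix(window) || (is.list(breakpoints) && length(breakpoints) == 2)) {
    window <- matrix(as.numeric(window), nrow = 2)
    stopifnot(all(is.finite(window)), all(window[, 1] < window[, 2]))
    if (is.null(breakpoints)) breakpoints <- list(NULL, NULL)
    g1 <- make_grid(window[1, ], breakpoints[[1]], order, max_panel_width)
    g2 <- make_grid(window[2, ], breakpoints[[2]], order, max_panel_width)
    nodes <- cbind(rep(g1$nodes, times = length(g2$nodes)),
                   rep(g2$nodes, each = length(g1$nodes)))
    weights <- rep(g2$weights, each = length(g1$weights)) *
      rep(g1$weights, times = length(g2$weights))
    return(structure(list(dimension = 2L, nodes = nodes, weights = weights,
                          window = window,
                          breakpoints = list(g1$breakpoints, g2$breakpoints),
                          order = order),
                     class = "quadrature_grid"))
  }
  window <- as.numeric(window)
  stopifnot(length(window) == 2L, all(is.finite(window)), window[1] < window[2])
  bp <- breakpoints
  if (!is.null(bp)) {
    if (is.unsorted(bp, strictly = FALSE)) stop("breakpoints must be sorted")
    bp <- bp[bp > window[1] & bp < window[2]]
  }
  edges <- sort(unique(c(window, bp)))
  if (is.null(max_panel_width))
    max_panel_width <- diff(window) / 16
  # subdivide wide panels
  refined <- unlist(lapply(seq_len(length(edges) - 1), function(i) {
    a <- edges[i]; b <- edges[i + 1]
    m <- max(1L, ceiling((b - a) / max_panel_width))
    seq(a, b, length.out = m + 1L)[-(m + 1L)]
  }))
  edges <- c(refined, edges[length(edges)])
  base <- pracma::gaussLegendre(order, 0, 1)
  nodes <- numeric(0); weights <- numeric(0)
  for (i in seq_len(length(edges) - 1)) {
    a <- edges[i]; b <- edges[i + 1]
    nodes <- c(nodes, a + (b - a) * base$x)
    weights <- c(weights, (b - a) * base$w)
  }
  structure(list(dimension = 1L, nodes = nodes, weights = weights,
                 window = window, breakpoints = bp, order = order),
            class = "quadrature_grid")
}

#' Integrate tabulated values over a quadrature grid
#'
#' @param grid a [make_grid()] object.
#' @param values density (or integrand) values at `grid$nodes`, or a
#'   [density_fn()] to be evaluated there.
#' @return the quadrature approximation to the integral over the window.
#' @export
grid_integrate <- function(grid, values) {
  stopifnot(inherits(grid, "quadrature_grid"))
  if (inherits(values, "density_fn")) values <- eval_density(values, grid$nodes)
  sum(grid$weights * values)
}

#' @export
print.quadrature_grid <- function(x, ...) {
  cat("<quadrature_grid> dim ", x$dimension, ", ",
      if (x$dimension == 1L) length(x$nodes) else nrow(x$nodes),
      " nodes, order ", x$order, "\n", sep = "")
  invisible(x)
}

# Default evaluation window for a density: its finite support if stated,
# otherwise data-driven (range +/- 4 robust sds), used by high-level wrappers.
default_window_for <- function(g, data = NULL) {
  if (g$dim == 1L) {
    if (all(is.finite(g$support))) return(g$support)
    stopifnot(!is.null(data))
    s <- max(stats::mad(data), stats::sd(data) / 3, 1e-8)
    range(data) + c(-4, 4) * s
  } else {
    if (all(is.finite(g$support))) return(g$support)
    stopifnot(!is.null(data))
    t(vapply(1:2, function(j) {
      s <- max(stats::mad(data[, j]), stats::sd(data[, j]) / 3, 1e-8)
      range(data[, j]) + c(-4, 4) * s
    }, numeric(2)))
  }
}
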
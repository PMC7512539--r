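# Internal helpers shared across modules.

# Run `expr` with the RNG seeded at `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic sub-seed stream: distinct, reproducible, < 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(index)) %% 2147483647)
}

is_square_pd <- function(S, tol = 1e-12) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) return(FALSE)
  if (max(abs(S - t(S))) > 1e-8 * (1 + max(abs(S)))) return(FALSE)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol * max(abs(ev), 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

as_point_matrix <- function(x, dim) {
  if (dim == 1L) {
    if (is.matrix(x)) x <- drop(x)
    return(as.numeric(x))
  }
  if (is.null(dim(x))) x <- matrix(x, ncol = dim, byrow = FALSE)
  if (ncol(x) != dim) stop("points must have ", dim, " columns")
  x
}
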
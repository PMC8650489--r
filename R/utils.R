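# Internal helpers shared across modules.

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministically mix two non-negative integers into a valid seed (< 2^31).
# Used to derive per-subject / per-run seeds from a master seed.
mix_seed <- function(seed, k) {
  m <- 2147483647
  s <- (as.double(seed) %% m)
  for (x in c(k, 0x9E37)) {
    s <- (s * 48271 + as.double(x) + 1) %% m
  }
  as.integer(s)
}

stopifnot_scalar_count <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || x != round(x))
    stop(sprintf("`%s` must be a single positive integer", name), call. = FALSE)
  invisible(as.integer(x))
}

is_near_integer <- function(x, tol = 1e-8) abs(x - round(x)) < tol

# Symmetry / range checks for weighted adjacency matrices.
check_adjacency <- function(w) {
  if (!is.matrix(w) || nrow(w) != ncol(w))
    stop("adjacency must be a square matrix", call. = FALSE)
  if (any(!is.finite(w)))
    stop("adjacency contains non-finite values", call. = FALSE)
  if (max(abs(w - t(w))) > 1e-12)
    stop("adjacency must be symmetric", call. = FALSE)
  if (any(w < 0))
    stop("adjacency weights must be non-negative", call. = FALSE)
  if (any(diag(w) != 0))
    stop("adjacency must have a zero diagonal (no self-loops)", call. = FALSE)
  invisible(w)
}
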
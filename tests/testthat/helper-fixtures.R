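# Small graph and cohort builders used across test files.

# Random symmetric weight matrix with zero diagonal; `density` < 1 zeroes a
# matching fraction of edges.
rand_sym <- function(n, seed, density = 1) {
  set.seed(seed)
  w <- matrix(runif(n * n), n, n)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  if (density < 1) {
    ut <- which(upper.tri(w))
    drop <- sample(ut, round((1 - density) * length(ut)))
    w[drop] <- 0
    w <- pmin(w, t(w))
  }
  w
}

# Symmetric matrix from an edge list: rows (i, j, weight).
edges_to_adj <- function(n, edges) {
  w <- matrix(0, n, n)
  for (r in seq_len(nrow(edges))) {
    w[edges[r, 1], edges[r, 2]] <- edges[r, 3]
    w[edges[r, 2], edges[r, 1]] <- edges[r, 3]
  }
  w
}

# Two disconnected unit-weight triangles on nodes 1:3 and 4:6.
two_triangles <- function() {
  edges_to_adj(6, cbind(c(1, 1, 2, 4, 4, 5), c(2, 3, 3, 5, 6, 6), 1))
}

# Weighted planted 3-module graph: strong within-module, weak between.
planted_graph <- function(n_per_mod = 8, within = 0.9, between = 0.05,
                          seed = 1) {
  set.seed(seed)
  n <- 3 * n_per_mod
  memb <- rep(1:3, each = n_per_mod)
  w <- matrix(between, n, n) + matrix(runif(n * n, 0, 0.02), n, n)
  w <- (w + t(w)) / 2
  for (m in 1:3) {
    idx <- which(memb == m)
    w[idx, idx] <- within + matrix(runif(length(idx)^2, 0, 0.02), length(idx))
  }
  w <- (w + t(w)) / 2
  w <- pmin(w, 1)
  diag(w) <- 0
  list(w = w, memb = memb)
}

# Small fast cohort spec for pipeline tests.
small_spec <- function(seed = 1, n_rois = 24, n_sub = c(A = 3, B = 3),
                       within_b = NULL) {
  ge <- if (is.null(within_b)) list()
        else list(B = list(within_coupling = within_b))
  cohort_spec(
    n_per_group = n_sub, n_rois = n_rois,
    design = make_block_design(4, 20, 20, 2.5),
    structure = planted_structure(rep_len(1:3, n_rois),
                                  within_coupling = 0.7,
                                  between_coupling = 0.05,
                                  group_effects = ge),
    seed = seed)
}
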
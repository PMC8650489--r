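# Modular decomposition: Newman modularity maximization (greedy
# agglomeration + Kernighan-Lin style single-node reassignment), consensus
# over repeated randomized runs, and the normalized variation-of-information
# partition distance.

#' Modular partition container
#'
#' @param affiliation Integer module index per node; relabeled to contiguous
#'   `1..M` in order of first appearance, so the module containing node 1 is
#'   always labeled 1 (the "node 1 as reference" convention).
#' @param q Newman modularity of the partition (may be `NA` if not computed).
#' @param node_names Node labels.
#' @param n_runs Number of optimization runs behind the partition.
#' @return An object of class `modular_partition`.
#' @export
modular_partition <- function(affiliation, q = NA_real_, node_names = NULL,
                              n_runs = 1L) {
  affiliation <- relabel_first_appearance(as.integer(affiliation))
  if (is.null(node_names)) node_names <- default_roi_names(length(affiliation))
  if (length(node_names) != length(affiliation))
    stop("`node_names` must match `affiliation` length", call. = FALSE)
  structure(list(affiliation = setNames(affiliation, node_names), q = q,
                 n_runs = as.integer(n_runs),
                 node_names = as.character(node_names)),
            class = "modular_partition")
}

#' @export
print.modular_partition <- function(x, ...) {
  cat(sprintf("Modular partition: %d nodes in %d modules (Q = %s, %d run%s)\n",
              length(x$affiliation), max(x$affiliation),
              ifelse(is.na(x$q), "NA", sprintf("%.4f", x$q)), x$n_runs,
              ifelse(x$n_runs == 1, "", "s")))
  invisible(x)
}

# Map labels to 1..M in order of first appearance (node 1's module -> 1).
relabel_first_appearance <- function(aff) {
  if (anyNA(aff)) stop("affiliation contains NA", call. = FALSE)
  match(aff, unique(aff))
}

#' Newman modularity of a partition
#'
#' `Q = (1/2m) * sum_ij (w_ij - s_i s_j / 2m) delta(c_i, c_j)` with
#' `m = (1/2) sum_ij w_ij` and `s` the nodal strengths. Zero-edge graphs have
#' no defined modularity and raise an error.
#'
#' @param g A [brain_graph()].
#' @param partition A [modular_partition()] or an affiliation vector over the
#'   nodes of `g`.
#' @return Scalar `Q` in `[-1, 1]`.
#' @export
newman_modularity <- function(g, partition) {
  stopifnot(inherits(g, "brain_graph"))
  aff <- as_affiliation(partition, g)
  w <- g$adjacency
  two_m <- sum(w)
  if (two_m == 0) stop("modularity undefined on a zero-edge graph", call. = FALSE)
  s <- colSums(w)
  q <- 0
  for (c in unique(aff)) {
    idx <- aff == c
    q <- q + sum(w[idx, idx]) / two_m - (sum(s[idx]) / two_m)^2
  }
  q
}

as_affiliation <- function(partition, g) {
  aff <- if (inherits(partition, "modular_partition")) partition$affiliation
         else as.integer(partition)
  if (length(aff) != nrow(g$adjacency))
    stop("partition does not cover all nodes of the graph", call. = FALSE)
  unname(aff)
}

# --- optimizer internals -----------------------------------------------------

# Greedy agglomeration from singleton modules: repeatedly merge a module
# pair with positive modularity gain -- the largest gain when
# `randomize = FALSE` (ties broken at random), or a uniform draw among all
# positive-gain pairs when `randomize = TRUE`, which gives independent
# restarts genuinely different trajectories.
greedy_merge <- function(w, tol = 1e-12, randomize = FALSE) {
  n <- nrow(w)
  memb <- seq_len(n)
  m2 <- sum(w)                     # 2m
  B <- w                           # aggregated module adjacency
  S <- colSums(w)                  # aggregated module strengths
  alive <- rep(TRUE, n)
  repeat {
    ids <- which(alive)
    if (length(ids) < 2) break
    D <- B[ids, ids, drop = FALSE] / (m2 / 2) -
      outer(S[ids], S[ids]) / (2 * (m2 / 2)^2)
    diag(D) <- -Inf
    best <- max(D)
    if (best <= tol) break
    cand <- if (randomize) which(D > tol, arr.ind = TRUE)
            else which(D == best, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pick <- cand[sample.int(nrow(cand), 1L), ]
    a <- ids[pick[1L]]; b <- ids[pick[2L]]
    memb[memb == b] <- a
    B[a, ] <- B[a, ] + B[b, ]
    B[, a] <- B[, a] + B[, b]
    S[a] <- S[a] + S[b]
    alive[b] <- FALSE
  }
  memb
}

# Kernighan-Lin refinement. Each pass tentatively moves every node exactly
# once: at each step the (node, destination-module) reassignment with the
# largest modularity gain among unlocked nodes is applied -- even when that
# gain is negative, which lets the search tunnel out of local optima -- and
# the node is locked. Destinations include one empty module, so nodes can
# split off. The pass then rolls back to the best prefix of the move
# sequence; passes repeat while they improve modularity. Ties among best
# moves are broken at random.
kl_refine <- function(w, memb, tol = 1e-12, max_passes = 50L) {
  n <- nrow(w)
  m <- sum(w) / 2
  s <- colSums(w)
  memb <- relabel_first_appearance(memb)
  for (pass in seq_len(max_passes)) {
    M <- max(memb) + 1L                 # slot M is the empty module
    K <- matrix(0, M, n)                # K[c, i]: strength from i into c
    for (c in seq_len(M - 1L))
      K[c, ] <- colSums(w[memb == c, , drop = FALSE])
    S <- numeric(M)
    S[seq_len(M - 1L)] <- as.vector(rowsum(s, memb))
    cur <- memb
    locked <- rep(FALSE, n)
    gain <- 0
    best_gain <- 0
    snapshot <- memb
    while (!all(locked)) {
      kcur <- K[cbind(cur, seq_len(n))]
      dq <- sweep(K, 2L, kcur) / m -
        (outer(S, s) - matrix(s * S[cur] - s^2, M, n, byrow = TRUE)) /
          (2 * m^2)
      dq[cbind(cur, seq_len(n))] <- -Inf
      dq[, locked] <- -Inf
      top <- max(dq)
      cand <- which(dq == top)
      pick <- if (length(cand) > 1) cand[sample.int(length(cand), 1L)] else cand
      i <- ((pick - 1L) %/% M) + 1L
      c_new <- ((pick - 1L) %% M) + 1L
      c_old <- cur[i]
      K[c_old, ] <- K[c_old, ] - w[i, ]
      K[c_new, ] <- K[c_new, ] + w[i, ]
      S[c_old] <- S[c_old] - s[i]
      S[c_new] <- S[c_new] + s[i]
      cur[i] <- c_new
      locked[i] <- TRUE
      gain <- gain + top
      if (c_new == M) {                 # empty module used: open a new slot
        M <- M + 1L
        K <- rbind(K, 0)
        S <- c(S, 0)
      }
      if (gain > best_gain + tol) {
        best_gain <- gain
        snapshot <- cur
      }
    }
    if (best_gain <= tol) break
    memb <- relabel_first_appearance(snapshot)
  }
  memb
}

# Merge whole modules greedily on the module-aggregated adjacency.
merge_modules <- function(w, memb, tol = 1e-12, randomize = FALSE) {
  memb <- relabel_first_appearance(memb)
  if (max(memb) == 1L) return(memb)
  agg <- rowsum(t(rowsum(w, memb)), memb)
  grouping <- greedy_merge(agg, tol, randomize = randomize)
  relabel_first_appearance(grouping[memb])
}

# Modularity from raw inputs (no container overhead), used inside loops.
q_of <- function(w, memb) {
  two_m <- sum(w)
  s <- colSums(w)
  q <- 0
  for (c in unique(memb)) {
    idx <- memb == c
    q <- q + sum(w[idx, idx]) / two_m - (sum(s[idx]) / two_m)^2
  }
  q
}

#' Single-run modularity maximization
#'
#' Heuristic Newman-modularity maximization: every node starts in its own
#' module, then greedy agglomeration phases (merging module pairs while the
#' modularity gain is positive) alternate with Kernighan-Lin style
#' single-node reassignment sweeps (which may also split nodes off into a
#' fresh module) until a full cycle yields no further modularity gain. Sweep
#' order and tie-breaking among equal-gain moves are randomized from `seed`,
#' so repeated runs explore different local optima; `Q` never decreases
#' across the phases.
#'
#' @param g A [brain_graph()] with at least one edge.
#' @param seed Integer seed for the run's randomness.
#' @param restarts Randomized merge-refine cycles per run; the best-Q
#'   partition is returned. More restarts harden a single run against local
#'   optima at proportional cost. The default scales inversely with graph
#'   size (`max(4, ceiling(192 / N))`): on tiny graphs each cycle costs
#'   microseconds while local optima weigh heaviest, so many cheap restarts
#'   are spent there; large graphs keep 4.
#' @return A [modular_partition()] with its modularity `q` and `n_runs = 1`.
#' @export
optimize_modularity <- function(g, seed = 1L, restarts = NULL) {
  stopifnot(inherits(g, "brain_graph"))
  w <- g$adjacency
  if (is.null(restarts)) restarts <- max(4L, as.integer(ceiling(192 / nrow(w))))
  stopifnot_scalar_count(restarts, "restarts")
  if (sum(w) == 0) stop("graph has no edges", call. = FALSE)
  n <- nrow(w)
  memb <- with_seed(seed, {
    best <- NULL
    q_best <- -Inf
    for (r in seq_len(restarts)) {
      if (r == 1L) {
        # the canonical schedule: from singletons, agglomerate then refine
        memb <- seq_len(n)
      } else {
        # diversification: restart from a random coarse partition, refined
        # before any merging so its structure is not collapsed prematurely
        memb <- kl_refine(w, sample.int(sample.int(min(n, 8L), 1L), n,
                                        replace = TRUE))
      }
      q_cur <- -Inf
      repeat {
        memb <- merge_modules(w, memb, randomize = r > 1L)
        memb <- kl_refine(w, memb)
        q_new <- q_of(w, memb)
        if (q_new <= q_cur + 1e-12) break
        q_cur <- q_new
      }
      if (q_cur > q_best) {
        q_best <- q_cur
        best <- memb
      }
    }
    best
  })
  p <- modular_partition(memb, node_names = g$node_names, n_runs = 1L)
  p$q <- newman_modularity(g, p)
  p
}

# Align labels of `aff` to `ref` by greedy maximum-overlap matching of the
# contingency table; unmatched labels receive fresh ids.
align_labels <- function(aff, ref) {
  tab <- table(aff, ref)
  map <- integer(0)
  used_ref <- integer(0)
  t2 <- tab
  while (any(t2 > 0)) {
    idx <- which(t2 == max(t2), arr.ind = TRUE)[1L, ]
    a <- as.integer(rownames(t2)[idx[1L]])
    r <- as.integer(colnames(t2)[idx[2L]])
    map[as.character(a)] <- r
    used_ref <- c(used_ref, r)
    t2[idx[1L], ] <- -1
    t2[, idx[2L]] <- -1
  }
  unmatched <- setdiff(unique(aff), as.integer(names(map)))
  if (length(unmatched)) {
    fresh <- max(c(ref, map)) + seq_along(unmatched)
    map[as.character(unmatched)] <- fresh
  }
  unname(map[as.character(aff)])
}

#' Consensus modular decomposition
#'
#' Runs [optimize_modularity()] `n_runs` times with seeds derived from
#' `seed`, aligns every run's module labels to the first run by greedy
#' maximum-overlap matching (module labels are nominal, so runs must be
#' aligned before any averaging), assigns each node its modal aligned label,
#' applies one final refinement sweep so the consensus is itself a local
#' optimum, and relabels modules with node 1's module as reference label 1.
#'
#' @param g A [brain_graph()] with at least one edge.
#' @param n_runs Number of randomized runs; default 100.
#' @param seed Master seed; run seeds are derived deterministically.
#' @return A [modular_partition()] with the consensus `q` and `n_runs`.
#' @export
consensus_partition <- function(g, n_runs = 100L, seed = 1L) {
  stopifnot(inherits(g, "brain_graph"))
  stopifnot_scalar_count(n_runs, "n_runs")
  runs <- lapply(seq_len(n_runs), function(r)
    unname(optimize_modularity(g, seed = mix_seed(seed, r))$affiliation))
  ref <- runs[[1L]]
  aligned <- vapply(runs, align_labels, integer(length(ref)), ref = ref)
  # modal aligned label per node; ties -> smallest label (deterministic)
  memb <- apply(aligned, 1L, function(lbls) {
    tab <- table(lbls)
    as.integer(names(tab)[which.max(tab)])
  })
  memb <- with_seed(mix_seed(seed, 0L), kl_refine(g$adjacency, memb))
  p <- modular_partition(memb, node_names = g$node_names, n_runs = n_runs)
  p$q <- newman_modularity(g, p)
  p
}

#' Partition distance (normalized variation of information)
#'
#' `VI(P, Q) = H(P) + H(Q) - 2 I(P; Q)` computed from the module-overlap
#' contingency table (natural logs), normalized by `log N` so the distance
#' lies in `[0, 1]` and is invariant to the logarithm base. It is 0 exactly
#' when the partitions are identical up to relabeling, and 1 between the
#' all-in-one and all-singletons partitions.
#'
#' @param p,q [modular_partition()] objects (or affiliation vectors) over the
#'   same node set.
#' @return Scalar distance in `[0, 1]`.
#' @export
partition_distance <- function(p, q) {
  ap <- if (inherits(p, "modular_partition")) unname(p$affiliation) else as.integer(p)
  aq <- if (inherits(q, "modular_partition")) unname(q$affiliation) else as.integer(q)
  if (length(ap) != length(aq))
    stop("partitions must cover the same node set", call. = FALSE)
  n <- length(ap)
  if (n < 2) return(0)
  tab <- table(ap, aq) / n
  hp <- entropy_from_counts(table(ap))
  hq <- entropy_from_counts(table(aq))
  pij <- tab[tab > 0]
  hjoint <- -sum(pij * log(pij))
  mi <- hp + hq - hjoint
  vi <- hp + hq - 2 * mi
  min(max(vi / log(n), 0), 1)
}
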
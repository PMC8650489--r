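# Weighted network metrics: normalized nodal degree and strength, Onnela
# weighted clustering, and global efficiency on inverse-weight lengths.

#' Normalized nodal degree
#'
#' Number of edges incident to each node divided by the node count `N`, so
#' values from networks with different node sets are comparable.
#'
#' @param g A [brain_graph()] with >= 2 nodes.
#' @return Named numeric vector `k_i / N`.
#' @export
nodal_degree <- function(g) {
  stopifnot(inherits(g, "brain_graph"))
  n <- nrow(g$adjacency)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  colSums(g$adjacency > 0) / n
}

#' Normalized nodal strength
#'
#' Sum of the weights of the edges incident to each node, divided by `N`.
#'
#' @inheritParams nodal_degree
#' @return Named numeric vector `s_i / N`.
#' @export
nodal_strength <- function(g) {
  stopifnot(inherits(g, "brain_graph"))
  n <- nrow(g$adjacency)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  colSums(g$adjacency) / n
}

#' Weighted clustering coefficients
#'
#' Per-node clustering based on the geometric mean of the weights in each
#' triangle around the node:
#' `C_i = 2 t_i / (k_i (k_i - 1))` with
#' `t_i = 1/2 * sum_{j,h} (w_ij w_ih w_jh)^{1/3}`, and `C_i = 0` for nodes
#' with fewer than two neighbours. For weights in `[0, 1]`, `C_i` lies in
#' `[0, 1]`; scaling all weights by `c` scales every `C_i` by `c`.
#'
#' @param g A [brain_graph()] with weights in `[0, 1]`.
#' @return Named numeric vector of `C_i`.
#' @export
clustering_coefficients <- function(g) {
  stopifnot(inherits(g, "brain_graph"))
  w <- g$adjacency
  if (any(w > 1))
    stop("clustering assumes weights in [0, 1]", call. = FALSE)
  cw <- w^(1 / 3)
  t_i <- diag(cw %*% cw %*% cw) / 2          # triangle intensity per node
  k <- colSums(w > 0)
  ci <- numeric(nrow(w))
  ok <- k >= 2
  ci[ok] <- 2 * t_i[ok] / (k[ok] * (k[ok] - 1))
  names(ci) <- g$node_names
  ci
}

# Per-node efficiency: e_i = mean_j 1/d(i,j) with edge length 1/w and
# 1/Inf = 0 for unreachable pairs. mean(e_i) is the global efficiency.
nodal_efficiency <- function(g) {
  stopifnot(inherits(g, "brain_graph"))
  n <- nrow(g$adjacency)
  if (n < 2) stop("need at least 2 nodes", call. = FALSE)
  d <- shortest_path_lengths(g)
  inv <- 1 / d
  diag(inv) <- 0
  setNames(rowSums(inv) / (n - 1), g$node_names)
}

# All-pairs weighted shortest-path matrix with length = 1/weight (Dijkstra
# via igraph); Inf for unreachable pairs.
shortest_path_lengths <- function(g) {
  w <- g$adjacency
  ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  if (igraph::ecount(ig) == 0) {
    d <- matrix(Inf, nrow(w), ncol(w), dimnames = dimnames(w))
    diag(d) <- 0
    return(d)
  }
  igraph::distances(ig, weights = 1 / igraph::E(ig)$weight,
                    algorithm = "dijkstra")
}

#' Global efficiency
#'
#' Average inverse shortest-path length over all ordered node pairs, with
#' inverse edge weights as connection lengths and a contribution of 0 for
#' disconnected pairs:
#' `E = 1/(N(N-1)) * sum_{i != j} 1/d_ij`. Equals 1 on a complete unit-weight
#' graph and 0 on an edgeless one.
#'
#' @inheritParams nodal_degree
#' @return Scalar efficiency, `>= 0`.
#' @export
global_efficiency <- function(g) {
  mean(nodal_efficiency(g))
}

#' Summary metrics of a network
#'
#' Computes the four network metrics on one graph and returns both the
#' per-node vectors and the mean-and-SD summaries used for group reporting.
#'
#' @inheritParams nodal_degree
#' @return A list of class `network_metrics` with `per_node` (data frame:
#'   node, degree_norm, strength_norm, clustering, efficiency) and `global`
#'   (named list of means, sample SDs and `global_efficiency`).
#' @export
network_metrics <- function(g) {
  deg <- nodal_degree(g)
  str <- nodal_strength(g)
  clu <- clustering_coefficients(g)
  eff <- nodal_efficiency(g)
  per_node <- data.frame(node = g$node_names, degree_norm = unname(deg),
                         strength_norm = unname(str), clustering = unname(clu),
                         efficiency = unname(eff),
                         stringsAsFactors = FALSE)
  glob <- list(
    mean_degree_norm = mean(deg), sd_degree_norm = stats::sd(deg),
    mean_strength_norm = mean(str), sd_strength_norm = stats::sd(str),
    mean_clustering = mean(clu), sd_clustering = stats::sd(clu),
    global_efficiency = mean(eff), sd_efficiency = stats::sd(eff))
  structure(list(per_node = per_node, global = glob),
            class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  g <- x$global
  cat(sprintf(
    "Network metrics over %d nodes:\n  degree %0.2f ± %0.2f | strength %0.2f ± %0.2f | clustering %0.2f ± %0.2f | efficiency %0.2f\n",
    nrow(x$per_node), g$mean_degree_norm, g$sd_degree_norm,
    g$mean_strength_norm, g$sd_strength_norm,
    g$mean_clustering, g$sd_clustering, g$global_efficiency))
  invisible(x)
}
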
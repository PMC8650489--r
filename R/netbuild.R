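#' Weighted undirected brain graph
#'
#' Wraps a symmetric non-negative weighted adjacency matrix (0 = absent edge,
#' zero diagonal) with ROI node names and the size of the original
#' parcellation, which is kept for normalization bookkeeping across the
#' nodal-elimination steps.
#'
#' @param adjacency Symmetric numeric matrix with zero diagonal, weights in
#'   `[0, 1]` for NMI graphs (non-negativity is enforced; the unit upper
#'   bound is not, so unit-weight toy graphs are allowed).
#' @param node_names Node labels; default from dimnames or `ROI<i>`.
#' @param n_original Node count of the pre-elimination parcellation; defaults
#'   to the current node count.
#' @return An object of class `brain_graph`.
#' @export
brain_graph <- function(adjacency, node_names = NULL, n_original = NULL) {
  adjacency <- as.matrix(adjacency)
  check_adjacency(adjacency)
  if (is.null(node_names)) {
    node_names <- rownames(adjacency)
    if (is.null(node_names)) node_names <- default_roi_names(nrow(adjacency))
  }
  node_names <- as.character(node_names)
  if (length(node_names) != nrow(adjacency) || anyDuplicated(node_names))
    stop("`node_names` must be unique, one per node", call. = FALSE)
  dimnames(adjacency) <- list(node_names, node_names)
  if (is.null(n_original)) n_original <- nrow(adjacency)
  structure(list(adjacency = adjacency, node_names = node_names,
                 n_original = as.integer(n_original)),
            class = "brain_graph")
}

#' @export
print.brain_graph <- function(x, ...) {
  n <- length(x$node_names)
  cat(sprintf("Brain graph: %d nodes (of %d original), %d edges, density %.3f\n",
              n, x$n_original, n_edges(x),
              if (n >= 2) graph_density(x) else NA_real_))
  invisible(x)
}

n_edges <- function(g) sum(g$adjacency[upper.tri(g$adjacency)] > 0)

#' Edge density of a graph
#'
#' Number of present (nonzero-weight) edges divided by the number of possible
#' edges `N(N-1)/2`.
#'
#' @param g A [brain_graph()].
#' @return Fraction in `[0, 1]`.
#' @export
graph_density <- function(g) {
  stopifnot(inherits(g, "brain_graph"))
  n <- length(g$node_names)
  if (n < 2) stop("density needs at least 2 nodes", call. = FALSE)
  n_edges(g) / (n * (n - 1) / 2)
}

#' Threshold a graph to a target edge density
#'
#' Iteratively removes (sets to zero) the weakest edges until the density is
#' at most the target: exactly `floor(target * N(N-1)/2)` strongest edges are
#' retained (all edges if the graph is already at or below the target).
#' Weight ties are broken deterministically: among equal weights, edges with
#' lexicographically smaller (i, j) node-index pairs are removed first.
#'
#' @param g A [brain_graph()].
#' @param target Target density in `(0, 1]`; default 0.5.
#' @return A thresholded [brain_graph()] with the same node set.
#' @export
threshold_to_density <- function(g, target = 0.5) {
  stopifnot(inherits(g, "brain_graph"))
  if (target <= 0 || target > 1)
    stop("`target` must be in (0, 1]", call. = FALSE)
  w <- g$adjacency
  n <- nrow(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  wt <- w[upper.tri(w)]
  present <- wt > 0
  k_target <- floor(target * n * (n - 1) / 2)
  if (sum(present) <= k_target) return(g)
  # removal order: ascending weight, ties by ascending (i, j)
  ord <- order(wt, ut[, 1L], ut[, 2L])
  ord <- ord[present[ord]]
  drop <- ord[seq_len(sum(present) - k_target)]
  w[cbind(ut[drop, 1L], ut[drop, 2L])] <- 0
  w[cbind(ut[drop, 2L], ut[drop, 1L])] <- 0
  brain_graph(w, node_names = g$node_names, n_original = g$n_original)
}

#' Remove sparsely connected nodes
#'
#' Single-pass nodal elimination: removes nodes whose degree is strictly
#' below `min_frac` of the possible connections `(N - 1)` (with `N` the node
#' count at entry), then drops any node left with no edges at all. Intended
#' to run after [threshold_to_density()], pruning nodes so weakly connected
#' that they are likely noise artifacts.
#'
#' @param g A thresholded [brain_graph()].
#' @param min_frac Minimum fraction of possible connections; default 0.05.
#' @return A [brain_graph()] restricted to the surviving nodes
#'   (`n_original` is preserved).
#' @export
eliminate_sparse_nodes <- function(g, min_frac = 0.05) {
  stopifnot(inherits(g, "brain_graph"))
  if (min_frac < 0 || min_frac > 1)
    stop("`min_frac` must be in [0, 1]", call. = FALSE)
  w <- g$adjacency
  n <- nrow(w)
  deg <- colSums(w > 0)
  keep <- deg >= min_frac * (n - 1)
  w2 <- w[keep, keep, drop = FALSE]
  # final sweep: nodes disconnected by the removal above
  connected <- colSums(w2 > 0) > 0
  w2 <- w2[connected, connected, drop = FALSE]
  brain_graph(w2, n_original = g$n_original)
}

#' Restrict graphs to their common node set
#'
#' Reduces every graph in the list to the intersection of all node-name sets
#' (the nodes present in all subjects of a group), in a consistent order
#' (that of the first graph).
#'
#' @param graphs Non-empty list of [brain_graph()] objects.
#' @return List of graphs over the identical, ordered common node set.
#' @export
reduce_to_common_nodes <- function(graphs) {
  if (!length(graphs)) stop("need at least one graph", call. = FALSE)
  stopifnot(all(vapply(graphs, inherits, TRUE, "brain_graph")))
  common <- Reduce(intersect, lapply(graphs, `[[`, "node_names"))
  if (!length(common))
    stop("node-name intersection across graphs is empty", call. = FALSE)
  common <- graphs[[1L]]$node_names[graphs[[1L]]$node_names %in% common]
  lapply(graphs, function(g)
    brain_graph(g$adjacency[common, common, drop = FALSE],
                n_original = g$n_original))
}

#' Group-averaged network
#'
#' Averages the (thresholded) adjacency matrices of subjects sharing a node
#' set — absent edges enter the mean as zeros — and re-thresholds the
#' averaged network to the target density. This is the per-group network the
#' downstream metric, community and hub analyses operate on.
#'
#' @param graphs List of [brain_graph()] objects over an identical node set
#'   (apply [reduce_to_common_nodes()] first).
#' @param target Density of the averaged network; default 0.5.
#' @return A [brain_graph()]; its `n_original` is taken from the first graph.
#' @export
group_average_network <- function(graphs, target = 0.5) {
  if (!length(graphs)) stop("need at least one graph", call. = FALSE)
  stopifnot(all(vapply(graphs, inherits, TRUE, "brain_graph")))
  names0 <- graphs[[1L]]$node_names
  for (g in graphs)
    if (!identical(g$node_names, names0))
      stop("graphs must share an identical node set; run reduce_to_common_nodes()",
           call. = FALSE)
  avg <- Reduce(`+`, lapply(graphs, `[[`, "adjacency")) / length(graphs)
  threshold_to_density(
    brain_graph(avg, node_names = names0, n_original = graphs[[1L]]$n_original),
    target = target)
}
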
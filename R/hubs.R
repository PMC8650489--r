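# Participation coefficients and the four-way hub taxonomy:
# connector hub / provincial hub / high-influence node / other.

#' Participation coefficients
#'
#' Degree-based participation coefficient of every node with respect to a
#' modular partition: `pc_i = 1 - sum_m (k_im / k_i)^2`, where `k_im` counts
#' the edges from node `i` into module `m`. It is 0 when all of a node's
#' edges stay in one module and approaches its maximum `1 - 1/M` when the
#' edges are spread evenly over the `M` modules. Nodes with no edges get 0.
#'
#' @param g A [brain_graph()].
#' @param partition A [modular_partition()] or affiliation vector over the
#'   nodes of `g`.
#' @return Named numeric vector of `pc_i` in `[0, 1 - 1/M]`.
#' @export
participation_coefficients <- function(g, partition) {
  stopifnot(inherits(g, "brain_graph"))
  aff <- as_affiliation(partition, g)
  a <- g$adjacency > 0
  k <- colSums(a)
  # k_im: edges from i into module m, via indicator aggregation
  kim <- rowsum(a + 0, aff)                 # M x N: column i = counts per module
  pc <- numeric(length(k))
  ok <- k > 0
  pc[ok] <- 1 - colSums((kim[, ok, drop = FALSE] /
                           rep(k[ok], each = nrow(kim)))^2)
  setNames(pc, g$node_names)
}

#' Classify nodes into the hub taxonomy
#'
#' Applies three rules on one network and its modular partition:
#' \itemize{
#'   \item \strong{hub}: degree and strength both at least one sample
#'     standard deviation above the network's mean (when a metric's SD is 0
#'     the comparison degenerates to strictly above the mean, so fully
#'     regular networks have no hubs);
#'   \item \strong{connector} hub: a hub whose participation coefficient
#'     reaches at least 90\% of the network's theoretical maximum
#'     `1 - 1/M`; all remaining hubs are \strong{provincial} (with `M = 1`
#'     the maximum is degenerate at 0 and every hub is provincial, flagged);
#'   \item \strong{high-influence}: a non-hub ranking in the top 30\% for
#'     both degree and strength (minimum-rank ties; if ties push the
#'     candidate set over `ceiling(0.3 N)` it is truncated in node order).
#' }
#'
#' @param g A [brain_graph()] with at least 3 nodes.
#' @param partition A [modular_partition()] or affiliation vector.
#' @return A data frame of class `hub_table`: `node`, `module`,
#'   `degree_norm`, `strength_norm`, `pc`, `hub_class` (factor with levels
#'   connector, provincial, high_influence, other). Attribute
#'   `degenerate_single_module` flags the `M = 1` case.
#' @export
classify_nodes <- function(g, partition) {
  stopifnot(inherits(g, "brain_graph"))
  n <- nrow(g$adjacency)
  if (n < 3) stop("hub classification needs at least 3 nodes", call. = FALSE)
  aff <- as_affiliation(partition, g)
  m_mod <- length(unique(aff))
  deg <- nodal_degree(g)
  str <- nodal_strength(g)
  pc <- participation_coefficients(g, aff)

  above_thr <- function(x) {
    s <- stats::sd(x)
    if (s > 0) x >= mean(x) + s else x > mean(x)
  }
  hub <- above_thr(deg) & above_thr(str)

  cap <- ceiling(0.3 * n)
  rk_d <- rank(-deg, ties.method = "min")
  rk_s <- rank(-str, ties.method = "min")
  cand <- which(rk_d <= cap & rk_s <= cap)
  if (length(cand) > cap) cand <- cand[seq_len(cap)]   # tie overflow: node order
  high <- rep(FALSE, n)
  high[cand] <- TRUE
  high <- high & !hub

  pc_max <- 1 - 1 / m_mod
  connector <- if (m_mod > 1) hub & (pc >= 0.9 * pc_max) else rep(FALSE, n)
  cls <- rep("other", n)
  cls[high] <- "high_influence"
  cls[hub] <- "provincial"
  cls[connector] <- "connector"

  out <- data.frame(
    node = g$node_names, module = aff,
    degree_norm = unname(deg), strength_norm = unname(str), pc = unname(pc),
    hub_class = factor(cls, levels = c("connector", "provincial",
                                       "high_influence", "other")),
    stringsAsFactors = FALSE)
  class(out) <- c("hub_table", "data.frame")
  attr(out, "degenerate_single_module") <- m_mod == 1
  out
}

#' Compare hub sets of two networks
#'
#' Tabulates, per hub class, the nodes shared between two hub tables and the
#' nodes gained or lost from the first network to the second (restricted to
#' nodes classed connector, provincial or high_influence).
#'
#' @param a,b [classify_nodes()] tables.
#' @return List with per-class `shared`, `only_a`, `only_b` node-name sets
#'   and the class count tables of both networks.
#' @export
compare_hub_tables <- function(a, b) {
  stopifnot(inherits(a, "hub_table"), inherits(b, "hub_table"))
  classes <- c("connector", "provincial", "high_influence")
  per_class <- lapply(classes, function(cl) {
    na <- a$node[a$hub_class == cl]
    nb <- b$node[b$hub_class == cl]
    list(shared = intersect(na, nb),
         only_a = setdiff(na, nb), only_b = setdiff(nb, na))
  })
  names(per_class) <- classes
  list(per_class = per_class,
       counts_a = table(a$hub_class), counts_b = table(b$hub_class))
}
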
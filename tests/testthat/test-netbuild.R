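test_that("graph density counts present edges over possible edges", {
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  expect_equal(graph_density(brain_graph(k4)), 1)
  expect_equal(graph_density(brain_graph(matrix(0, 4, 4))), 0)
  w5 <- edges_to_adj(5, cbind(c(1, 1, 2, 3, 4), c(2, 3, 3, 4, 5), 0.5))
  expect_equal(graph_density(brain_graph(w5)), 5 / 10)
})

test_that("density thresholding keeps exactly the strongest edges", {
  # 4 nodes, 6 distinct weights, target 0.5 -> keep floor(3) largest
  w <- edges_to_adj(4, cbind(c(1, 1, 1, 2, 2, 3), c(2, 3, 4, 3, 4, 4),
                             c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)))
  g <- threshold_to_density(brain_graph(w), 0.5)
  kept <- sort(g$adjacency[upper.tri(g$adjacency)][
    g$adjacency[upper.tri(g$adjacency)] > 0])
  expect_equal(kept, c(0.4, 0.5, 0.6))

  # dense 212-node matrix -> floor(0.5 * 22366) edges, density 50%
  big <- brain_graph(rand_sym(212, seed = 1))
  thr <- threshold_to_density(big, 0.5)
  expect_equal(sum(thr$adjacency[upper.tri(thr$adjacency)] > 0), 11183)
  expect_equal(graph_density(thr), 11183 / 22366)

  # graphs at or below target are untouched
  sparse <- threshold_to_density(big, 0.3)
  expect_identical(threshold_to_density(sparse, 0.5), sparse)
  # idempotence
  expect_identical(threshold_to_density(thr, 0.5), thr)
})

test_that("retained set matches a full-sort oracle and ties break lexicographically", {
  for (seed in 1:5) {
    w <- rand_sym(10, seed = seed)
    g <- threshold_to_density(brain_graph(w), 0.4)
    k <- floor(0.4 * 45)
    cut <- sort(w[upper.tri(w)], decreasing = TRUE)[k]
    expect_equal(sum(g$adjacency[upper.tri(w)] > 0), k)
    expect_true(all(g$adjacency[g$adjacency > 0] >= cut))
  }
  # all-equal weights: removal order is ascending (i, j), so the retained
  # edges are the lexicographically largest pairs
  w <- matrix(0.5, 4, 4); diag(w) <- 0
  g <- threshold_to_density(brain_graph(w), 0.5)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  kept <- ut[g$adjacency[upper.tri(w)] > 0, , drop = FALSE]
  kept <- kept[order(kept[, 1], kept[, 2]), ]
  expect_equal(unname(kept), rbind(c(2, 3), c(2, 4), c(3, 4)))
})

test_that("sparse-node elimination applies the 5% rule then drops isolates", {
  # star K1,19: leaves have degree 1 of 19 possible (5.3% >= 5%) -> all kept
  star <- edges_to_adj(20, cbind(1, 2:20, 1))
  g <- eliminate_sparse_nodes(brain_graph(star), 0.05)
  expect_length(g$node_names, 20)
  expect_equal(g$n_original, 20)

  # an isolated node is removed even with min_frac = 0
  w <- edges_to_adj(4, cbind(c(1, 1), c(2, 3), 1))
  g0 <- eliminate_sparse_nodes(brain_graph(w), 0)
  expect_equal(length(g0$node_names), 3)
  expect_equal(g0$n_original, 4)

  # strict inequality: degree exactly at the cut survives
  # 21 nodes: leaf degree 1, 5% of 20 possible = 1 -> kept (1 >= 1)
  star21 <- edges_to_adj(21, cbind(1, 2:21, 1))
  expect_length(eliminate_sparse_nodes(brain_graph(star21), 0.05)$node_names, 21)

  # re-running on its own output removes nothing more (no cascade here)
  for (seed in 1:20) {
    w <- rand_sym(15, seed = seed, density = 0.25)
    g1 <- eliminate_sparse_nodes(brain_graph(w), 0.2)
    g2 <- eliminate_sparse_nodes(g1, 0.2)
    expect_true(all(colSums(g2$adjacency > 0) > 0))
    expect_lte(length(g2$node_names), length(g1$node_names))
  }
})

test_that("common-node reduction intersects node-name sets", {
  w3 <- rand_sym(3, 1) + 0.1; diag(w3) <- 0
  ga <- brain_graph(w3, node_names = c("A", "B", "C"))
  gb <- brain_graph(w3, node_names = c("B", "C", "D"))
  red <- reduce_to_common_nodes(list(ga, gb))
  expect_equal(red[[1]]$node_names, c("B", "C"))
  expect_equal(red[[2]]$node_names, c("B", "C"))

  same <- reduce_to_common_nodes(list(ga, ga))
  expect_identical(same[[1]]$adjacency, ga$adjacency)

  # staggered eliminations: intersection equals the set oracle
  specs <- lapply(1:3, function(s) {
    g <- brain_graph(rand_sym(12, seed = s, density = 0.3))
    eliminate_sparse_nodes(g, 0.2)
  })
  red <- reduce_to_common_nodes(specs)
  expected <- Reduce(intersect, lapply(specs, function(g) g$node_names))
  expect_true(all(vapply(red, function(g)
    identical(sort(g$node_names), sort(expected)), TRUE)))
})

test_that("group averaging means thresholded weights then re-thresholds", {
  # disjoint supports with equal weights: averaged weights halve, then cut
  wa <- edges_to_adj(4, cbind(c(1, 1), c(2, 3), 0.8))
  wb <- edges_to_adj(4, cbind(c(2, 3), c(4, 4), 0.6))
  avg <- group_average_network(list(brain_graph(wa), brain_graph(wb)), 0.5)
  # means: 0.4 on (1,2),(1,3) and 0.3 on (2,4),(3,4); keep floor(3) largest
  expect_equal(avg$adjacency[1, 2], 0.4)
  expect_equal(avg$adjacency[1, 3], 0.4)
  expect_equal(sum(avg$adjacency[upper.tri(avg$adjacency)] > 0), 3)

  # single graph already at target passes through unchanged
  g <- threshold_to_density(brain_graph(rand_sym(8, 3)), 0.5)
  expect_equal(group_average_network(list(g), 0.5)$adjacency, g$adjacency)

  expect_error(group_average_network(list(
    brain_graph(wa, node_names = letters[1:4]),
    brain_graph(wb, node_names = letters[2:5]))), "identical node set")
})
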
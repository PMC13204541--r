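test_that("metric hand values on canonical small graphs", {
  tri <- unit_triangle()
  expect_equal(net_density(unit_complete(5)), 1)
  expect_equal(net_density(matrix(0, 4, 4)), 0)
  w4 <- matrix(0, 4, 4)
  w4[1, 2] <- w4[2, 1] <- w4[2, 3] <- w4[3, 2] <- w4[3, 4] <- w4[4, 3] <- 1
  expect_equal(net_density(w4), 0.5)  # 3 of 6 possible edges

  cl <- net_clustering(tri)
  expect_equal(cl$per_node, rep(1, 3))
  expect_equal(cl$mean, 1)
  expect_equal(net_clustering(unit_path3())$per_node[2], 0)
  # weighted triangle: every node sees one triangle of intensity (w123)^(1/3)
  wt <- tri
  wt[2, 3] <- wt[3, 2] <- 0.125
  expect_equal(net_clustering(wt)$per_node, rep(0.5, 3))

  expect_equal(net_transitivity(tri), 1)
  # a star has connected-neighbor pairs at the hub but no triangles: ratio 0
  expect_equal(net_transitivity(unit_star(5)), 0)
  # only a graph with no node of degree >= 2 hits the 0/0 case
  two_edges0 <- matrix(0, 4, 4)
  two_edges0[1, 2] <- two_edges0[2, 1] <- two_edges0[3, 4] <- two_edges0[4, 3] <- 1
  expect_true(is.na(net_transitivity(two_edges0)))

  expect_equal(net_path_length(unit_complete(4)), 1)
  expect_equal(net_path_length(unit_path3()), 4 / 3)
  # halving all weights doubles every shortest path
  set.seed(5)
  w <- random_weight_matrix(7, 0.6)
  expect_equal(suppressWarnings(net_path_length(w / 2)),
               2 * suppressWarnings(net_path_length(w)))

  expect_equal(net_global_efficiency(unit_complete(4)), 1)
  expect_equal(net_global_efficiency(unit_path3()), 5 / 6)
  expect_equal(net_global_efficiency(matrix(0, 4, 4)), 0)

  expect_equal(net_local_efficiency(unit_complete(4))$per_node, rep(1, 4))
  expect_equal(net_local_efficiency(unit_star(5))$mean, 0)

  expect_equal(net_assortativity(unit_star(5)), -1)
  expect_true(is.na(net_assortativity(unit_complete(4))))
  two_edges <- matrix(0, 4, 4)
  two_edges[1, 2] <- two_edges[2, 1] <- two_edges[3, 4] <- two_edges[4, 3] <- 1
  expect_true(is.na(net_assortativity(two_edges)))

  expect_equal(net_rich_club(unit_complete(5), 2), 1)
  expect_true(is.na(net_rich_club(unit_star(5), 1)))  # only the hub survives
})

test_that("structural impossibilities raise errors, undefined values are NA", {
  expect_error(net_density(matrix(0, 1, 1)), "2 nodes")
  expect_error(net_path_length(matrix(0, 4, 4)), "no connected")
  expect_error(net_assortativity(matrix(0, 3, 3)), "2 edges")
  expect_error(small_worldness(matrix(0, 4, 4)), "empty graph")
  pairs_only <- matrix(0, 4, 4)
  pairs_only[1, 2] <- pairs_only[2, 1] <- pairs_only[3, 4] <- pairs_only[4, 3] <- 1
  res <- network_metrics(pairs_only)
  expect_true(is.na(res$transitivity))
  expect_true(is.na(res$assortativity))
  expect_true(is.finite(res$density))
})

test_that("every metric matches its brute-force oracle on random small graphs", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    w <- random_weight_matrix(n, runif(1, 0.3, 0.9))
    if (sum(w) == 0) next
    expect_equal(net_clustering(w)$per_node, bf_clustering(w),
                 tolerance = 1e-9)
    expect_equal(net_transitivity(w), bf_transitivity(w), tolerance = 1e-9)
    if (any(w > 0)) {
      expect_equal(suppressWarnings(net_path_length(w)), bf_path_length(w),
                   tolerance = 1e-9)
    }
    expect_equal(net_global_efficiency(w), bf_global_efficiency(w),
                 tolerance = 1e-9)
    expect_equal(net_local_efficiency(w)$per_node, bf_local_efficiency(w),
                 tolerance = 1e-9)
    if (sum(w[upper.tri(w)] > 0) >= 2) {
      expect_equal(net_assortativity(w), bf_assortativity(w),
                   tolerance = 1e-9)
    }
    for (k in 0:(n - 1)) {
      expect_equal(net_rich_club(w, k), bf_rich_club(w, k), tolerance = 1e-9)
    }
  }
})

test_that("shortest-path distances agree with an independent graph library", {
  skip_if_not_installed("igraph")
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    w <- random_weight_matrix(n, 0.5)
    d1 <- hdbn:::.sp_distances(w)
    len <- ifelse(w > 0, 1 / w, 0)
    g <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    d2 <- igraph::distances(g)
    expect_equal(d1, d2, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("the metric suite is invariant to node relabeling", {
  set.seed(13)
  w <- random_weight_matrix(8, 0.6)
  perm <- sample(8)
  wp <- w[perm, perm]
  a <- network_metrics(w)
  b <- network_metrics(wp)
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("density and efficiency respond monotonically to edits", {
  set.seed(14)
  w <- random_weight_matrix(7, 0.4)
  off <- which(upper.tri(w) & w == 0)
  if (length(off) > 0) {
    w2 <- w
    w2[off[1]] <- 0.5
    w2 <- pmax(w2, t(w2))
    expect_gt(net_density(w2), net_density(w))
    expect_gte(net_global_efficiency(w2), net_global_efficiency(w))
  }
  on <- which(upper.tri(w) & w > 0 & w < 0.9)
  if (length(on) > 0) {
    w3 <- w
    w3[on[1]] <- w3[on[1]] + 0.05
    w3 <- pmax(w3, t(w3))
    expect_gte(net_global_efficiency(w3), net_global_efficiency(w))
  }
})

test_that("small-worldness: rigid complete graph gives sigma exactly 1", {
  sw <- small_worldness(unit_complete(8), n_null = 5, seed = 1)
  expect_equal(sw$sigma, 1)
  expect_equal(sw$c_ratio, 1)
  expect_equal(sw$l_ratio, 1)
})

test_that("small-worldness is reproducible and detects lattice structure", {
  g <- ring_lattice_graph(36, 4, 0.1, seed = 7)
  a <- small_worldness(g, n_null = 20, swaps_per_edge = 10, seed = 3)
  b <- small_worldness(g, n_null = 20, swaps_per_edge = 10, seed = 3)
  expect_identical(a, b)
  expect_gt(a$sigma, 1)
  # rewired surrogates preserve the degree sequence
  w <- g$weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  set.seed(9)
  e <- hdbn:::.ms_rewire(idx, 36, 10 * nrow(idx))
  wb <- matrix(0, 36, 36)
  wb[e] <- 1
  wb <- pmax(wb, t(wb))
  expect_equal(rowSums(wb > 0), rowSums(w > 0), ignore_attr = TRUE)
})

test_that("density-matched random graphs are their own null: mean sigma near 1", {
  # a single sparse instance has few triangles and a noisy sigma, so the
  # self-null check averages over independent random graphs
  set.seed(21)
  sig <- vapply(1:12, function(i) {
    repeat {
      w <- random_weight_matrix(30, 0.2, unit = TRUE)
      if (all(rowSums(w) > 0)) break
    }
    small_worldness(w, n_null = 20, seed = i)$sigma
  }, numeric(1))
  expect_gt(mean(sig), 0.8)
  expect_lt(mean(sig), 1.2)
})

test_that("ring lattice generator yields the requested lattice", {
  g <- ring_lattice_graph(10, 4, 0, seed = 1)
  expect_equal(rowSums(g$weights > 0), rep(4, 10), ignore_attr = TRUE)
  expect_error(ring_lattice_graph(10, 3, 0.1), "even")
})
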
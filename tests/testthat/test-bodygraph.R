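test_that("graph construction correlates rows, keeps positives, thresholds", {
  set.seed(3)
  mu <- matrix(runif(18 * 18), 18)
  mu[2, ] <- mu[1, ] + 1e-3 * rnorm(18)       # near-identical rows
  mu[4, ] <- -mu[3, ] + mean(mu[3, ]) * 2     # anticorrelated with row 3
  g <- body_graph(mu, drop_fraction = 0)
  expect_gt(g$w[1, 2], 0.99)
  expect_equal(g$w[3, 4], 0)                  # negative correlation removed
  expect_true(isSymmetric(g$w))
  expect_true(all(diag(g$w) == 0))
  # thresholding removes floor(drop_fraction * m) lowest positive edges
  m <- sum(g$w[upper.tri(g$w)] > 0)
  g5 <- body_graph(mu, drop_fraction = 0.05)
  m5 <- sum(g5$w[upper.tri(g5$w)] > 0)
  expect_equal(m - m5, floor(0.05 * m))
  expect_equal(g5$threshold$n_removed, floor(0.05 * m))
  # constant rows are an error naming the row
  mu_bad <- mu; mu_bad[7, ] <- 0.5
  expect_error(body_graph(mu_bad), "7")
})

test_that("hand-worked graph metric examples", {
  # triangle with all weights 0.8: t = 0.8, C = 0.8
  tri <- matrix(0.8, 3, 3); diag(tri) <- 0
  expect_equal(unname(clustering_coefficient(tri)), rep(0.8, 3))
  # unit triangle is a perfect clique
  tri1 <- matrix(1, 3, 3); diag(tri1) <- 0
  expect_equal(unname(clustering_coefficient(tri1)), rep(1, 3))
  # degree sums incident weights
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.5; w[1, 3] <- w[3, 1] <- 0.3
  expect_equal(weighted_degree(w, 1), 0.8)
  expect_equal(weighted_degree(w, 2), 0.5)
  # middle of a path: no triangle, betweenness 0.5
  expect_equal(clustering_coefficient(w, 1), 0)
  expect_equal(betweenness_centrality(w, 1), 0.5)
  expect_equal(betweenness_centrality(w, 2), 0)
  # star of 4: center betweenness 3/(3*2) = 0.5
  s <- matrix(0, 4, 4); s[1, 2:4] <- s[2:4, 1] <- 0.6
  expect_equal(betweenness_centrality(s, 1), 0.5)
  # uniform complete graph: betweenness 0 everywhere
  K <- matrix(0.7, 5, 5); diag(K) <- 0
  expect_equal(unname(betweenness_centrality(K)), rep(0, 5))
  # single edge of weight 0.5 has length 2
  e <- matrix(0, 2, 2); e[1, 2] <- e[2, 1] <- 0.5
  expect_equal(shortest_paths_weighted(e)$lengths[1, 2], 2)
  # triangle: direct edge beats the detour
  expect_equal(shortest_paths_weighted(tri)$lengths[1, 2], 1 / 0.8)
  # path lengths: end node of a 3-node path with unit weights
  pw <- matrix(0, 3, 3); pw[1, 2] <- pw[2, 1] <- 1; pw[2, 3] <- pw[3, 2] <- 1
  expect_equal(characteristic_path_length(pw, 1), 1.5)
  expect_equal(characteristic_path_length(pw, 2), 1)
  # complete unit graph: L = 1
  K1 <- matrix(1, 4, 4); diag(K1) <- 0
  expect_equal(unname(characteristic_path_length(K1)), rep(1, 4))
  # isolated node: zero degree, infinite path length flagged
  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 1
  expect_equal(weighted_degree(iso, 3), 0)
  expect_warning(L <- characteristic_path_length(iso), "reach")
  expect_true(is.infinite(L[3]))
})

test_that("tied shortest paths are counted", {
  # square with equal weights: two shortest paths between opposite corners
  sq <- matrix(0, 4, 4)
  sq[1, 2] <- sq[2, 1] <- sq[2, 3] <- sq[3, 2] <- 1
  sq[3, 4] <- sq[4, 3] <- sq[4, 1] <- sq[1, 4] <- 1
  sp <- shortest_paths_weighted(sq)
  expect_equal(sp$lengths[1, 3], 2)
  expect_equal(sp$counts[1, 3], 2)
  # each node carries half of one opposite-corner pair: (1/2) / ((n-1)(n-2))
  expect_equal(unname(betweenness_centrality(sq)), rep(0.5 / 6, 4))
})

test_that("metrics match brute-force enumeration on random small graphs", {
  for (k in 1:25) {
    n <- 3 + (k %% 4)
    w <- random_connected_graph(n, seed = 100 + k)
    expect_equal(unname(weighted_degree(w)), reference_degree(w),
                 tolerance = 1e-12)
    expect_equal(unname(clustering_coefficient(w)), reference_clustering(w),
                 tolerance = 1e-12)
    sp <- shortest_paths_weighted(w)
    ref <- reference_shortest_paths(w)
    expect_equal(sp$lengths, ref$lengths, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(sp$counts, ref$counts, ignore_attr = TRUE)
    expect_equal(unname(betweenness_centrality(w)), reference_betweenness(w),
                 tolerance = 1e-9)
    expect_equal(unname(characteristic_path_length(w)),
                 reference_path_length(w), tolerance = 1e-9)
    # igraph cross-checks where conventions coincide
    ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                              weighted = TRUE)
    expect_equal(unname(weighted_degree(w)),
                 unname(igraph::strength(ig)), tolerance = 1e-12)
    expect_equal(
      unname(betweenness_centrality(w)),
      unname(igraph::betweenness(ig, weights = 1 / igraph::E(ig)$weight)) /
        ((n - 1) * (n - 2)), tolerance = 1e-9)
  }
})

test_that("metrics are permutation equivariant", {
  w <- random_connected_graph(6, seed = 77)
  set.seed(78)
  perm <- sample(6)
  wp <- w[perm, perm]
  expect_equal(unname(weighted_degree(wp)),
               unname(weighted_degree(w))[perm])
  expect_equal(unname(clustering_coefficient(wp)),
               unname(clustering_coefficient(w))[perm])
  expect_equal(unname(betweenness_centrality(wp)),
               unname(betweenness_centrality(w))[perm], tolerance = 1e-12)
  expect_equal(unname(characteristic_path_length(wp)),
               unname(characteristic_path_length(w))[perm],
               tolerance = 1e-12)
})

test_that("thresholding never increases weighted degree", {
  set.seed(5)
  mu <- matrix(runif(18 * 18), 18) + diag(18)
  fracs <- c(0, 0.05, 0.1, 0.2, 0.4)
  degs <- sapply(fracs, function(f)
    suppressWarnings(weighted_degree(body_graph(mu, drop_fraction = f))))
  for (j in seq_len(ncol(degs) - 1))
    expect_true(all(degs[, j + 1] <= degs[, j] + 1e-12))
})

test_that("Louvain separates weakly joined cliques and reports exact Q", {
  w <- two_clique_graph(bridge = 0.1)
  mods <- louvain_modules(w, seed = 1, restarts = 10)
  expect_length(unique(mods$membership), 2L)
  expect_equal(length(unique(mods$membership[1:3])), 1L)
  expect_equal(length(unique(mods$membership[4:6])), 1L)
  # reported Q equals an independent direct evaluation of the formula
  expect_equal(mods$q, reference_modularity(w, mods$membership),
               tolerance = 1e-12)
  # and matches the exhaustive best partition on 6 nodes
  best <- reference_best_partition(w)
  expect_equal(mods$q, best$q, tolerance = 1e-12)
  # uniform complete graph has no community structure
  K <- matrix(0.5, 6, 6); diag(K) <- 0
  expect_lte(reference_best_partition(K)$q, 1e-9)
  # determinism: fixed seed and restarts give identical partitions
  expect_identical(louvain_modules(w, seed = 3, restarts = 5),
                   louvain_modules(w, seed = 3, restarts = 5))
})

test_that("modularity agrees with igraph's weighted modularity", {
  for (k in 1:5) {
    w <- random_connected_graph(6, seed = 300 + k)
    set.seed(k)
    m <- sample(1:3, 6, replace = TRUE)
    ig <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                              weighted = TRUE)
    expect_equal(modularity_q(w, m),
                 igraph::modularity(ig, m, weights = igraph::E(ig)$weight),
                 tolerance = 1e-12)
  }
})

test_that("graph_metrics assembles all node metrics", {
  w <- two_clique_graph()
  gm <- graph_metrics(w, seed = 2)
  expect_equal(nrow(gm), 6L)
  expect_named(gm, c("part", "degree", "clustering", "betweenness",
                     "path_length", "module"))
  expect_true(all(gm$betweenness >= 0 & gm$betweenness <= 1))
  expect_equal(attr(gm, "q"), reference_best_partition(w)$q,
               tolerance = 1e-12)
})
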
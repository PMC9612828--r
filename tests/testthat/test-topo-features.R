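test_that("node weight sums incident edge weights", {
  star <- make_fixture_graph("star", size = 4, omega = 0.5)
  w <- node_weight(star$graph)
  expect_equal(unname(w["G01"]), 1.5)          # hub
  expect_equal(unname(w["G02"]), 0.5)          # leaf
  g_iso <- igraph::add_vertices(star$graph, 1, name = "ISO")
  expect_equal(unname(node_weight(g_iso)["ISO"]), 0)
})

test_that("closeness matches closed forms and excludes unreachable nodes", {
  cl <- make_fixture_graph("clique", size = 4, omega = 0.5)
  expect_equal(unname(closeness_centrality(cl$graph)), rep(2, 4))
  # path a-b (0.2), b-c (0.3): C(a) = 2 / (0.2 + 0.5)
  pa <- make_fixture_graph("path", size = 3, weights = c(0.2, 0.3))
  cc <- closeness_centrality(pa$graph)
  expect_equal(unname(cc["G01"]), 2 / 0.7)
  # singleton component scores 0
  g <- igraph::add_vertices(pa$graph, 1, name = "ZZ")
  expect_equal(unname(closeness_centrality(g)["ZZ"]), 0)
})

test_that("betweenness matches enumeration on canonical small graphs", {
  pa <- make_fixture_graph("path", size = 3, weights = c(0.2, 0.3))
  b <- betweenness_centrality(pa$graph)
  expect_equal(unname(b), c(0, 1, 0))
  # equal-weight triangle: direct edge always beats the two-hop route
  tri <- make_fixture_graph("clique", size = 3, omega = 0.5)
  expect_equal(unname(betweenness_centrality(tri$graph)), rep(0, 3))
  # 4-cycle with equal weights: two tied shortest paths between opposite
  # corners, each intermediate node gets 1/2
  W <- matrix(0, 4, 4)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))) {
    W[e[1], e[2]] <- W[e[2], e[1]] <- 0.5
  }
  g <- graph_from_W(W)
  expect_equal(unname(betweenness_centrality(g)), rep(0.5, 4))
  expect_equal(unname(betweenness_centrality(g)), oracle_betweenness(W))
})

test_that("closeness and betweenness equal brute-force oracles on random graphs", {
  for (seed in 1:8) {
    n <- 4 + (seed %% 4)
    W <- random_weighted_W(n, p = 0.5, seed = 100 + seed)
    g <- graph_from_W(W)
    expect_equal(unname(closeness_centrality(g)), oracle_closeness(W),
                 tolerance = 1e-12)
    expect_equal(unname(betweenness_centrality(g)), oracle_betweenness(W),
                 tolerance = 1e-9)
  }
})

test_that("the PageRank variant hits its fixed point", {
  # regular equal-weight graph: PR = 1 for every node
  cl <- make_fixture_graph("clique", size = 5, omega = 0.25)
  expect_equal(unname(pagerank_scores(cl$graph)), rep(1, 5), tolerance = 1e-8)
  # isolated node anchors at 1 - d
  g <- igraph::add_vertices(cl$graph, 1, name = "ISO")
  expect_equal(unname(pagerank_scores(g)["ISO"]), 0.15)
  # 3-node path with equal weights: dense linear solve agrees
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- W[2, 3] <- W[3, 2] <- 0.5
  gp <- graph_from_W(W)
  pr <- pagerank_scores(gp, tol = 1e-12)
  expect_equal(unname(pr), oracle_pagerank(W), tolerance = 1e-9)
  # residual of the fixed-point equation
  s <- colSums(W)
  M <- W; nz <- s > 0
  M[, nz] <- sweep(W[, nz, drop = FALSE], 2, s[nz], "/")
  M[, !nz] <- 0
  expect_lt(max(abs(pr - ((1 - 0.85) + 0.85 * M %*% pr))), 1e-9)
})

test_that("eigenvector centrality is the unit-norm Perron vector per component", {
  cl <- make_fixture_graph("clique", size = 4, omega = 0.7)
  ev <- eigenvector_scores(cl$graph)
  expect_equal(unname(ev), rep(1 / 2, 4), tolerance = 1e-9)
  # 3-node equal-weight path: proportional to (1, sqrt(2), 1)
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- W[2, 3] <- W[3, 2] <- 0.4
  g <- graph_from_W(W)
  ev3 <- eigenvector_scores(g)
  expect_equal(unname(ev3), c(1, sqrt(2), 1) / 2, tolerance = 1e-9)
  # isolated node scores 0; eigen-residual small on a random graph
  gi <- igraph::add_vertices(g, 1, name = "ISO")
  expect_equal(unname(eigenvector_scores(gi)["ISO"]), 0)
  W5 <- random_weighted_W(6, p = 0.6, seed = 5)
  g5 <- graph_from_W(W5)
  v <- eigenvector_scores(g5)
  comp <- igraph::components(g5)$membership
  for (k in unique(comp)) {
    idx <- which(comp == k)
    if (length(idx) < 2) next
    vk <- v[idx]
    lam <- as.numeric(t(vk) %*% W5[idx, idx] %*% vk)
    expect_lt(max(abs(W5[idx, idx] %*% vk - lam * vk)) / lam, 1e-8)
  }
})

test_that("graph entropy follows the strength distribution", {
  cl <- make_fixture_graph("clique", size = 6, omega = 0.5)
  expect_equal(graph_entropy(cl$graph), log(6))
  # one node holding all weight
  expect_equal(graph_entropy(c(a = 2.5, b = 0, c = 0)), 0)
  # star on 4 nodes, omega 0.5: pi = (1/2, 1/6, 1/6, 1/6)
  st <- make_fixture_graph("star", size = 4, omega = 0.5)
  p <- c(1 / 2, rep(1 / 6, 3))
  expect_equal(graph_entropy(st$graph), -sum(p * log(p)))
  expect_equal(graph_entropy(st$graph), st$expected$entropy)
})

test_that("entropy effect respects automorphisms and degenerate removals", {
  st <- make_fixture_graph("star", size = 4, omega = 0.5)
  eff <- entropy_effect(st$graph)
  leaves <- eff[-1]
  expect_true(max(leaves) - min(leaves) < 1e-12)     # automorphic leaves
  # removing the hub zeroes all remaining strengths: En drops to 0
  expect_equal(unname(eff["G01"]), graph_entropy(st$graph))
  gi <- igraph::add_vertices(st$graph, 1, name = "ISO")
  expect_equal(unname(entropy_effect(gi)["ISO"]), 0)
})

test_that("feature matrix has fixed column order and honest scaling", {
  W <- random_weighted_W(7, p = 0.5, seed = 9)
  g <- graph_from_W(W)
  X <- build_feature_matrix(g, scaling = "none")
  expect_equal(colnames(X), c("weight", "closeness", "betweenness",
                              "pagerank", "eigenvector", "entropy"))
  expect_true(all(is.finite(X)))
  expect_equal(unname(X[, "weight"]), unname(node_weight(g)))
  expect_equal(unname(X[, "entropy"]), unname(entropy_effect(g)))
  Xm <- build_feature_matrix(g, scaling = "minmax")
  nonconst <- apply(X, 2, function(x) diff(range(x)) > 0)
  expect_true(all(apply(Xm[, nonconst, drop = FALSE], 2, min) == 0))
  expect_true(all(apply(Xm[, nonconst, drop = FALSE], 2, max) == 1))
  expect_true(all(Xm >= 0 & Xm <= 1))
  expect_equal(attr(Xm, "scaling_applied"), "minmax")
})

test_that("all six features are invariant under node relabeling", {
  W <- random_weighted_W(6, p = 0.6, seed = 21)
  dimnames(W) <- list(LETTERS[1:6], LETTERS[1:6])
  perm <- c(3, 1, 6, 2, 5, 4)
  Wp <- W[perm, perm]
  X1 <- build_feature_matrix(graph_from_W(W), scaling = "none")
  X2 <- build_feature_matrix(graph_from_W(Wp), scaling = "none")
  expect_equal(X2[rownames(X1), ], X1[rownames(X1), ], tolerance = 1e-9)
})
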
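test_that("bio-graph edges come from the union of PPI and shared processes", {
  genes <- c("A", "B", "C", "D")
  ls <- c(A = 4, B = 3, C = 2, D = 1)
  ppi <- data.frame(gene_a = "A", gene_b = "B", stringsAsFactors = FALSE)
  class(ppi) <- c("interaction_table", "data.frame")
  ann <- structure(list(B = "GO:1", C = "GO:1"), class = "annotation_table")
  g <- build_bio_graph(genes, ls, ppi, ann)
  expect_true(igraph::are_adjacent(g, "A", "B"))   # PPI only
  expect_true(igraph::are_adjacent(g, "B", "C"))   # shared term only
  expect_false(igraph::are_adjacent(g, "A", "C"))  # neither
  expect_equal(igraph::degree(g)[["D"]], 0)        # isolated allowed
  expect_equal(igraph::V(g)$ls, unname(ls[igraph::V(g)$name]))
})

test_that("neighborhood returns exactly the outside nodes adjacent to S", {
  tri <- make_fixture_graph("clique", size = 3)
  g <- tri$graph
  igraph::V(g)$ls <- c(3, 2, 1)
  expect_equal(bio_neighborhood(g, "G01"), c("G02", "G03"))
  expect_equal(bio_neighborhood(g, igraph::V(g)$name), character(0))
  g2 <- igraph::add_vertices(g, 1, name = "LONER", ls = 0)
  expect_equal(bio_neighborhood(g2, "LONER"), character(0))
})

test_that("module density follows 2E / V(V-1)", {
  fix <- make_fixture_graph("planted_clique", size = 7, k_planted = 3)
  g <- fix$graph
  expect_equal(module_density(g, c("P01", "P02", "P03")), 1)  # triangle
  expect_equal(module_density(g, c("P03", "Q01", "Q02")), 2 / 3)  # path
  expect_equal(module_density(g, c("P01", "Q01")), 0)  # no edge
  expect_equal(module_density(g, "P01"), 0)            # singleton
})

test_that("expansion accepts uphill moves deterministically", {
  # seed's neighbors all have higher LS: every step is the accept branch
  W <- igraph::make_full_graph(4)
  igraph::V(W)$name <- c("S", "A", "B", "C")
  igraph::V(W)$ls <- c(1, 5, 4, 3)
  set.seed(1)
  m <- mg_expand(W, "S")
  expect_setequal(m$members, c("S", "A", "B", "C"))
  # uniform weights: the Metropolis probability is exp(0) = 1, so the
  # candidate is always accepted
  igraph::V(W)$ls <- rep(2, 4)
  set.seed(1)
  m2 <- mg_expand(W, "S")
  expect_setequal(m2$members, c("S", "A", "B", "C"))
})

test_that("a seed with no neighbors yields a singleton module", {
  g <- igraph::make_full_graph(3)
  igraph::V(g)$name <- c("A", "B", "C")
  g <- igraph::add_vertices(g, 1, name = "ISO")
  igraph::V(g)$ls <- c(3, 2, 1, 9)
  set.seed(1)
  m <- mg_expand(g, "ISO")
  expect_equal(m$members, "ISO")
  expect_equal(m$density, 0)
  expect_equal(m$mean_ls, 9)
})

test_that("module size is capped by the cooling schedule", {
  # 66 steps at the defaults: at most 67 genes even on a huge clique
  n <- 80
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- sprintf("G%02d", seq_len(n))
  igraph::V(g)$ls <- rep(1, n)
  set.seed(3)
  m <- mg_expand(g, "G01")
  expect_equal(length(m$members), 67)
})

test_that("identical seeds reproduce identical module lists", {
  fix <- make_fixture_graph("planted_clique", size = 9, k_planted = 4)
  p <- mg_params(max_modules = 3, rng_seed = 11)
  m1 <- find_modules(fix$graph, p)
  m2 <- find_modules(fix$graph, p)
  expect_identical(m1, m2)
})

test_that("modules are connected, dense in [0,1], and seeded fresh", {
  fix <- make_fixture_graph("planted_clique", size = 10, k_planted = 4)
  mods <- find_modules(fix$graph, mg_params(max_modules = 4, rng_seed = 2))
  ls <- stats::setNames(igraph::V(fix$graph)$ls, igraph::V(fix$graph)$name)
  seen <- character(0)
  for (m in mods) {
    sg <- igraph::induced_subgraph(fix$graph, m$members)
    expect_true(igraph::is_connected(sg))
    expect_true(m$density >= 0 && m$density <= 1)
    expect_equal(m$mean_ls, mean(ls[m$members]))
    expect_true(m$seed %in% m$members)
    expect_false(m$seed %in% seen)       # seeds never reused
    seen <- union(seen, m$members)
  }
  # output ordered by mean LS, descending
  mls <- vapply(mods, function(m) m$mean_ls, numeric(1))
  expect_true(all(diff(mls) <= 0))
})

test_that("two disjoint cliques seed two distinct modules", {
  fix <- make_fixture_graph("two_cliques", size = 4)
  mods <- find_modules(fix$graph, mg_params(max_modules = 2, rng_seed = 5))
  expect_equal(length(mods), 2L)
  in_a <- vapply(mods, function(m) all(m$members %in% fix$expected$clique_a),
                 logical(1))
  in_b <- vapply(mods, function(m) all(m$members %in% fix$expected$clique_b),
                 logical(1))
  expect_true(any(in_a) && any(in_b))
})

test_that("overlap is allowed: only seeds must be fresh", {
  # hub H dominates its neighbors; later seeds pull H into their own
  # modules deterministically (its weight exceeds any module mean)
  g <- igraph::make_graph(c("H", "A", "H", "B"), directed = FALSE)
  igraph::V(g)$ls <- c(H = 1000, A = 900, B = 10)[igraph::V(g)$name]
  mods <- find_modules(g, mg_params(max_modules = 3, rng_seed = 1))
  expect_gte(length(mods), 2L)
  n_with_hub <- sum(vapply(mods, function(m) "H" %in% m$members, logical(1)))
  expect_gte(n_with_hub, 2L)
})
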
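test_that("confusion counts partition the universe", {
  u <- sprintf("g%d", 1:20)
  cc <- confusion_counts(u, u, u)
  expect_equal(cc$tp, 20); expect_equal(cc$fp + cc$fn + cc$tn, 0)
  cc2 <- confusion_counts(u[1:5], c("x1", "x2"), u)
  expect_equal(cc2$tp, 0); expect_equal(cc2$fp, 5)
  cc3 <- confusion_counts(u[1:8], u[5:12], u)
  expect_equal(cc3$tp + cc3$tn + cc3$fp + cc3$fn, cc3$n_universe)
  expect_equal(cc3$tp + cc3$fn, 8)   # |benchmark n universe|
  expect_equal(cc3$tp + cc3$fp, 8)   # |predicted|
  expect_error(confusion_counts("zzz", u, u), "subset")
})

test_that("precision/recall/F match the standard formulas and bounds", {
  m <- precision_recall_f(list(tp = 187, fp = 22, fn = 178))
  expect_equal(round(m[["precision"]], 2), 0.89)
  expect_equal(round(m[["recall"]], 2), 0.51)
  for (seed in 1:10) {
    set.seed(seed)
    cnt <- list(tp = sample(0:50, 1) + 1, fp = sample(0:50, 1),
                fn = sample(0:50, 1))
    v <- precision_recall_f(cnt)
    expect_true(all(v >= 0 & v <= 1))
    mn <- min(v[["precision"]], v[["recall"]])
    mx <- max(v[["precision"]], v[["recall"]])
    if (mn + mx > 0) {
      expect_lte(v[["f"]], 2 * mn * mx / (mn + mx) + 1e-12)
    }
  }
  expect_warning(z <- precision_recall_f(list(tp = 0, fp = 0, fn = 3)),
                 "precision")
  expect_equal(unname(z), c(0, 0, 0))
})

test_that("EV is 0 for strictly dominating modules and reproducible", {
  fix <- make_fixture_graph("planted_clique", size = 12, k_planted = 5)
  g <- fix$graph
  planted <- driver_module(g, fix$expected$planted[1], fix$expected$planted)
  expect_equal(planted$density, 1)
  r1 <- ev_test(planted, g, n_samples = 500, rng_seed = 9)
  expect_equal(r1$ev, 0)      # nothing can strictly beat max LS and density 1
  expect_true(r1$significant)
  r2 <- ev_test(planted, g, n_samples = 500, rng_seed = 9)
  expect_identical(r1, r2)
  # uniform LS on a complete graph: strict exceedance is impossible
  gk <- igraph::make_full_graph(8)
  igraph::V(gk)$name <- sprintf("K%d", 1:8)
  igraph::V(gk)$ls <- rep(3, 8)
  mod <- driver_module(gk, "K1", c("K1", "K2", "K3"))
  expect_equal(ev_test(mod, gk, n_samples = 200, rng_seed = 1)$ev, 0)
})

test_that("EV separates planted modules from weak random subsets", {
  fix <- make_fixture_graph("planted_clique", size = 20, k_planted = 5)
  g <- fix$graph
  planted <- driver_module(g, fix$expected$planted[1], fix$expected$planted)
  ev_planted <- ev_test(planted, g, n_samples = 1000, rng_seed = 31)
  expect_lt(ev_planted$ev, 0.05)
  # a sparse low-LS background subset is beaten by most samples
  weak <- driver_module(g, "Q01", c("Q01", "Q03", "Q05", "Q07", "Q09"))
  ev_weak <- ev_test(weak, g, n_samples = 1000, rng_seed = 31)
  expect_gt(ev_weak$ev, 0.05)
})

test_that("hypergeometric pmf matches binomial-coefficient arithmetic", {
  e <- hypergeom_enrichment(N = 10, K = 5, n = 4, k = 4)
  expect_equal(e$pmf, choose(5, 4) * choose(5, 0) / choose(10, 4))
  expect_equal(e$pmf, 5 / 210)
  expect_equal(hypergeom_enrichment(10, 10, 4, 4)$pmf, 1)  # K = N, k = n
  expect_equal(hypergeom_enrichment(10, 5, 0, 0)$pmf, 1)   # empty module
  expect_gte(e$tail_p, e$pmf)
  # tail equals the explicit sum over the upper support
  ks <- 2:4
  expect_equal(hypergeom_enrichment(12, 6, 4, 2)$tail_p,
               sum(choose(6, ks) * choose(6, 4 - ks) / choose(12, 4)))
})

test_that("pmf sums to 1 over its support for random parameter triples", {
  set.seed(99)
  for (i in 1:25) {
    N <- sample(5:60, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    supp <- max(0, n + K - N):min(n, K)
    tot <- sum(vapply(supp, function(k)
      hypergeom_enrichment(N, K, n, k)$pmf, numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-12)
  }
})

test_that("module enrichment table covers every module-set pair", {
  fix <- make_fixture_graph("planted_clique", size = 8, k_planted = 3)
  mods <- find_modules(fix$graph, mg_params(max_modules = 2, rng_seed = 3))
  gs <- structure(list(
    SET1 = list(description = "d", genes = c("P01", "P02", "Q01")),
    SET2 = list(description = "d", genes = c("Q02", "Q03"))),
    class = "gene_set_collection")
  tab <- enrich_modules(mods, gs, igraph::V(fix$graph)$name)
  expect_equal(nrow(tab), 2L * length(mods))
  expect_true(all(tab$pmf >= 0 & tab$pmf <= 1))
  expect_true(all(tab$tail_p >= tab$pmf - 1e-12))
})

test_that("co-mutation case counts stratify by site and partition at 10%", {
  cat <- mutation_catalog(
    case_id = c("c1", "c1", "c2", "c3", "c3", "c4"),
    gene    = c("A",  "B",  "A",  "A",  "B",  "C"),
    site    = c(c1 = "Lung", c2 = "Lung", c3 = "Colon", c4 = "Colon"))
  res <- module_case_counts(cat, c("A", "B"), min_genes = 2)
  sc <- res$site_counts
  expect_equal(sc$n_co_mutated[sc$site == "Lung"], 1L)   # only c1 has both
  expect_equal(sc$n_co_mutated[sc$site == "Colon"], 1L)  # c3 has both
  gf <- res$gene_fractions
  expect_equal(gf$fraction[gf$site == "Lung" & gf$gene == "A"], 1)
  expect_true(all(gf$high[gf$fraction > 0.10]))
  # catalog without site labels falls back to one "all" stratum
  cat2 <- mutation_catalog(c("c1", "c1", "c2"), c("A", "B", "A"))
  res2 <- module_case_counts(cat2, c("A", "B"), min_genes = 2)
  expect_equal(res2$site_counts$site, "all")
  expect_equal(res2$site_counts$n_co_mutated, 1L)
  # a case mutated in one module gene only does not count at min_genes = 2
  expect_equal(module_case_counts(cat2, c("A", "C"),
                                  min_genes = 2)$site_counts$n_co_mutated, 0L)
})
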
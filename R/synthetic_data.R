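#' Parameters of the planted-driver simulation
#'
#' The simulated study design: a catalog of `n_related + n_unrelated`
#' genes and `n_cases` cases, where each (gene, case) pair is mutated by an
#' independent Bernoulli draw at the gene-class rate. The defaults emulate
#' the prostate-cancer simulation design: 20 related genes mutated in 40%
#' of cases, 80 unrelated genes at 20%, 200 cases.
#'
#' @param n_related number of planted driver ("related") genes.
#' @param n_unrelated number of background genes.
#' @param n_cases number of cases.
#' @param rate_related per-case mutation probability of related genes.
#' @param rate_unrelated per-case mutation probability of background genes.
#' @param rng_seed integer seed.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(n_related = 20, n_unrelated = 80, n_cases = 200,
                       rate_related = 0.40, rate_unrelated = 0.20,
                       rng_seed = 1L) {
  stopifnot(n_related >= 1, n_unrelated >= 0, n_cases >= 1,
            rate_related >= 0, rate_related <= 1,
            rate_unrelated >= 0, rate_unrelated <= 1)
  structure(list(n_related = as.integer(n_related),
                 n_unrelated = as.integer(n_unrelated),
                 n_cases = as.integer(n_cases),
                 rate_related = rate_related,
                 rate_unrelated = rate_unrelated,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_params")
}

#' Simulate a mutation catalog with planted driver structure
#'
#' Every (gene, case) incidence is an independent Bernoulli draw at the
#' gene's class rate; no case-level budget or exclusivity constraint is
#' imposed. Gene names are synthetic (`REL_01..`, `BG_01..`) unless
#' `related_names` / `unrelated_names` supply real symbols.
#'
#' @param params a [sim_params()] object.
#' @param related_names,unrelated_names optional character vectors of gene
#'   symbols to use instead of the synthetic names.
#' @return A list of class `simulated_catalog` with `catalog` (a
#'   [mutation_catalog()]) and `truth` (named character vector,
#'   `"related"` / `"unrelated"` per gene).
#' @export
simulate_catalog <- function(params = sim_params(), related_names = NULL,
                             unrelated_names = NULL) {
  stopifnot(inherits(params, "sim_params"))
  name_block <- function(prefix, n) {
    sprintf("%s_%0*d", prefix, max(2L, nchar(n)), seq_len(n))
  }
  rel <- if (is.null(related_names)) name_block("REL", params$n_related)
         else toupper(related_names)
  bg <- if (params$n_unrelated == 0L) character(0)
        else if (is.null(unrelated_names)) name_block("BG", params$n_unrelated)
        else toupper(unrelated_names)
  stopifnot(length(rel) == params$n_related, length(bg) == params$n_unrelated,
            anyDuplicated(c(rel, bg)) == 0L)
  genes <- c(rel, bg)
  rates <- c(rep(params$rate_related, length(rel)),
             rep(params$rate_unrelated, length(bg)))
  cases <- sprintf("CASE_%0*d", max(3L, nchar(params$n_cases)),
                   seq_len(params$n_cases))
  set.seed(params$rng_seed)
  hits <- matrix(stats::rbinom(length(genes) * params$n_cases, 1,
                               rep(rates, times = params$n_cases)) == 1,
                 nrow = length(genes), ncol = params$n_cases,
                 dimnames = list(genes, cases))
  idx <- which(hits, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    stop("simulation produced an empty catalog; increase the rates",
         call. = FALSE)
  }
  catalog <- mutation_catalog(cases[idx[, 2]], genes[idx[, 1]])
  truth <- stats::setNames(
    c(rep("related", length(rel)), rep("unrelated", length(bg))), genes)
  structure(list(catalog = catalog, truth = truth, params = params),
            class = "simulated_catalog")
}

#' Write a simulated catalog and its truth labels
#'
#' @param sim a `simulated_catalog`.
#' @param catalog_path,truth_path output paths (catalog TSV; truth TSV with
#'   columns `gene`, `class`, `rate`).
#' @return Invisibly, the two paths.
#' @export
write_simulated_catalog <- function(sim, catalog_path, truth_path) {
  write_mutation_catalog(sim$catalog, catalog_path)
  rate <- ifelse(sim$truth == "related", sim$params$rate_related,
                 sim$params$rate_unrelated)
  utils::write.table(
    data.frame(gene = names(sim$truth), class = unname(sim$truth),
               rate = rate, stringsAsFactors = FALSE),
    truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(catalog_path, truth_path))
}

#' Planted-driver recovery experiment
#'
#' Runs the whole first step on one simulated catalog: build the weighted
#' mutation network, compute the six topological features, score genes with
#' the Laplacian-score weighting, take the `top_k` genes by LS, and count
#' how many are planted related genes.
#'
#' @param params a [sim_params()] object (its `rng_seed` drives the
#'   simulation).
#' @param top_k number of top-ranked genes to inspect; default 20.
#' @param scaling feature-matrix scaling, see [build_feature_matrix()].
#' @param lsfs an [lsfs_params()] object.
#' @param cost path-cost semantics, see [shortest_path_weights()].
#' @return A list with `recovered` (integer: related genes among the top
#'   `top_k`), `top_genes`, `scores` and `truth`.
#' @export
recovery_experiment <- function(params = sim_params(), top_k = 20,
                                scaling = "none", lsfs = lsfs_params(),
                                cost = "raw") {
  sim <- simulate_catalog(params)
  g <- build_mutation_network(sim$catalog)
  X <- build_feature_matrix(g, scaling = scaling, cost = cost)
  scores <- laplacian_scores(X, params = lsfs)
  top <- select_genes(scores, mode = "top_k", k = top_k)
  list(recovered = sum(sim$truth[top] == "related"),
       top_genes = top, scores = scores, truth = sim$truth)
}

#' Deterministic fixture graphs with known feature values
#'
#' Small graphs used to validate the feature computations and the module
#' search against closed forms and exhaustive enumeration:
#' * `path`: a path with the given edge weights (default all 0.5);
#' * `star`: a star, hub first, all edge weights `omega`;
#' * `clique`: a complete graph, all edge weights `omega`;
#' * `two_cliques`: two disjoint cliques of `size` nodes each, joined by
#'   nothing (a bio-graph fixture; node LS decreasing within each clique);
#' * `planted_clique`: a bio graph of `size` nodes whose first `k_planted`
#'   nodes form a high-LS clique, attached to a low-LS path.
#'
#' @param kind fixture family.
#' @param size number of nodes (per clique for `two_cliques`).
#' @param omega edge weight for the weighted fixtures; default 0.5.
#' @param weights explicit edge-weight vector for `path`.
#' @param k_planted planted-clique size; default `min(4, size - 1)`.
#' @param ls_high,ls_low LS levels of planted vs background nodes.
#' @return A list with `graph` (igraph; weighted for the first three kinds,
#'   LS-attributed for the bio kinds) and `expected` (named list of known
#'   values where a closed form exists).
#' @export
make_fixture_graph <- function(kind = c("path", "star", "clique",
                                        "two_cliques", "planted_clique"),
                               size = 4, omega = 0.5, weights = NULL,
                               k_planted = NULL, ls_high = 10, ls_low = 1) {
  kind <- match.arg(kind)
  stopifnot(size >= 2)
  lab <- function(n, prefix = "G") sprintf("%s%02d", prefix, seq_len(n))
  if (kind == "path") {
    v <- lab(size)
    w <- if (is.null(weights)) rep(omega, size - 1) else weights
    stopifnot(length(w) == size - 1)
    g <- igraph::make_graph(as.vector(rbind(v[-size], v[-1])),
                            directed = FALSE)
    igraph::E(g)$weight <- w
    return(list(graph = g,
                expected = list(end_to_end_dw = sum(w))))
  }
  if (kind == "star") {
    v <- lab(size)
    g <- igraph::make_graph(as.vector(rbind(v[1], v[-1])), directed = FALSE)
    igraph::E(g)$weight <- rep(omega, size - 1)
    en <- local({
      s <- c((size - 1) * omega, rep(omega, size - 1))
      p <- s / sum(s)
      -sum(p * log(p))
    })
    return(list(graph = g,
                expected = list(center_weight = (size - 1) * omega,
                                leaf_weight = omega,
                                entropy = en,
                                center_entropy_effect = en)))
  }
  if (kind == "clique") {
    v <- lab(size)
    g <- igraph::make_full_graph(size)
    igraph::V(g)$name <- v
    igraph::E(g)$weight <- omega
    return(list(graph = g,
                expected = list(closeness = 1 / omega,
                                node_weight = (size - 1) * omega,
                                entropy = log(size),
                                betweenness = 0)))
  }
  if (kind == "two_cliques") {
    v1 <- lab(size, "A"); v2 <- lab(size, "B")
    g1 <- igraph::make_full_graph(size); igraph::V(g1)$name <- v1
    g2 <- igraph::make_full_graph(size); igraph::V(g2)$name <- v2
    g <- igraph::disjoint_union(g1, g2)
    igraph::V(g)$ls <- c(ls_high - seq_len(size) * 0.1,
                         ls_high * 0.8 - seq_len(size) * 0.1)
    return(list(graph = g,
                expected = list(clique_a = v1, clique_b = v2)))
  }
  # planted_clique
  if (is.null(k_planted)) k_planted <- min(4L, size - 1L)
  stopifnot(k_planted >= 2, k_planted < size)
  vp <- lab(k_planted, "P")
  vb <- lab(size - k_planted, "Q")
  gp <- igraph::make_full_graph(k_planted); igraph::V(gp)$name <- vp
  v <- c(vp, vb)
  g <- gp
  g <- igraph::add_vertices(g, length(vb), name = vb)
  # attach the background as a path hanging off the clique
  chain <- c(vp[k_planted], vb)
  g <- igraph::add_edges(g, as.vector(rbind(chain[-length(chain)],
                                            chain[-1])))
  ls <- stats::setNames(c(ls_high + seq_len(k_planted) * 0.1,
                          ls_low + seq_along(vb) * 0.1), v)
  igraph::V(g)$ls <- as.numeric(ls[igraph::V(g)$name])
  list(graph = g,
       expected = list(planted = vp,
                       planted_mean_ls = mean(ls[vp])))
}
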
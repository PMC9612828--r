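#' Parameters of the MG annealing search
#'
#' The search starts at temperature `T0` and cools geometrically
#' (`T <- cooling * T`) until `T <= T_low`; at the defaults
#' (`T0 = 10`, `T_low = 0.01`, `cooling = 0.9`) this is 66 expansion
#' steps, so a module holds at most 67 genes.
#'
#' @param T0 starting temperature (> `T_low`).
#' @param T_low temperature floor (> 0).
#' @param cooling geometric cooling factor in (0, 1).
#' @param max_modules number of modules [find_modules()] extracts.
#' @param restarts independent expansions per seed; the best (highest mean
#'   LS) is kept.
#' @param rng_seed integer seed making the stochastic search reproducible.
#' @return A list of class `mg_params`.
#' @export
mg_params <- function(T0 = 10, T_low = 0.01, cooling = 0.9,
                      max_modules = 8, restarts = 1, rng_seed = 1L) {
  stopifnot(T_low > 0, T0 > T_low, cooling > 0, cooling < 1,
            max_modules >= 1, restarts >= 1)
  structure(list(T0 = T0, T_low = T_low, cooling = cooling,
                 max_modules = as.integer(max_modules),
                 restarts = as.integer(restarts),
                 rng_seed = as.integer(rng_seed)),
            class = "mg_params")
}

#' Build the biological graph over top genes
#'
#' Nodes are the supplied genes (typically the top-N by LS); two genes are
#' connected when they participate in at least one common biological
#' process or interact physically (union of the two evidence sources).
#' Each node carries its Laplacian score as weight.
#'
#' @param genes character vector of gene symbols (N >= 2).
#' @param scores a `gene_score_table` covering every gene, or a named
#'   numeric vector of LS values.
#' @param ppi an `interaction_table` from [read_interactions()], or `NULL`.
#' @param annotations an `annotation_table` from [read_annotations()], or
#'   `NULL`.
#' @return An undirected unweighted [igraph::igraph] with vertex attribute
#'   `ls`.
#' @export
build_bio_graph <- function(genes, scores, ppi = NULL, annotations = NULL) {
  genes <- sort(unique(toupper(genes)))
  if (length(genes) < 2L) stop("need at least 2 genes", call. = FALSE)
  ls <- if (is.data.frame(scores)) {
    stats::setNames(scores$ls, scores$gene)[genes]
  } else {
    scores[genes]
  }
  if (anyNA(ls)) {
    stop("missing LS for gene(s): ",
         paste(genes[is.na(ls)], collapse = ", "), call. = FALSE)
  }
  edges <- matrix(character(0), ncol = 2)
  if (!is.null(ppi)) {
    keep <- ppi$gene_a %in% genes & ppi$gene_b %in% genes
    edges <- rbind(edges, cbind(ppi$gene_a[keep], ppi$gene_b[keep]))
  }
  if (!is.null(annotations)) {
    terms <- unlist(lapply(genes, function(g) annotation_terms(annotations, g)))
    gvec <- rep(genes, vapply(genes, function(g)
      length(annotation_terms(annotations, g)), integer(1)))
    for (members in split(gvec, terms)) {
      members <- unique(members)
      if (length(members) >= 2L) {
        edges <- rbind(edges, t(utils::combn(sort(members), 2)))
      }
    }
  }
  if (nrow(edges) > 0L) {
    lo <- pmin(edges[, 1], edges[, 2])
    hi <- pmax(edges[, 1], edges[, 2])
    ed <- unique(data.frame(a = lo, b = hi, stringsAsFactors = FALSE))
    ed <- ed[ed$a != ed$b, , drop = FALSE]
  } else {
    ed <- data.frame(a = character(0), b = character(0))
  }
  g <- igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = data.frame(name = genes, stringsAsFactors = FALSE))
  igraph::V(g)$ls <- as.numeric(ls[igraph::V(g)$name])
  g
}

#' Neighborhood of a gene set
#'
#' `C(S)`: the nodes outside `S` adjacent to at least one member of `S`.
#'
#' @param graph a bio graph from [build_bio_graph()].
#' @param members character vector of member genes (subset of the nodes).
#' @return Character vector of neighboring genes (sorted).
#' @export
bio_neighborhood <- function(graph, members) {
  stopifnot(all(members %in% igraph::V(graph)$name))
  nb <- unique(unlist(lapply(igraph::adjacent_vertices(graph, members),
                             function(v) igraph::V(graph)$name[as.integer(v)])))
  sort(setdiff(nb, members))
}

#' Density of an induced subgraph
#'
#' `D(H) = 2 |E(H)| / (|V(H)| (|V(H)| - 1))` for the subgraph induced by
#' `members`; singletons have density 0.
#'
#' @param graph a bio graph.
#' @param members character vector of member genes.
#' @return Density in `[0, 1]`.
#' @export
module_density <- function(graph, members) {
  stopifnot(length(members) >= 1L, all(members %in% igraph::V(graph)$name))
  n <- length(members)
  if (n < 2L) return(0)
  h <- igraph::induced_subgraph(graph, members)
  2 * igraph::ecount(h) / (n * (n - 1))
}

#' Expand a single module from a seed (MG annealing step)
#'
#' Starting from `S = {seed}`, each cooling step proposes the highest-LS
#' gene in the neighborhood `C(S)` (ties broken lexicographically). The
#' candidate joins `S` deterministically when its weight exceeds the
#' module's mean LS `W(S)`, and otherwise joins with Metropolis probability
#' `exp((W(g_i) - W(S)) / T)` against a fresh uniform draw; a rejected
#' candidate may be proposed again at a later (lower) temperature. After
#' every step `T <- cooling * T`; the loop runs while `T > T_low`.
#'
#' Uses the R random number stream; call `set.seed()` (or use
#' [find_modules()], which seeds from `params$rng_seed`) for reproducible
#' results.
#'
#' @param graph a bio graph from [build_bio_graph()].
#' @param seed seed gene (must be a node).
#' @param params an [mg_params()] object.
#' @return A `driver_module`: list with `seed`, `members` (sorted), `mean_ls`,
#'   `density` and `ev` (`NA` until [ev_test()] is run).
#' @export
mg_expand <- function(graph, seed, params = mg_params()) {
  vnames <- igraph::V(graph)$name
  if (!seed %in% vnames) stop("seed '", seed, "' is not a node", call. = FALSE)
  ls <- stats::setNames(igraph::V(graph)$ls, vnames)
  members <- seed
  temp <- params$T0
  while (temp > params$T_low) {
    nb <- bio_neighborhood(graph, members)
    x <- stats::runif(1)             # drawn every step, as the anneal's
    if (length(nb) > 0L) {           # per-iteration randomness
      cand <- nb[order(-ls[nb], nb)][1]
      w_s <- mean(ls[members])
      if (ls[[cand]] > w_s || x < exp((ls[[cand]] - w_s) / temp)) {
        members <- c(members, cand)
      }
    }
    temp <- params$cooling * temp
  }
  new_module(graph, seed, members)
}

#' Construct a driver module from an explicit member set
#'
#' Fills in mean LS and density from the bio graph. Useful for evaluating
#' externally chosen gene sets with [ev_test()] or [module_case_counts()].
#'
#' @param graph a bio graph from [build_bio_graph()].
#' @param seed seed gene label for the module.
#' @param members character vector of member genes (must be nodes).
#' @return A `driver_module` object.
#' @export
driver_module <- function(graph, seed, members) {
  stopifnot(all(members %in% igraph::V(graph)$name), seed %in% members)
  new_module(graph, seed, members)
}

new_module <- function(graph, seed, members) {
  ls <- stats::setNames(igraph::V(graph)$ls, igraph::V(graph)$name)
  members <- sort(unique(members))
  structure(list(seed = seed,
                 members = members,
                 mean_ls = mean(ls[members]),
                 density = module_density(graph, members),
                 ev = NA_real_),
            class = "driver_module")
}

#' @export
print.driver_module <- function(x, ...) {
  cat(sprintf("driver_module: seed %s, %d genes, mean LS %.4g, density %.3f%s\n",
              x$seed, length(x$members), x$mean_ls, x$density,
              if (is.na(x$ev)) "" else sprintf(", EV %.3g", x$ev)))
  cat("  members:", paste(x$members, collapse = ", "), "\n")
  invisible(x)
}

#' Extract ranked driver modules
#'
#' Seeds are taken in decreasing LS order among the nodes not yet placed in
#' any previously returned module; each seed is expanded with [mg_expand()]
#' (best of `params$restarts` expansions by mean LS). Expansion may re-use
#' genes that already belong to other modules, so modules can overlap;
#' only seeds must be fresh. The search stops after `params$max_modules`
#' modules or when no fresh seed remains. The result is ordered by mean LS,
#' descending.
#'
#' @param graph a bio graph from [build_bio_graph()].
#' @param params an [mg_params()] object; `params$rng_seed` fixes the
#'   whole module list.
#' @return A list of `driver_module` objects.
#' @export
find_modules <- function(graph, params = mg_params()) {
  vnames <- igraph::V(graph)$name
  if (length(vnames) == 0L) stop("bio graph is empty", call. = FALSE)
  ls <- stats::setNames(igraph::V(graph)$ls, vnames)
  seed_order <- vnames[order(-ls, vnames)]
  set.seed(params$rng_seed)
  placed <- character(0)
  modules <- list()
  for (seed in seed_order) {
    if (length(modules) >= params$max_modules) break
    if (seed %in% placed) next
    best <- NULL
    for (r in seq_len(params$restarts)) {
      m <- mg_expand(graph, seed, params)
      if (is.null(best) || m$mean_ls > best$mean_ls) best <- m
    }
    modules[[length(modules) + 1L]] <- best
    placed <- union(placed, best$members)
  }
  modules[order(-vapply(modules, function(m) m$mean_ls, numeric(1)))]
}
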
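#' Build the weighted mutation co-occurrence network
#'
#' Genes are nodes; two genes `g_i`, `g_j` are connected if and only if at
#' least one case carries mutations in both, i.e. `C(g_i) n C(g_j) != {}`.
#' The edge weight is the shared-case count normalized by the smaller of the
#' two genes' case counts,
#' `w(g_i g_j) = |C(g_i) n C(g_j)| / min(|C(g_i)|, |C(g_j)|)`,
#' so `w` is a co-occurrence similarity in `(0, 1]` and equals 1 exactly
#' when the rarer gene's cases are a subset of the other's.
#'
#' @param catalog a [mutation_catalog()].
#' @return An undirected [igraph::igraph] whose vertices are the catalog's
#'   genes in lexicographic order, with edge attribute `weight` and vertex
#'   attribute `n_cases` (`|C(g)|`). Genes that share no case with any other
#'   gene are isolated vertices.
#' @export
build_mutation_network <- function(catalog) {
  stopifnot(inherits(catalog, "mutation_catalog"))
  genes <- catalog_genes(catalog)
  cases <- catalog_cases(catalog)
  if (length(genes) == 0L) stop("catalog has no genes", call. = FALSE)
  # gene x case incidence; genes and cases both small enough for a dense
  # logical matrix at the scales this method targets (hundreds of genes)
  M <- matrix(FALSE, nrow = length(genes), ncol = length(cases),
              dimnames = list(genes, cases))
  M[cbind(match(catalog$records$gene, genes),
          match(catalog$records$case_id, cases))] <- TRUE
  counts <- rowSums(M)
  shared <- tcrossprod(M * 1)          # |C(gi) n C(gj)|
  minc <- outer(counts, counts, pmin)
  W <- shared / minc
  W[shared == 0] <- 0
  diag(W) <- 0
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$n_cases <- as.integer(counts[igraph::V(g)$name])
  g
}

#' Single-source shortest-path weights on the mutation network
#'
#' A path's cost is the sum of the weights of its edges, and the shortest
#' path between two genes is the path of minimum cost `d_w`. With
#' `cost = "raw"` (the default) edge costs are the co-occurrence weights
#' `w` themselves, taking the network's path-length definition literally;
#' with `cost = "inverse"` edge costs are `1/w`, the conventional
#' similarity-to-distance transform.
#'
#' @param graph a weighted gene graph from [build_mutation_network()].
#' @param source gene symbol (vertex name); when `NULL`, the full
#'   gene-by-gene matrix is returned.
#' @param cost `"raw"` or `"inverse"` edge-cost semantics.
#' @return A numeric vector (or matrix) of `d_w` values; unreachable pairs
#'   are `Inf` ("unreachable"), never 0; `d_w(g, g) = 0`.
#' @export
shortest_path_weights <- function(graph, source = NULL,
                                  cost = c("raw", "inverse")) {
  cost <- match.arg(cost)
  w <- igraph::E(graph)$weight
  if (!is.null(w) && any(w <= 0)) {
    stop("edge weights must be positive", call. = FALSE)
  }
  costs <- switch(cost, raw = w, inverse = 1 / w)
  if (is.null(source)) {
    igraph::distances(graph, weights = costs, mode = "all")
  } else {
    if (!source %in% igraph::V(graph)$name) {
      stop("source gene '", source, "' is not a network node", call. = FALSE)
    }
    d <- igraph::distances(graph, v = source, weights = costs, mode = "all")
    stats::setNames(as.numeric(d[1, ]), colnames(d))
  }
}

#' Serialize / load a weighted gene graph as edge-list TSV
#'
#' Three tab-separated columns `gene_a`, `gene_b`, `weight`, with weights
#' printed at 10 significant digits. Isolated vertices are preserved via
#' rows with an empty `gene_b` and weight 0.
#'
#' @param graph a weighted gene graph.
#' @param path output (input) path.
#' @return `write_gene_graph()`: `path` invisibly; `read_gene_graph()`: the
#'   igraph object.
#' @export
write_gene_graph <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  df <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                   weight = signif(igraph::E(graph)$weight, 10),
                   stringsAsFactors = FALSE)
  iso <- setdiff(igraph::V(graph)$name, unique(c(el[, 1], el[, 2])))
  if (length(iso) > 0L) {
    df <- rbind(df, data.frame(gene_a = iso, gene_b = "", weight = 0))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_graph
#' @export
read_gene_graph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  need <- c("gene_a", "gene_b", "weight")
  if (!all(need %in% names(df))) {
    stop("graph file '", path, "' must have columns gene_a, gene_b, weight",
         call. = FALSE)
  }
  df$gene_b[is.na(df$gene_b)] <- ""
  edges <- df[nzchar(df$gene_b), , drop = FALSE]
  iso <- df$gene_a[!nzchar(df$gene_b)]
  verts <- sort(unique(c(edges$gene_a, edges$gene_b, iso)))
  g <- igraph::graph_from_data_frame(
    edges[, c("gene_a", "gene_b", "weight")], directed = FALSE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE))
  igraph::E(g)$weight <- edges$weight
  g
}
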
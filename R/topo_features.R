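# Six per-node topological features of the weighted mutation network.
# All functions accept the igraph produced by build_mutation_network() and
# return values in the graph's vertex order (named by gene).

weighted_adjacency <- function(graph) {
  A <- igraph::as_adjacency_matrix(graph, attr = "weight", sparse = FALSE)
  dimnames(A) <- list(igraph::V(graph)$name, igraph::V(graph)$name)
  A
}

#' Node weight (strength)
#'
#' The weight of a node is the sum of the co-occurrence weights of its
#' incident edges; 0 for isolated nodes.
#'
#' @param graph a weighted gene graph.
#' @return Named numeric vector of node strengths.
#' @export
node_weight <- function(graph) {
  s <- igraph::strength(graph, weights = igraph::E(graph)$weight)
  stats::setNames(as.numeric(s), igraph::V(graph)$name)
}

#' Closeness centrality under summed-weight path costs
#'
#' For a node `g` in a component of `r` nodes, closeness is
#' `(r - 1) / sum(d_w(g, .))` with the sum over the `r - 1` nodes reachable
#' from `g`; nodes in singleton components score 0. Unreachable pairs are
#' excluded from the sum rather than given an arbitrary constant.
#'
#' @inheritParams node_weight
#' @param cost edge-cost semantics, see [shortest_path_weights()].
#' @return Named numeric vector of closeness values.
#' @export
closeness_centrality <- function(graph, cost = c("raw", "inverse")) {
  cost <- match.arg(cost)
  d <- shortest_path_weights(graph, cost = cost)
  vals <- vapply(seq_len(nrow(d)), function(i) {
    di <- d[i, -i]
    reach <- di[is.finite(di)]
    if (length(reach) == 0L) 0 else length(reach) / sum(reach)
  }, numeric(1))
  stats::setNames(vals, rownames(d))
}

#' Betweenness centrality under summed-weight path costs
#'
#' Unnormalized shortest-path betweenness: for each unordered pair of other
#' nodes, the fraction of minimum-cost paths that pass through the node,
#' summed over pairs (Brandes counting on the weighted graph).
#'
#' @inheritParams closeness_centrality
#' @return Named numeric vector of betweenness values.
#' @export
betweenness_centrality <- function(graph, cost = c("raw", "inverse")) {
  cost <- match.arg(cost)
  w <- igraph::E(graph)$weight
  costs <- switch(cost, raw = w, inverse = 1 / w)
  b <- igraph::betweenness(graph, weights = costs, directed = FALSE,
                           normalized = FALSE)
  stats::setNames(as.numeric(b), igraph::V(graph)$name)
}

#' Weighted PageRank variant
#'
#' Fixed point of
#' `PR(g_i) = (1 - d) + d * sum_j w(g_i g_j) / s(g_j) * PR(g_j)`,
#' where the sum runs over neighbors `g_j` and `s(g_j)` is the strength of
#' `g_j`. Unlike the probabilistic PageRank there is no `1/n` term: scores
#' are anchored at `(1 - d)`, an isolated node scores exactly `1 - d`, and
#' a regular equal-weight graph fixes `PR = 1` for every node. Iteration
#' starts from all ones and stops when the maximum absolute change drops
#' below `tol`.
#'
#' @inheritParams node_weight
#' @param d damping factor in (0, 1); default 0.85.
#' @param tol convergence tolerance on the max absolute per-node change.
#' @param max_iter iteration cap; non-convergence warns and returns the
#'   last iterate.
#' @return Named numeric vector of PageRank scores.
#' @export
pagerank_scores <- function(graph, d = 0.85, tol = 1e-10, max_iter = 1000) {
  stopifnot(d > 0, d < 1)
  A <- weighted_adjacency(graph)
  s <- colSums(A)
  # column-stochastic transition on non-dangling columns: M[i,j] = w_ij / s_j
  M <- A
  nz <- s > 0
  M[, nz] <- sweep(A[, nz, drop = FALSE], 2, s[nz], "/")
  M[, !nz] <- 0
  pr <- rep(1, nrow(A))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    pr_new <- (1 - d) + d * as.numeric(M %*% pr)
    if (max(abs(pr_new - pr)) < tol) {
      pr <- pr_new
      converged <- TRUE
      break
    }
    pr <- pr_new
  }
  if (!converged) {
    warning("PageRank did not converge in ", max_iter,
            " iterations; returning the last iterate", call. = FALSE)
  }
  stats::setNames(pr, rownames(A))
}

#' Eigenvector centrality of the weighted adjacency matrix
#'
#' The Perron (leading) eigenvector of `A_w = [w(g_i, g_j)]`, computed by
#' power iteration separately on each connected component, reported
#' nonnegative with unit Euclidean norm per component. Isolated nodes
#' score 0.
#'
#' @inheritParams node_weight
#' @param tol convergence tolerance on the iterate change.
#' @param max_iter power-iteration cap; non-convergence warns.
#' @return Named numeric vector of eigenvector centralities.
#' @export
eigenvector_scores <- function(graph, tol = 1e-12, max_iter = 10000) {
  A <- weighted_adjacency(graph)
  out <- stats::setNames(numeric(nrow(A)), rownames(A))
  comp <- igraph::components(graph)
  for (k in seq_len(comp$no)) {
    idx <- which(comp$membership == k)
    if (length(idx) < 2L) next          # isolated node -> 0
    Ak <- A[idx, idx, drop = FALSE]
    # positive diagonal shift keeps the Perron eigenvalue strictly dominant
    # in magnitude (bipartite components otherwise make the iteration
    # oscillate between the +/- extreme eigenvectors)
    shift <- 1 + max(rowSums(Ak))
    v <- rep(1 / sqrt(length(idx)), length(idx))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      v_new <- as.numeric(Ak %*% v) + shift * v
      v_new <- v_new / sqrt(sum(v_new^2))
      if (max(abs(v_new - v)) < tol) {
        v <- v_new
        converged <- TRUE
        break
      }
      v <- v_new
    }
    if (!converged) {
      warning("eigenvector power iteration did not converge for a ",
              length(idx), "-node component", call. = FALSE)
    }
    out[idx] <- abs(v)
  }
  out
}

#' Entropy of a weighted graph
#'
#' Shannon entropy (natural log) of the node-strength distribution:
#' `pi_i = w(g_i) / sum_j w(g_j)`, `En(G) = -sum pi_i ln pi_i`, with
#' `0 ln 0 = 0`. A graph whose total strength is 0 has entropy 0.
#'
#' @param strengths named numeric vector of node strengths, or a graph
#'   (strengths are then computed with [node_weight()]).
#' @return The entropy, a scalar in `[0, ln n]`.
#' @export
graph_entropy <- function(strengths) {
  if (inherits(strengths, "igraph")) strengths <- node_weight(strengths)
  tot <- sum(strengths)
  if (tot <= 0) return(0)
  p <- strengths / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Entropy effect of removing each node
#'
#' `eps(g) = |En(G) - En(G \ g)|`, where `G \ g` drops the node and its
#' incident edges and node strengths are recomputed. Removal only subtracts
#' the node's incident weights from its neighbors, so all effects are
#' computed from the adjacency matrix without rebuilding graphs.
#'
#' @inheritParams node_weight
#' @return Named numeric vector of entropy effects.
#' @export
entropy_effect <- function(graph) {
  A <- weighted_adjacency(graph)
  s <- rowSums(A)
  en_full <- graph_entropy(s)
  vals <- vapply(seq_along(s), function(i) {
    s_rem <- s[-i] - A[-i, i]
    abs(en_full - graph_entropy(s_rem))
  }, numeric(1))
  stats::setNames(vals, rownames(A))
}

#' Assemble the feature matrix
#'
#' One row per gene, six columns in fixed order: `weight` (strength),
#' `closeness`, `betweenness`, `pagerank`, `eigenvector`, `entropy` (the
#' node's entropy effect). Optional column scaling is applied after the raw
#' computation: `"minmax"` maps each column to `[0, 1]` (constant columns
#' map to 0), `"zscore"` standardizes (constant columns map to 0). The
#' default is `"none"`: the downstream affinity parameters (`delta`, `t`)
#' are coupled to raw feature magnitudes, and rescaling the columns to
#' `[0, 1]` collapses all pairwise distances below `delta`, which makes the
#' neighborhood threshold vacuous and the feature weighting degenerate.
#'
#' @inheritParams closeness_centrality
#' @param scaling `"none"` (default), `"minmax"` or `"zscore"`.
#' @param d damping factor for the PageRank feature.
#' @return A numeric matrix with gene rownames, feature colnames, and
#'   attribute `scaling_applied`.
#' @export
build_feature_matrix <- function(graph, scaling = c("none", "minmax", "zscore"),
                                 cost = c("raw", "inverse"), d = 0.85) {
  scaling <- match.arg(scaling)
  cost <- match.arg(cost)
  if (igraph::vcount(graph) == 0L) stop("graph has no nodes", call. = FALSE)
  X <- cbind(
    weight      = node_weight(graph),
    closeness   = closeness_centrality(graph, cost = cost),
    betweenness = betweenness_centrality(graph, cost = cost),
    pagerank    = pagerank_scores(graph, d = d),
    eigenvector = eigenvector_scores(graph),
    entropy     = entropy_effect(graph)
  )
  X <- scale_features(X, scaling)
  attr(X, "scaling_applied") <- scaling
  X
}

scale_features <- function(X, scaling) {
  if (scaling == "none") return(X)
  apply_col <- function(f) {
    Y <- X
    for (j in seq_len(ncol(X))) Y[, j] <- f(X[, j])
    Y
  }
  if (scaling == "minmax") {
    apply_col(function(x) {
      rng <- range(x)
      if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) else x * 0
    })
  } else {
    apply_col(function(x) {
      s <- stats::sd(x)
      if (s > 0) (x - mean(x)) / s else x * 0
    })
  }
}

#' Write / read a feature matrix as TSV
#'
#' Columns: `gene` then the six feature names.
#'
#' @param X feature matrix from [build_feature_matrix()].
#' @param path output (input) path.
#' @return `write_feature_matrix()`: `path` invisibly;
#'   `read_feature_matrix()`: the matrix.
#' @export
write_feature_matrix <- function(X, path) {
  df <- data.frame(gene = rownames(X), X, stringsAsFactors = FALSE,
                   row.names = NULL)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  X <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  rownames(X) <- df$gene
  X
}
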
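# Independent brute-force oracles used to validate the graph-feature and
# score computations on small fixtures. These deliberately use naive
# enumeration / dense linear algebra, not the code paths under test.

# igraph from a symmetric weighted adjacency matrix (0 = no edge)
graph_from_W <- function(W) {
  if (is.null(rownames(W))) {
    dimnames(W) <- list(sprintf("G%02d", seq_len(nrow(W))),
                        sprintf("G%02d", seq_len(nrow(W))))
  }
  igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# all simple paths from s to t with their summed-weight costs
enumerate_paths <- function(W, s, t) {
  n <- nrow(W)
  res <- list()
  recurse <- function(path, cost) {
    last <- path[length(path)]
    if (last == t) {
      res[[length(res) + 1L]] <<- list(path = path, cost = cost)
      return(invisible())
    }
    for (v in seq_len(n)) {
      if (W[last, v] > 0 && !(v %in% path)) {
        recurse(c(path, v), cost + W[last, v])
      }
    }
  }
  recurse(s, 0)
  res
}

# minimum summed-weight distances by exhaustive simple-path enumeration
oracle_distances <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n, dimnames = dimnames(W))
  diag(D) <- 0
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    ps <- enumerate_paths(W, s, t)
    if (length(ps) > 0L) {
      D[s, t] <- D[t, s] <- min(vapply(ps, `[[`, numeric(1), "cost"))
    }
  }
  D
}

oracle_closeness <- function(W) {
  D <- oracle_distances(W)
  vapply(seq_len(nrow(W)), function(i) {
    di <- D[i, -i]
    reach <- di[is.finite(di)]
    if (length(reach) == 0L) 0 else length(reach) / sum(reach)
  }, numeric(1))
}

# Brandes-style pair-dependency betweenness from exhaustive enumeration
oracle_betweenness <- function(W, tol = 1e-12) {
  n <- nrow(W)
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    ps <- enumerate_paths(W, s, t)
    if (length(ps) == 0L) next
    costs <- vapply(ps, `[[`, numeric(1), "cost")
    sp <- ps[costs <= min(costs) + tol]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      through <- sum(vapply(sp, function(p) v %in% p$path, logical(1)))
      b[v] <- b[v] + through / length(sp)
    }
  }
  b
}

# exact fixed point of the weighted PageRank variant via a dense solve:
# (I - d M) pr = (1 - d) 1 with M[i,j] = w_ij / strength_j
oracle_pagerank <- function(W, d = 0.85) {
  s <- colSums(W)
  M <- W
  nz <- s > 0
  M[, nz] <- sweep(W[, nz, drop = FALSE], 2, s[nz], "/")
  M[, !nz] <- 0
  as.numeric(solve(diag(nrow(W)) - d * M, rep(1 - d, nrow(W))))
}

# loop-based dense reference for the Laplacian-score feature weighting
oracle_lsfs <- function(X, delta = 5, t = 100) {
  m <- nrow(X)
  S <- matrix(0, m, m)
  for (i in seq_len(m)) for (j in seq_len(m)) {
    dist_ij <- sqrt(sum((X[i, ] - X[j, ])^2))
    if (dist_ij < delta) S[i, j] <- exp(-dist_ij^2 / t)
  }
  D <- diag(rowSums(S))
  L <- D - S
  J <- rep(1, m)
  Lj <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    Fj <- X[, j]
    Ft <- Fj - as.numeric(t(Fj) %*% D %*% J) /
      as.numeric(t(J) %*% D %*% J) * J
    den <- as.numeric(t(Ft) %*% D %*% Ft)
    Lj[j] <- if (den < 1e-12 * max(1, sum(Fj^2))) 0 else
      as.numeric(t(Ft) %*% L %*% Ft) / den
  }
  list(S = S, L = L, Lj = Lj, LS = as.numeric(X %*% Lj))
}

# random connected-ish weighted graph with dyadic weights, so summed path
# costs compare exactly (no floating-point tie ambiguity)
random_weighted_W <- function(n, p = 0.5, seed = 1) {
  set.seed(seed)
  repeat {
    W <- matrix(0, n, n)
    pool <- c(0.125, 0.25, 0.375, 0.5, 0.625, 0.75, 1)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (stats::runif(1) < p) W[i, j] <- W[j, i] <- sample(pool, 1)
    }
    if (sum(W > 0) > 0) return(W)
  }
}

# best mean-LS over all connected induced subgraphs of a given size
oracle_best_connected <- function(graph, k) {
  v <- igraph::V(graph)$name
  ls <- stats::setNames(igraph::V(graph)$ls, v)
  if (k == 1L) return(max(ls))
  best <- -Inf
  for (comb in utils::combn(v, k, simplify = FALSE)) {
    sg <- igraph::induced_subgraph(graph, comb)
    if (igraph::is_connected(sg)) best <- max(best, mean(ls[comb]))
  }
  best
}

# small catalog literal for io tests
write_tsv_catalog <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
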
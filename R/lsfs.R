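#' Parameters for the Laplacian-score feature weighting
#'
#' `delta` is the neighborhood radius: two genes' feature vectors are
#' connected in the sample affinity graph only when their Euclidean
#' distance is strictly below `delta`. `t` is the heat-kernel bandwidth of
#' the affinity `s_ij = exp(-|p_i - p_j|^2 / t)`. Defaults are `delta = 5`
#' and `t = 100`.
#'
#' @param delta neighborhood distance threshold (> 0).
#' @param t heat-kernel bandwidth (> 0).
#' @return A list of class `lsfs_params`.
#' @export
lsfs_params <- function(delta = 5, t = 100) {
  stopifnot(is.numeric(delta), delta > 0, is.numeric(t), t > 0)
  structure(list(delta = delta, t = t), class = "lsfs_params")
}

#' Sample affinity, degree and Laplacian matrices
#'
#' Builds the m-by-m affinity matrix over gene feature vectors:
#' `s_ij = exp(-|p_i - p_j|^2 / t)` when `|p_i - p_j| < delta`, else 0
#' (the diagonal is always 1 since the self-distance is 0). `D` is the
#' diagonal matrix of row sums and `L = D - S` the (unnormalized) graph
#' Laplacian, which is positive semidefinite.
#'
#' @param X numeric feature matrix (genes in rows); typically the scaled
#'   matrix from [build_feature_matrix()].
#' @param params an [lsfs_params()] object.
#' @return A list with `S` (matrix), `d` (numeric vector, the diagonal of
#'   `D`) and `L` (matrix).
#' @export
affinity_matrix <- function(X, params = lsfs_params()) {
  stopifnot(is.matrix(X), all(is.finite(X)))
  dmat <- as.matrix(stats::dist(X, method = "euclidean"))
  S <- ifelse(dmat < params$delta, exp(-dmat^2 / params$t), 0)
  dimnames(S) <- list(rownames(X), rownames(X))
  d <- rowSums(S)
  L <- diag(d) - S
  list(S = S, d = d, L = L)
}

#' Laplacian score of each feature
#'
#' For feature column `F_j`, the D-weighted mean is removed,
#' `Ft_j = F_j - (F_j' D 1 / 1' D 1) 1`, and the score is the Rayleigh-type
#' quotient `L_j = Ft_j' L Ft_j / Ft_j' D Ft_j`. Constant columns (zero
#' weighted variance) score 0 by definition. Here a high `L_j` is treated
#' as high feature importance when aggregating per-gene scores.
#'
#' @param X numeric feature matrix (the same matrix used for the affinity).
#' @param aff the affinity structure from [affinity_matrix()]; computed
#'   from `X` and `params` when missing.
#' @param params an [lsfs_params()] object (used only when `aff` is missing).
#' @return Named numeric vector of per-feature scores `L_j`.
#' @export
feature_scores <- function(X, aff = NULL, params = lsfs_params()) {
  if (is.null(aff)) aff <- affinity_matrix(X, params)
  d <- aff$d
  L <- aff$L
  tot <- sum(d)
  vapply(seq_len(ncol(X)), function(j) {
    Fj <- X[, j]
    Ft <- Fj - sum(Fj * d) / tot
    den <- sum(d * Ft^2)
    if (den <= .Machine$double.eps * max(1, sum(Fj^2))) return(0)
    num <- as.numeric(t(Ft) %*% L %*% Ft)
    max(num, 0) / den      # clamp the tiny negative round-off of a PSD form
  }, numeric(1)) |> stats::setNames(colnames(X))
}

#' Per-gene Laplacian scores
#'
#' Aggregates the feature scores into a per-gene score
#' `LS(g_i) = sum_j x_ij L_j`, the feature-score-weighted row sum of the
#' same matrix `X` used for the affinity step, and ranks genes (rank 1 =
#' highest LS; ties broken lexicographically by gene symbol).
#'
#' @param X numeric feature matrix with gene rownames.
#' @param fscores named numeric vector from [feature_scores()]; computed
#'   when missing.
#' @param params an [lsfs_params()] object.
#' @return A data.frame of class `gene_score_table` with columns `gene`,
#'   the feature columns of `X`, `ls` and `rank`, ordered by rank.
#' @export
laplacian_scores <- function(X, fscores = NULL, params = lsfs_params()) {
  if (is.null(fscores)) fscores <- feature_scores(X, params = params)
  ls <- as.numeric(X %*% fscores)
  genes <- rownames(X)
  ord <- order(-ls, genes)
  out <- data.frame(gene = genes, X, ls = ls, stringsAsFactors = FALSE,
                    row.names = NULL)
  out$rank <- integer(nrow(out))
  out$rank[ord] <- seq_len(nrow(out))
  out <- out[order(out$rank), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "feature_scores") <- fscores
  class(out) <- c("gene_score_table", "data.frame")
  out
}

#' Select high-score genes
#'
#' `"above_mean"` keeps genes whose LS is strictly greater than the
#' arithmetic mean LS; `"top_k"` keeps the `k` best-ranked genes.
#'
#' @param scores a `gene_score_table` from [laplacian_scores()].
#' @param mode `"above_mean"` (default) or `"top_k"`.
#' @param k number of genes for `"top_k"`.
#' @return Character vector of selected gene symbols (in rank order).
#' @export
select_genes <- function(scores, mode = c("above_mean", "top_k"), k = 200) {
  mode <- match.arg(mode)
  stopifnot(nrow(scores) > 0L)
  ord <- scores[order(scores$rank), , drop = FALSE]
  if (mode == "above_mean") {
    ord$gene[ord$ls > mean(ord$ls)]
  } else {
    utils::head(ord$gene, k)
  }
}

#' Flag infrequently mutated genes
#'
#' A gene is infrequent when it is mutated in strictly fewer than
#' `threshold` cases of the catalog (`|C(g)| < threshold`).
#'
#' @param catalog a [mutation_catalog()].
#' @param threshold case-count threshold; default 100.
#' @return Named logical vector over the catalog's genes.
#' @export
flag_infrequent <- function(catalog, threshold = 100) {
  cc <- gene_case_counts(catalog)
  cc < threshold
}

#' Annotate a score table with selection and frequency flags
#'
#' @param scores a `gene_score_table`.
#' @param catalog the [mutation_catalog()] the scores came from.
#' @param mode,k selection rule, see [select_genes()].
#' @param freq_threshold case-count threshold for [flag_infrequent()].
#' @return The score table with added columns `mutation_count`, `selected`
#'   and `infrequent`.
#' @export
annotate_scores <- function(scores, catalog, mode = c("above_mean", "top_k"),
                            k = 200, freq_threshold = 100) {
  mode <- match.arg(mode)
  sel <- select_genes(scores, mode = mode, k = k)
  cc <- gene_case_counts(catalog)
  infreq <- flag_infrequent(catalog, freq_threshold)
  scores$mutation_count <- as.integer(cc[scores$gene])
  scores$selected <- scores$gene %in% sel
  scores$infrequent <- as.logical(infreq[scores$gene])
  scores
}
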
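#' Confusion counts against a benchmark gene set
#'
#' The benchmark is first intersected with the gene universe (the mutated
#' genes under study), then the standard 2x2 partition is counted: TP =
#' predicted driver genes in the benchmark, FP = predicted but not in the
#' benchmark, FN = benchmark genes not predicted, TN = the rest of the
#' universe.
#'
#' @param predicted character vector of predicted driver genes (subset of
#'   `universe`).
#' @param benchmark character vector of benchmark driver genes.
#' @param universe character vector: all genes under study.
#' @return A list of class `confusion_counts` with `tp`, `tn`, `fp`, `fn`
#'   and `n_universe`.
#' @export
confusion_counts <- function(predicted, benchmark, universe) {
  predicted <- unique(toupper(predicted))
  benchmark <- unique(toupper(benchmark))
  universe <- unique(toupper(universe))
  if (!all(predicted %in% universe)) {
    stop("predicted genes must be a subset of the universe", call. = FALSE)
  }
  bm <- intersect(benchmark, universe)
  tp <- length(intersect(predicted, bm))
  fp <- length(setdiff(predicted, bm))
  fn <- length(setdiff(bm, predicted))
  tn <- length(universe) - tp - fp - fn
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 n_universe = length(universe)),
            class = "confusion_counts")
}

#' Precision, recall and F-measure
#'
#' `Pre = TP / (TP + FP)`, `Re = TP / (TP + FN)`,
#' `F = 2 Pre Re / (Pre + Re)`. Degenerate denominators (no predictions,
#' or an empty benchmark) give a 0 metric with a warning rather than an
#' error.
#'
#' @param counts a `confusion_counts` object, or a list with `tp`, `fp`,
#'   `fn`.
#' @return Named numeric vector `c(precision, recall, f)`.
#' @export
precision_recall_f <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  pre <- if (tp + fp > 0) tp / (tp + fp) else {
    warning("no predicted genes; precision set to 0", call. = FALSE); 0
  }
  re <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("empty benchmark intersection; recall set to 0", call. = FALSE); 0
  }
  f <- if (pre + re > 0) 2 * pre * re / (pre + re) else 0
  c(precision = pre, recall = re, f = f)
}

#' Exceeding-value significance test for a module
#'
#' Draws `n_samples` uniform gene subsets of the module's size from the
#' top-gene pool (node subsets; connectivity is not required), computes for
#' each the mean LS `N_i` and the induced-subgraph density `M_i`, and counts
#' the samples that strictly exceed the module in BOTH statistics. The
#' exceeding value is `EV = |X| / n_samples`; the module is significant
#' when `EV < alpha`.
#'
#' @param module a `driver_module`.
#' @param graph the bio graph the module lives in (vertex attribute `ls`).
#' @param pool character vector: the top-N gene set to sample from;
#'   defaults to all nodes of `graph`.
#' @param n_samples number of random subsets; default 1000.
#' @param alpha significance threshold; default 0.05.
#' @param rng_seed integer seed for the sampling.
#' @return A list of class `ev_result` with `n_samples`, `exceed_count`,
#'   `ev`, `alpha` and `significant`.
#' @export
ev_test <- function(module, graph, pool = NULL, n_samples = 1000,
                    alpha = 0.05, rng_seed = 1L) {
  vnames <- igraph::V(graph)$name
  if (is.null(pool)) pool <- vnames
  stopifnot(all(pool %in% vnames), all(module$members %in% vnames))
  k <- length(module$members)
  if (k > length(pool)) stop("module larger than the pool", call. = FALSE)
  if (k < 2L) {
    warning("singleton module: the density comparison is degenerate",
            call. = FALSE)
  }
  ls <- stats::setNames(igraph::V(graph)$ls, vnames)
  A <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  dimnames(A) <- list(vnames, vnames)
  set.seed(rng_seed)
  exceed <- 0L
  for (i in seq_len(n_samples)) {
    smp <- sample(pool, k)
    ni <- mean(ls[smp])
    mi <- if (k < 2L) 0 else sum(A[smp, smp]) / (k * (k - 1))
    if (ni > module$mean_ls && mi > module$density) exceed <- exceed + 1L
  }
  structure(list(n_samples = as.integer(n_samples),
                 exceed_count = exceed,
                 ev = exceed / n_samples,
                 alpha = alpha,
                 significant = (exceed / n_samples) < alpha),
            class = "ev_result")
}

#' Hypergeometric gene-set enrichment of a module
#'
#' With `N` mutated genes in total, `K` of which belong to the pathway,
#' and a module of `n` genes `k` of which are in the pathway, the point
#' probability is the hypergeometric pmf
#' `C(K, k) C(N - K, n - k) / C(N, n)`; the upper-tail p-value
#' `P[X >= k]` is also reported and is the conventional enrichment
#' significance.
#'
#' @param N total number of mutated genes.
#' @param K pathway size within the universe.
#' @param n module size.
#' @param k overlap between module and pathway.
#' @return A list of class `enrichment_result` with `N`, `K`, `n`, `k`,
#'   `pmf` and `tail_p`.
#' @export
hypergeom_enrichment <- function(N, K, n, k) {
  stopifnot(k >= 0, n >= 0, K >= 0, N >= 0, k <= n, k <= K, n <= N, K <= N)
  pmf <- stats::dhyper(k, K, N - K, n)
  tail_p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(N = N, K = K, n = n, k = k, pmf = pmf, tail_p = tail_p),
            class = "enrichment_result")
}

#' Enrichment of each module against each gene set
#'
#' @param modules list of `driver_module` objects.
#' @param gene_sets a `gene_set_collection` from [read_gmt()].
#' @param universe character vector of all mutated genes (defines `N`).
#' @return Data.frame with one row per (module, set): `module`, `pathway`,
#'   `N`, `K`, `n`, `k`, `pmf`, `tail_p`.
#' @export
enrich_modules <- function(modules, gene_sets, universe) {
  universe <- unique(toupper(universe))
  N <- length(universe)
  rows <- list()
  for (i in seq_along(modules)) {
    mod <- modules[[i]]
    mg <- intersect(toupper(mod$members), universe)
    for (nm in names(gene_sets)) {
      pg <- intersect(gene_sets[[nm]]$genes, universe)
      k <- length(intersect(mg, pg))
      e <- hypergeom_enrichment(N, length(pg), length(mg), k)
      rows[[length(rows) + 1L]] <- data.frame(
        module = i, pathway = nm, N = e$N, K = e$K, n = e$n, k = e$k,
        pmf = e$pmf, tail_p = e$tail_p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-site co-mutation case counts for a module
#'
#' For each primary site (or a single `"all"` stratum when the catalog has
#' no site labels) counts the cases carrying mutations in at least
#' `min_genes` of the module's genes, and reports each module gene's
#' mutated-case fraction among the site's cases, partitioned at the 10%
#' threshold (`high` when the fraction exceeds `frac_threshold`).
#'
#' @param catalog a [mutation_catalog()].
#' @param module a `driver_module` (or character vector of genes).
#' @param min_genes minimum number of co-mutated module genes per case;
#'   default 2.
#' @param frac_threshold per-gene case-fraction cut; default 0.10.
#' @return A list with `site_counts` (data.frame: `site`, `n_cases`,
#'   `n_co_mutated`) and `gene_fractions` (data.frame: `site`, `gene`,
#'   `fraction`, `high`).
#' @export
module_case_counts <- function(catalog, module, min_genes = 2,
                               frac_threshold = 0.10) {
  genes <- if (inherits(module, "driver_module")) module$members
           else toupper(module)
  rec <- catalog$records[catalog$records$gene %in% genes, , drop = FALSE]
  all_cases <- catalog_cases(catalog)
  site_of <- catalog$site_of_case
  site_vec <- if (is.null(site_of)) {
    stats::setNames(rep("all", length(all_cases)), all_cases)
  } else {
    s <- site_of[all_cases]
    s[is.na(s)] <- "unlabeled"
    stats::setNames(s, all_cases)
  }
  sites <- sort(unique(site_vec))
  sc <- list(); gf <- list()
  for (st in sites) {
    cases_st <- names(site_vec)[site_vec == st]
    rec_st <- rec[rec$case_id %in% cases_st, , drop = FALSE]
    per_case <- table(rec_st$case_id)
    sc[[st]] <- data.frame(site = st, n_cases = length(cases_st),
                           n_co_mutated = sum(per_case >= min_genes),
                           stringsAsFactors = FALSE)
    frac <- vapply(genes, function(g)
      sum(rec_st$gene == g) / length(cases_st), numeric(1))
    gf[[st]] <- data.frame(site = st, gene = genes, fraction = frac,
                           high = frac > frac_threshold,
                           stringsAsFactors = FALSE, row.names = NULL)
  }
  list(site_counts = do.call(rbind, c(sc, list(make.row.names = FALSE))),
       gene_fractions = do.call(rbind, c(gf, list(make.row.names = FALSE))))
}
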
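#' Pipeline configuration
#'
#' Collects every tunable of the two-step method with the method's stated
#' defaults: heat-kernel affinity `delta = 5`, `t = 100`; PageRank damping
#' 0.85; above-mean gene selection (or `top_k` with `k = 200`); infrequency
#' threshold 100 cases; annealing `T0 = 10`, `T_low = 0.01`, cooling 0.9,
#' 8 modules; 1000 exceeding-value samples at `alpha = 0.05`; raw
#' (summed-weight) path costs; unscaled features (the affinity parameters
#' are coupled to raw feature magnitudes, see [build_feature_matrix()]).
#'
#' @param scaling feature scaling mode.
#' @param cost path-cost semantics.
#' @param delta,t Laplacian-score affinity parameters.
#' @param damping PageRank damping factor.
#' @param selection gene-selection rule.
#' @param k top-k size when `selection = "top_k"`, and the bio-graph size
#'   cap.
#' @param freq_threshold infrequent-gene case-count threshold.
#' @param T0,T_low,cooling,max_modules,restarts annealing controls.
#' @param ev_samples,alpha exceeding-value test controls.
#' @param seed global seed; per-stage seeds are derived from it by fixed
#'   offsets so stages are individually reproducible.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(scaling = c("none", "minmax", "zscore"),
                            cost = c("raw", "inverse"),
                            delta = 5, t = 100, damping = 0.85,
                            selection = c("above_mean", "top_k"), k = 200,
                            freq_threshold = 100,
                            T0 = 10, T_low = 0.01, cooling = 0.9,
                            max_modules = 8, restarts = 1,
                            ev_samples = 1000, alpha = 0.05,
                            seed = 1L) {
  structure(list(scaling = match.arg(scaling), cost = match.arg(cost),
                 delta = delta, t = t, damping = damping,
                 selection = match.arg(selection), k = k,
                 freq_threshold = freq_threshold,
                 T0 = T0, T_low = T_low, cooling = cooling,
                 max_modules = max_modules, restarts = restarts,
                 ev_samples = ev_samples, alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# fixed per-stage seed offsets keep stages individually reproducible
stage_seed <- function(config, stage) {
  offsets <- c(modules = 101L, ev = 211L)
  (config$seed + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the two-step pipeline end to end
#'
#' Mutation network -> six features -> Laplacian scoring -> gene selection
#' -> biological graph -> MG module search -> exceeding-value test, plus
#' optional benchmark metrics and gene-set enrichment. Intermediate
#' artifacts and a run manifest are written when `out_dir` is given.
#'
#' @param catalog a [mutation_catalog()].
#' @param ppi an `interaction_table`, or `NULL` (bio-graph edges then come
#'   from annotations alone).
#' @param annotations an `annotation_table`, or `NULL`.
#' @param gene_sets a `gene_set_collection` for enrichment and benchmark
#'   metrics, or `NULL`.
#' @param config a [pipeline_config()].
#' @param out_dir directory for artifacts (created if needed), or `NULL`.
#' @return A list with `scores` (annotated `gene_score_table`), `selected`
#'   (character), `bio_graph`, `modules` (with `ev` filled in),
#'   `enrichment` (data.frame or `NULL`) and `benchmarks` (data.frame or
#'   `NULL`).
#' @export
run_pipeline <- function(catalog, ppi = NULL, annotations = NULL,
                         gene_sets = NULL, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(catalog, "mutation_catalog"),
            inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  net <- stage("mutation_network", build_mutation_network(catalog))
  message(sprintf("mutation network: %d genes, %d edges",
                  igraph::vcount(net), igraph::ecount(net)))
  X <- stage("features",
             build_feature_matrix(net, scaling = config$scaling,
                                  cost = config$cost, d = config$damping))
  scores <- stage("lsfs",
                  laplacian_scores(X, params = lsfs_params(config$delta,
                                                           config$t)))
  scores <- annotate_scores(scores, catalog, mode = config$selection,
                            k = config$k,
                            freq_threshold = config$freq_threshold)
  selected <- scores$gene[scores$selected]
  message(sprintf("selected %d of %d genes (%s)", length(selected),
                  nrow(scores), config$selection))

  bio <- NULL
  modules <- list()
  if (length(selected) >= 2L && (!is.null(ppi) || !is.null(annotations))) {
    top <- utils::head(selected, config$k)
    bio <- stage("bio_graph", build_bio_graph(top, scores, ppi, annotations))
    mgp <- mg_params(T0 = config$T0, T_low = config$T_low,
                     cooling = config$cooling,
                     max_modules = config$max_modules,
                     restarts = config$restarts,
                     rng_seed = stage_seed(config, "modules"))
    modules <- stage("module_search", find_modules(bio, mgp))
    message(sprintf("extracted %d modules (sizes %s)", length(modules),
                    paste(vapply(modules, function(m) length(m$members),
                                 integer(1)), collapse = ", ")))
    ev_seed <- stage_seed(config, "ev")
    for (i in seq_along(modules)) {
      res <- stage("ev_test",
                   ev_test(modules[[i]], bio,
                           n_samples = config$ev_samples,
                           alpha = config$alpha,
                           rng_seed = ev_seed + i))
      modules[[i]]$ev <- res$ev
    }
  }

  enrichment <- NULL
  benchmarks <- NULL
  if (!is.null(gene_sets)) {
    universe <- catalog_genes(catalog)
    if (length(modules) > 0L) {
      enrichment <- stage("enrichment",
                          enrich_modules(modules, gene_sets, universe))
    }
    benchmarks <- stage("benchmarks", local({
      rows <- lapply(names(gene_sets), function(nm) {
        cc <- confusion_counts(selected, gene_sets[[nm]]$genes, universe)
        m <- precision_recall_f(cc)
        data.frame(benchmark = nm, tp = cc$tp, tn = cc$tn, fp = cc$fp,
                   fn = cc$fn, precision = m[["precision"]],
                   recall = m[["recall"]], f = m[["f"]],
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    }))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_gene_graph(net, file.path(out_dir, "mutation_network.tsv"))
    write_feature_matrix(X, file.path(out_dir, "features.tsv"))
    write_gene_scores(scores, file.path(out_dir, "scores.tsv"))
    if (length(modules) > 0L) {
      write_modules(modules, file.path(out_dir, "modules.json"))
    }
    if (!is.null(benchmarks)) {
      utils::write.table(benchmarks, file.path(out_dir, "benchmarks.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(enrichment)) {
      utils::write.table(enrichment, file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    manifest <- c(unclass(config),
                  list(n_genes = nrow(scores), n_selected = length(selected),
                       n_modules = length(modules)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(scores = scores, selected = selected, bio_graph = bio,
       modules = modules, enrichment = enrichment, benchmarks = benchmarks)
}
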
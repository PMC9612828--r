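#' Read gene sets in GMT format
#'
#' Standard MSigDB-style GMT: one set per line, tab-separated fields
#' `name`, `description`, then the member gene symbols. Gene symbols are
#' upper-cased; duplicate members collapse.
#'
#' @param path path to a GMT file.
#' @return A named list of class `gene_set_collection`; each element is a
#'   list with `description` (string) and `genes` (character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file '", path, "' is empty", call. = FALSE)
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    f <- trimws(f)
    if (length(f) < 3L) {
      stop("malformed GMT line ", i, " in '", path,
           "': fewer than 3 tab-separated fields", call. = FALSE)
    }
    genes <- unique(toupper(f[-(1:2)][nzchar(f[-(1:2)])]))
    if (length(genes) == 0L) {
      stop("malformed GMT line ", i, " in '", path, "': empty gene set",
           call. = FALSE)
    }
    if (f[[1]] %in% names(sets)) {
      stop("duplicate gene-set name '", f[[1]], "' at GMT line ", i,
           call. = FALSE)
    }
    sets[[f[[1]]]] <- list(description = f[[2]], genes = sort(genes))
  }
  structure(sets, class = "gene_set_collection")
}

#' Read a protein-protein interaction edge list
#'
#' Headerless two-column TSV of gene-symbol pairs. Pairs are stored
#' unordered (symmetrized), self-pairs are dropped, symbols upper-cased.
#'
#' @param path path to the edge-list file.
#' @return A two-column data.frame (`gene_a`, `gene_b`) of class
#'   `interaction_table` with `gene_a < gene_b` lexicographically and no
#'   duplicate pairs.
#' @export
read_interactions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2L) {
    stop("interaction file '", path, "' must have 2 tab-separated columns",
         call. = FALSE)
  }
  a <- toupper(trimws(as.character(df[[1]])))
  b <- toupper(trimws(as.character(df[[2]])))
  keep <- nzchar(a) & nzchar(b) & a != b
  lo <- pmin(a[keep], b[keep])
  hi <- pmax(a[keep], b[keep])
  out <- unique(data.frame(gene_a = lo, gene_b = hi,
                           stringsAsFactors = FALSE))
  out <- out[order(out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_table", "data.frame")
  out
}

#' Read gene-to-biological-process annotations
#'
#' Headerless two-column TSV: gene symbol, process/term id. Genes absent
#' from the table simply have no annotation (lookups return the empty set).
#'
#' @param path path to the annotation file.
#' @return A named list of class `annotation_table` mapping each gene to a
#'   character vector of term ids.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2L) {
    stop("annotation file '", path, "' must have 2 tab-separated columns",
         call. = FALSE)
  }
  g <- toupper(trimws(as.character(df[[1]])))
  term <- trimws(as.character(df[[2]]))
  keep <- nzchar(g) & nzchar(term)
  ann <- lapply(split(term[keep], g[keep]), function(x) sort(unique(x)))
  ann <- ann[order(names(ann))]
  structure(ann, class = "annotation_table")
}

#' Look up annotation terms for genes
#'
#' @param annotations an `annotation_table` from [read_annotations()].
#' @param gene gene symbol.
#' @return Character vector of term ids (empty when the gene is absent).
#' @export
annotation_terms <- function(annotations, gene) {
  t <- annotations[[toupper(gene)]]
  if (is.null(t)) character(0) else t
}

#' Write and read the per-gene score table
#'
#' The on-disk dialect is a TSV with one row per gene: the six raw feature
#' columns, the Laplacian score `ls`, its `rank`, and the `selected` and
#' `infrequent` flags plus `mutation_count`.
#'
#' @param scores a `gene_score_table` data.frame (see [laplacian_scores()]).
#' @param path output (input) path.
#' @return `write_gene_scores()`: `path` invisibly;
#'   `read_gene_scores()`: the score data.frame.
#' @export
write_gene_scores <- function(scores, path) {
  stopifnot(is.data.frame(scores), "gene" %in% names(scores))
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_scores
#' @export
read_gene_scores <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  if (!"gene" %in% names(df)) {
    stop("score file '", path, "' lacks a 'gene' column", call. = FALSE)
  }
  for (fl in intersect(c("selected", "infrequent"), names(df))) {
    df[[fl]] <- as.logical(df[[fl]])
  }
  class(df) <- c("gene_score_table", "data.frame")
  df
}

#' Serialize driver modules
#'
#' Modules are written as a JSON array of objects with fields `seed`,
#' `members`, `mean_ls`, `density` and `ev` (`null` when the exceeding-value
#' test has not been run).
#'
#' @param modules a list of `driver_module` objects (see [find_modules()]).
#' @param path output (input) path.
#' @return `write_modules()`: `path` invisibly; `read_modules()`: the list
#'   of modules.
#' @export
write_modules <- function(modules, path) {
  payload <- lapply(modules, function(m) {
    list(seed = m$seed, members = as.list(m$members),
         mean_ls = m$mean_ls, density = m$density,
         ev = if (is.null(m$ev) || is.na(m$ev)) NULL else m$ev)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_modules
#' @export
read_modules <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path)
  lapply(raw, function(m) {
    structure(list(seed = m$seed,
                   members = unlist(m$members, use.names = FALSE),
                   mean_ls = as.numeric(m$mean_ls),
                   density = as.numeric(m$density),
                   ev = if (is.null(m$ev)) NA_real_ else as.numeric(m$ev)),
              class = "driver_module")
  })
}
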
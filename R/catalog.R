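#' Mutation catalogs
#'
#' A mutation catalog is the per-case list of mutated genes: a set of
#' `(case_id, gene)` incidence records, optionally annotated with the primary
#' site of each case. It is the raw input of the whole pipeline; `C(g)`, the
#' set of cases in which gene `g` is mutated, is derived from it.
#'
#' Gene symbols are normalized to upper case on ingest and duplicate
#' `(case, gene)` pairs collapse to a single incidence record: a gene hit by
#' several distinct variants in one case still counts as mutated once in
#' that case.
#'
#' @param case_id character vector of case identifiers.
#' @param gene character vector of gene symbols (same length as `case_id`).
#' @param site optional character vector of primary sites per record, or a
#'   named character vector mapping case id to site.
#' @return An object of class `mutation_catalog`: a list with
#'   * `records`: data.frame with columns `case_id`, `gene` (deduplicated,
#'     genes upper-cased, sorted),
#'   * `site_of_case`: named character vector mapping case id to primary
#'     site, or `NULL` when no site information is available.
#' @examples
#' cat <- mutation_catalog(c("c1", "c1", "c2"), c("tp53", "TP53", "PTEN"))
#' nrow(cat$records)  # 2: the duplicate (c1, TP53) pair collapsed
#' @export
mutation_catalog <- function(case_id, gene, site = NULL) {
  case_id <- as.character(case_id)
  gene <- toupper(trimws(as.character(gene)))
  if (length(case_id) != length(gene)) {
    stop("`case_id` and `gene` must have the same length", call. = FALSE)
  }
  keep <- nzchar(gene) & nzchar(case_id)
  if (!any(keep)) {
    stop("mutation catalog has no usable (case, gene) records", call. = FALSE)
  }
  site_of_case <- NULL
  if (!is.null(site)) {
    if (!is.null(names(site))) {
      site_of_case <- as.character(site)
      names(site_of_case) <- names(site)
    } else {
      if (length(site) != length(case_id)) {
        stop("per-record `site` must match the length of `case_id`",
             call. = FALSE)
      }
      s <- as.character(site)[keep]
      cs <- case_id[keep]
      first <- !duplicated(cs)
      site_of_case <- s[first]
      names(site_of_case) <- cs[first]
    }
    site_of_case <- site_of_case[!is.na(site_of_case) & nzchar(site_of_case)]
    if (length(site_of_case) == 0L) site_of_case <- NULL
  }
  rec <- unique(data.frame(case_id = case_id[keep], gene = gene[keep],
                           stringsAsFactors = FALSE))
  rec <- rec[order(rec$gene, rec$case_id), , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(records = rec, site_of_case = site_of_case),
            class = "mutation_catalog")
}

#' @export
print.mutation_catalog <- function(x, ...) {
  cat(sprintf("mutation_catalog: %d records, %d genes, %d cases%s\n",
              nrow(x$records), length(catalog_genes(x)),
              length(catalog_cases(x)),
              if (is.null(x$site_of_case)) "" else
                sprintf(", %d sites", length(unique(x$site_of_case)))))
  invisible(x)
}

#' Genes and cases of a catalog
#'
#' @param catalog a [mutation_catalog()].
#' @return `catalog_genes()`: sorted character vector of distinct gene
#'   symbols; `catalog_cases()`: sorted character vector of distinct case
#'   ids; `gene_cases()`: named list mapping each gene to the character
#'   vector of cases in which it is mutated (`C(g)`);
#'   `gene_case_counts()`: named integer vector `|C(g)|`.
#' @export
catalog_genes <- function(catalog) {
  stopifnot(inherits(catalog, "mutation_catalog"))
  sort(unique(catalog$records$gene))
}

#' @rdname catalog_genes
#' @export
catalog_cases <- function(catalog) {
  stopifnot(inherits(catalog, "mutation_catalog"))
  sort(unique(catalog$records$case_id))
}

#' @rdname catalog_genes
#' @export
gene_cases <- function(catalog) {
  stopifnot(inherits(catalog, "mutation_catalog"))
  split(catalog$records$case_id, catalog$records$gene)
}

#' @rdname catalog_genes
#' @export
gene_case_counts <- function(catalog) {
  stopifnot(inherits(catalog, "mutation_catalog"))
  cc <- vapply(gene_cases(catalog), length, integer(1))
  cc[order(names(cc))]
}

#' Read a mutation catalog from disk
#'
#' Two dialects are supported. The canonical `tsv` dialect is a
#' tab-separated file with header columns `case_id`, `gene` and an optional
#' `primary_site`. The `maf` dialect is a convenience reader for MAF-style
#' mutation tables: it requires `Hugo_Symbol` and `Tumor_Sample_Barcode`
#' columns and treats every variant row as evidence that the gene is mutated
#' in that sample (no variant-classification filtering).
#'
#' @param path path to the file.
#' @param dialect `"tsv"` (default) or `"maf"`.
#' @return A [mutation_catalog()].
#' @export
read_mutation_catalog <- function(path, dialect = c("tsv", "maf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, comment.char = "#",
                      check.names = FALSE, quote = ""),
    error = function(e) stop("cannot parse catalog file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (nrow(df) == 0L) stop("catalog file '", path, "' is empty", call. = FALSE)
  need <- if (dialect == "tsv") c("case_id", "gene")
          else c("Tumor_Sample_Barcode", "Hugo_Symbol")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("catalog file '", path, "' lacks required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (dialect == "tsv") {
    site <- if ("primary_site" %in% names(df)) df$primary_site else NULL
    mutation_catalog(df$case_id, df$gene, site)
  } else {
    mutation_catalog(df$Tumor_Sample_Barcode, df$Hugo_Symbol, NULL)
  }
}

#' Write a mutation catalog as canonical TSV
#'
#' @param catalog a [mutation_catalog()].
#' @param path output path; a tab-separated file with header
#'   `case_id`, `gene` and, when site labels exist, `primary_site`.
#' @return `path`, invisibly.
#' @export
write_mutation_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "mutation_catalog"))
  df <- catalog$records
  if (!is.null(catalog$site_of_case)) {
    df$primary_site <- unname(catalog$site_of_case[df$case_id])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict a catalog to one primary site
#'
#' Keeps the cases whose primary site matches `site` (exact,
#' case-insensitive). Used to build the per-cancer mutation networks.
#'
#' @param catalog a [mutation_catalog()] with site labels.
#' @param site primary-site string to keep.
#' @return A [mutation_catalog()] restricted to the matching cases. When no
#'   case matches, an empty catalog is returned with a warning.
#' @export
filter_by_site <- function(catalog, site) {
  stopifnot(inherits(catalog, "mutation_catalog"))
  if (is.null(catalog$site_of_case)) {
    stop("catalog has no primary-site labels", call. = FALSE)
  }
  keep_cases <- names(catalog$site_of_case)[
    tolower(catalog$site_of_case) == tolower(site)]
  rec <- catalog$records[catalog$records$case_id %in% keep_cases, ,
                         drop = FALSE]
  if (nrow(rec) == 0L) {
    warning("no case with primary site '", site,
            "'; returning an empty catalog", call. = FALSE)
    out <- structure(list(records = rec[0, , drop = FALSE],
                          site_of_case = NULL),
                     class = "mutation_catalog")
    return(out)
  }
  mutation_catalog(rec$case_id, rec$gene,
                   catalog$site_of_case[intersect(names(catalog$site_of_case),
                                                  keep_cases)])
}
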
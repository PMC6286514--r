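# GAF parsing and annotation propagation (true-path rule).

#' Parse a GAF association file
#'
#' Reads GAF 2.1/2.2 (17 tab-separated columns, "!"-prefixed comments) into an
#' annotation set. NOT-qualified lines are excluded (a NOT annotation must not
#' be treated as positive evidence), lines citing terms absent from the DAG
#' (e.g. obsolete) are dropped with a warning counter, and duplicate
#' (gene, term) lines merge their reference and evidence sets. Column 2
#' (DB object ID) is the gene id; column 3 (symbol) is kept as a display
#' alias.
#'
#' @param path Path to a GAF file.
#' @param dag A `go_dag` used to validate term accessions (alternate ids are
#'   resolved to primary ids).
#' @param exclude_evidence Optional character vector of evidence codes to
#'   drop (e.g. `"IEA"`). Default: keep all.
#' @return An object of class `annotation_set` with elements `direct`
#'   (data.frame gene_id, symbol, term_id, evidence, references, qualifier)
#'   and, after [propagate_annotations()], `propagated` (named list
#'   gene_id -> term ids).
#' @export
parse_gaf <- function(path, dag, exclude_evidence = character()) {
  if (!file.exists(path)) stop("cannot read GAF file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (length(lines) == 0) {
    direct <- data.frame(gene_id = character(), symbol = character(),
                         term_id = character(), evidence = character(),
                         references = character(), qualifier = character(),
                         stringsAsFactors = FALSE)
    return(structure(list(direct = direct, propagated = NULL, dag_ns = term_namespaces(dag)),
                     class = "annotation_set"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 15)
  if (length(bad) > 0) {
    stop(sprintf("malformed GAF line %d: expected >= 15 columns, got %d",
                 bad[[1]], nf[[bad[[1]]]]))
  }
  col <- function(i) vapply(fields, `[`, "", i)
  df <- data.frame(gene_id = col(2), symbol = col(3), qualifier = col(4),
                   term_id = col(5), references = col(6), evidence = col(7),
                   stringsAsFactors = FALSE)
  df <- df[!grepl("(^|\\|)NOT($|\\|)", df$qualifier), , drop = FALSE]
  if (length(exclude_evidence) > 0) {
    df <- df[!(df$evidence %in% exclude_evidence), , drop = FALSE]
  }
  known <- df$term_id %in% dag$terms$term_id
  alt <- !known & df$term_id %in% names(dag$alt_ids)
  df$term_id[alt] <- unname(dag$alt_ids[df$term_id[alt]])
  drop_n <- sum(!known & !alt)
  if (drop_n > 0) {
    warning(sprintf("parse_gaf: dropped %d line(s) citing terms absent from the ontology", drop_n))
  }
  df <- df[known | alt, , drop = FALSE]
  # merge duplicate (gene, term) rows: union references and evidence codes
  key <- paste(df$gene_id, df$term_id, sep = "\r")
  merge_set <- function(x) {
    paste(sort(unique(unlist(strsplit(x, "|", fixed = TRUE)))), collapse = "|")
  }
  direct <- data.frame(
    gene_id = vapply(split(df$gene_id, key), `[`, "", 1L),
    symbol = vapply(split(df$symbol, key), `[`, "", 1L),
    term_id = vapply(split(df$term_id, key), `[`, "", 1L),
    evidence = vapply(split(df$evidence, key), merge_set, ""),
    references = vapply(split(df$references, key), merge_set, ""),
    qualifier = vapply(split(df$qualifier, key), `[`, "", 1L),
    stringsAsFactors = FALSE, row.names = NULL)
  direct <- direct[order(direct$gene_id, direct$term_id), , drop = FALSE]
  rownames(direct) <- NULL
  structure(list(direct = direct, propagated = NULL, dag_ns = term_namespaces(dag)),
            class = "annotation_set")
}

term_namespaces <- function(dag) {
  stats::setNames(dag$terms$namespace, dag$terms$term_id)
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("annotation_set: %d direct annotations, %d genes%s\n",
              nrow(x$direct), length(unique(x$direct$gene_id)),
              if (is.null(x$propagated)) " (not propagated)" else " (propagated)"))
  invisible(x)
}

#' Propagate annotations up the ontology (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to every ancestor of
#' that term; enrichment counting is only meaningful on the propagated sets.
#' Fills the `propagated` element: for each gene, the union over its direct
#' terms t of t plus all ancestors of t.
#'
#' @param annots An `annotation_set` from [parse_gaf()].
#' @param dag The `go_dag` the annotations refer to.
#' @return The `annotation_set` with `propagated` filled. Idempotent.
#' @export
propagate_annotations <- function(annots, dag) {
  stopifnot(inherits(annots, "annotation_set"))
  anc <- all_ancestors(dag)
  by_gene <- split(annots$direct$term_id, annots$direct$gene_id)
  annots$propagated <- lapply(by_gene, function(ts) {
    ts <- unique(ts)
    unique(c(ts, unlist(anc[ts], use.names = FALSE)))
  })
  annots
}

#' Invert propagated annotations into a term -> genes index
#'
#' @param annots A propagated `annotation_set`.
#' @param namespace One of the three GO namespaces; only terms of this
#'   namespace appear in the index.
#' @return Named list term_id -> character vector of gene ids. Terms
#'   annotating no gene are absent.
#' @export
term_gene_index <- function(annots, namespace) {
  stopifnot(inherits(annots, "annotation_set"))
  if (is.null(annots$propagated)) stop("annotations are not propagated; call propagate_annotations() first")
  namespace <- match.arg(namespace, GO_NAMESPACES)
  genes <- rep(names(annots$propagated), lengths(annots$propagated))
  terms <- unlist(annots$propagated, use.names = FALSE)
  keep <- annots$dag_ns[terms] == namespace
  if (!any(keep)) return(stats::setNames(list(), character(0)))
  lapply(split(genes[keep], terms[keep]), unique)
}

#' Genes with at least one propagated annotation in a namespace
#'
#' @inheritParams term_gene_index
#' @return Character vector of gene ids.
#' @export
namespace_universe <- function(annots, namespace) {
  stopifnot(inherits(annots, "annotation_set"))
  if (is.null(annots$propagated)) stop("annotations are not propagated; call propagate_annotations() first")
  namespace <- match.arg(namespace, GO_NAMESPACES)
  has <- vapply(annots$propagated,
                function(ts) any(annots$dag_ns[ts] == namespace, na.rm = TRUE),
                logical(1))
  names(annots$propagated)[has]
}
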
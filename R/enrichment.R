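# Over-representation testing: hypergeometric tail on the 2x2 contingency
# table, Benjamini-Hochberg FDR control, background construction.
#
# For a term annotating n of the M background genes, with N input genes in
# the background of which x carry the term, the one-sided p-value is
# P(X >= x) for X ~ Hypergeometric(M, n, N) — the upper tail of the Fisher
# exact test on the table
#
#                        in input   not in input   total
#   annotated               x          n - x         n
#   not annotated         N - x    M - N - (n-x)   M - n
#   total                   N          M - N         M

#' Build the enrichment background
#'
#' The background (gene universe) against which over-representation is
#' measured. Three kinds: `all_annotated` (every gene with at least one
#' propagated annotation in the namespace), `custom_list` (a user gene set),
#' or `expression_threshold` (genes whose expression in a chosen cell/tissue
#' type exceeds `tpm_threshold`, default 1 TPM). Custom and expression
#' backgrounds are always intersected with the namespace annotation universe
#' so that the total M counts only genes that can contribute to some term.
#' Input genes absent from the resulting background take no part in the
#' counts; they are reported in the `excluded_input` attribute and survive
#' as orphan nodes in the graph.
#'
#' @param kind One of `"all_annotated"`, `"custom_list"`,
#'   `"expression_threshold"`.
#' @param input_genes Character vector of resolved input primary ids.
#' @param annots Propagated `annotation_set`.
#' @param namespace GO namespace.
#' @param custom_genes For `custom_list`: character vector of gene ids.
#' @param expression For `expression_threshold`: data.frame, first column
#'   gene primary id, remaining columns cell/tissue types, values TPM.
#' @param celltype Column name in `expression`.
#' @param tpm_threshold Expression cutoff; genes strictly above it enter the
#'   background. Default 1 TPM.
#' @return Object of class `go_background`: list(kind, genes, source) with
#'   attribute `excluded_input`.
#' @export
build_background <- function(kind = c("all_annotated", "custom_list", "expression_threshold"),
                             input_genes, annots, namespace,
                             custom_genes = NULL, expression = NULL,
                             celltype = NULL, tpm_threshold = 1.0) {
  kind <- match.arg(kind)
  universe <- namespace_universe(annots, namespace)
  if (kind == "all_annotated") {
    genes <- universe
    source <- "all annotated genes"
  } else if (kind == "custom_list") {
    if (is.null(custom_genes)) stop("custom_list background requires custom_genes")
    genes <- intersect(custom_genes, universe)
    source <- "custom gene list"
  } else {
    if (is.null(expression) || is.null(celltype)) {
      stop("expression_threshold background requires an expression table and a celltype")
    }
    if (!celltype %in% names(expression)[-1]) {
      stop("unknown celltype in expression table: ", celltype)
    }
    expressed <- expression[[1]][expression[[celltype]] > tpm_threshold]
    genes <- intersect(expressed, universe)
    source <- sprintf("%s@TPM>%g", celltype, tpm_threshold)
  }
  if (length(genes) == 0) stop("resulting background is empty")
  excluded <- setdiff(input_genes, genes)
  if (length(excluded) > 0) {
    message(sprintf("background: %d input gene(s) outside the background are excluded from counting: %s",
                    length(excluded), paste(utils::head(excluded, 10), collapse = ", ")))
  }
  structure(list(kind = kind, genes = genes, source = source),
            class = "go_background", excluded_input = excluded)
}

#' Contingency table for one term
#'
#' @param term_id GO accession.
#' @param input_genes Input gene ids (will be intersected with the background).
#' @param background A `go_background` (or character vector of gene ids).
#' @param index Term -> genes index from [term_gene_index()].
#' @return Named list (x, n, N, M, genes) where `genes` are the input genes
#'   annotated with the term.
#' @export
contingency_table <- function(term_id, input_genes, background, index) {
  bg <- if (inherits(background, "go_background")) background$genes else background
  N_genes <- intersect(input_genes, bg)
  ann <- intersect(index[[term_id]], bg)
  hit <- intersect(ann, N_genes)
  list(x = length(hit), n = length(ann), N = length(N_genes), M = length(bg),
       genes = sort(hit))
}

validate_table <- function(x, n, N, M) {
  ok <- is.finite(x) & is.finite(n) & is.finite(N) & is.finite(M) &
    x >= 0 & n >= 0 & N >= 0 & M >= 0 &
    x <= pmin(n, N) & n <= M & N <= M & x >= n + N - M
  if (!all(ok)) stop("invalid contingency table: counts violate 0 <= x <= min(n, N), n <= M, N <= M")
}

#' Hypergeometric over-representation p-value
#'
#' Upper tail P(X >= x) for X ~ Hypergeometric(M, n, N): the probability of
#' drawing at least x term-annotated genes when N genes are sampled without
#' replacement from a background of M genes, n of which carry the term.
#' Equivalent to the one-sided Fisher exact test on the contingency table.
#' Vectorized over table components; numerically safe for M up to 1e5.
#'
#' @param table Named list or data.frame with components x, n, N, M (as from
#'   [contingency_table()]); alternatively pass the counts via `...` is not
#'   supported — build the table first.
#' @return p-value(s) in (0, 1]; exactly 1 when x = 0.
#' @export
#' @examples
#' hypergeom_pvalue(list(x = 4, n = 5, N = 4, M = 10))  # 5/210
hypergeom_pvalue <- function(table) {
  x <- table$x; n <- table$n; N <- table$N; M <- table$M
  validate_table(x, n, N, M)
  # P(X >= x) = 1 - P(X <= x - 1)
  stats::phyper(x - 1, m = n, n = M - n, k = N, lower.tail = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted values q_(i) = min_{j >= i} p_(j) * m / j, capped at 1,
#' returned in input order.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Adjusted q-values, same length and order.
#' @export
fdr_adjust <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Run GO term enrichment analysis
#'
#' Tests every namespace term in the multiple-testing family (by default all
#' terms annotating at least one input gene; optionally every term annotating
#' at least one background gene), adjusts p-values with Benjamini-Hochberg,
#' filters to q <= `q_threshold`, and returns results sorted ascending by
#' (q, p, term_id).
#'
#' @param input_genes Character vector of resolved input gene ids.
#' @param background A `go_background` from [build_background()].
#' @param annots Propagated `annotation_set`.
#' @param dag The `go_dag`.
#' @param namespace GO namespace.
#' @param q_threshold FDR threshold in (0, 1). The CLI restricts this to
#'   0.05 / 0.01 / 0.001 / 0.0001; the API accepts any value in (0, 1).
#' @param family `"represented"` (terms with x >= 1, default) or
#'   `"annotated"` (terms with n >= 1).
#' @return data.frame with one row per surviving term: term_id, name,
#'   namespace, p, q, x, n, N, M and a list-column `genes` of the annotated
#'   input genes. The full tested family (pre-filter) is attached as
#'   attribute `tested`.
#' @export
run_enrichment <- function(input_genes, background, annots, dag, namespace,
                           q_threshold = 0.05, family = c("represented", "annotated")) {
  family <- match.arg(family)
  if (!(q_threshold > 0 && q_threshold < 1)) stop("q_threshold must lie in (0, 1)")
  index <- term_gene_index(annots, namespace)
  bg <- background$genes
  input_bg <- intersect(input_genes, bg)
  if (length(input_bg) == 0) stop("no input genes left in the background")

  idx_bg <- lapply(index, intersect, bg)
  n_vec <- lengths(idx_bg)
  x_sets <- lapply(idx_bg, intersect, input_bg)
  x_vec <- lengths(x_sets)
  keep <- if (family == "represented") x_vec >= 1L else n_vec >= 1L
  terms <- names(index)[keep]
  if (length(terms) == 0) {
    res <- empty_enrichment()
    attr(res, "tested") <- empty_enrichment()
    return(res)
  }
  N <- length(input_bg); M <- length(bg)
  p <- hypergeom_pvalue(list(x = x_vec[keep], n = n_vec[keep], N = N, M = M))
  q <- fdr_adjust(p)
  tested <- data.frame(term_id = terms,
                       name = dag$terms[terms, "name"],
                       namespace = namespace,
                       p = unname(p), q = unname(q),
                       x = unname(x_vec[keep]), n = unname(n_vec[keep]),
                       N = N, M = M, stringsAsFactors = FALSE)
  tested$genes <- lapply(x_sets[keep], sort)
  ord <- order(tested$q, tested$p, tested$term_id)
  tested <- tested[ord, , drop = FALSE]
  rownames(tested) <- NULL
  res <- tested[tested$q <= q_threshold, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "tested") <- tested
  res
}

empty_enrichment <- function() {
  df <- data.frame(term_id = character(), name = character(),
                   namespace = character(), p = numeric(), q = numeric(),
                   x = integer(), n = integer(), N = integer(), M = integer(),
                   stringsAsFactors = FALSE)
  df$genes <- list()
  df
}
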
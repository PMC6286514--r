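# GO-slim ('annotation') analysis: map propagated gene annotations onto a
# fixed subset of the ontology instead of testing for enrichment.

#' Resolve a GO subset specification
#'
#' Either a named subset tagged in the OBO (e.g. `"goslim_generic"`) or a
#' custom list of GO accessions (a file with one id per line, `#` comments
#' allowed, or a character vector). Terms are restricted to the analysis
#' namespace; unknown, obsolete or foreign-namespace ids in a custom list are
#' dropped with a warning each.
#'
#' @param spec_input Subset label, file path, or character vector of GO ids.
#' @param dag A `go_dag`.
#' @param namespace Analysis namespace.
#' @return Object of class `slim_spec`: list(kind, name, terms).
#' @export
resolve_slim <- function(spec_input, dag, namespace) {
  namespace <- match.arg(namespace, GO_NAMESPACES)
  ns_of <- term_namespaces(dag)
  if (length(spec_input) == 1 && !grepl("^GO:", spec_input) &&
      !file.exists(spec_input)) {
    terms <- subset_terms(dag, spec_input)
    terms <- terms[ns_of[terms] == namespace]
    kind <- "named_subset"; name <- spec_input
  } else {
    ids <- if (length(spec_input) == 1 && file.exists(spec_input)) {
      lines <- trimws(readLines(spec_input, warn = FALSE))
      lines[nzchar(lines) & !startsWith(lines, "#")]
    } else {
      spec_input
    }
    terms <- character(0)
    for (id in unique(ids)) {
      if (!id %in% dag$terms$term_id && !id %in% names(dag$alt_ids)) {
        warning("slim: unknown or obsolete term dropped: ", id)
        next
      }
      prim <- resolve_term_id(dag, id)
      if (ns_of[[prim]] != namespace) {
        warning(sprintf("slim: term %s is in namespace %s, not %s; dropped",
                        id, ns_of[[prim]], namespace))
        next
      }
      terms <- c(terms, prim)
    }
    kind <- "custom_list"
    name <- if (length(spec_input) == 1) spec_input else "custom list"
  }
  if (length(terms) == 0) stop("slim specification resolves to no usable terms")
  structure(list(kind = kind, name = name, terms = sort(unique(terms))),
            class = "slim_spec")
}

#' Map genes onto a GO subset
#'
#' For each input gene, the intersection of its propagated annotations with
#' the slim terms. Genes with an empty intersection map to an empty set and
#' become orphan gene nodes in the graph.
#'
#' @param input_genes Character vector of gene ids.
#' @param annots Propagated `annotation_set`.
#' @param slim A `slim_spec` from [resolve_slim()].
#' @return Named list gene_id -> character vector of slim term ids (possibly
#'   empty), one element per input gene.
#' @export
annotate_against_slim <- function(input_genes, annots, slim) {
  stopifnot(inherits(slim, "slim_spec"))
  if (is.null(annots$propagated)) stop("annotations are not propagated; call propagate_annotations() first")
  out <- lapply(input_genes, function(g) {
    ts <- annots$propagated[[g]]
    if (is.null(ts)) character(0) else sort(intersect(ts, slim$terms))
  })
  stats::setNames(out, input_genes)
}
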
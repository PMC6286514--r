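# Construction of the mixed gene-term output graph.
#
# Three constraints govern the structure: (1) term-term edges connect
# displayed terms that stand in an ancestor relationship, then the edge set
# is transitively reduced so reachability among displayed terms is preserved
# with a minimal number of edges; (2) each gene attaches only to its most
# specific displayed terms; (3) anything left unconnected — slim terms no
# gene maps to, submitted tokens that failed to resolve — stays in the graph
# as an orphan node. All edges run general -> specific, and term -> gene.

#' Select the terms to display
#'
#' @param mode `"enrichment"` (terms passing the q filter) or `"annotation"`
#'   (all slim terms, used or not).
#' @param enrichment_results Result data.frame from [run_enrichment()].
#' @param slim A `slim_spec`.
#' @return Character vector of term ids.
#' @export
select_display_terms <- function(mode = c("enrichment", "annotation"),
                                 enrichment_results = NULL, slim = NULL) {
  mode <- match.arg(mode)
  if (mode == "enrichment") {
    if (is.null(enrichment_results)) stop("enrichment mode requires enrichment_results")
    enrichment_results$term_id
  } else {
    if (is.null(slim)) stop("annotation mode requires a slim_spec")
    slim$terms
  }
}

#' Reduced term-term edge set over the displayed terms
#'
#' Draws an edge a -> b for every pair of displayed terms where a is an
#' ontology ancestor of b, then applies [transitive_reduction()]. A surviving
#' edge that coincides with a direct ontology edge carries its relation
#' (`is_a`/`part_of`); an edge spanning omitted intermediate terms carries
#' relation `"indirect"`. This keeps two displayed terms connected even when
#' the ontology path between them runs through terms that are not displayed.
#'
#' @param display_terms Character vector of term ids.
#' @param dag A `go_dag`.
#' @return data.frame(parent, child, relation); zero rows when no displayed
#'   pair is comparable.
#' @export
term_subgraph <- function(display_terms, dag) {
  display_terms <- unique(display_terms)
  empty <- data.frame(parent = character(), child = character(),
                      relation = character(), stringsAsFactors = FALSE)
  if (length(display_terms) < 2) return(empty)
  anc <- all_ancestors(dag)
  pairs <- list()
  for (b in display_terms) {
    as <- intersect(anc[[b]], display_terms)
    if (length(as)) pairs[[b]] <- data.frame(parent = as, child = b,
                                             stringsAsFactors = FALSE)
  }
  if (length(pairs) == 0) return(empty)
  closure <- do.call(rbind, pairs)
  reduced <- transitive_reduction(closure)
  if (nrow(reduced) == 0) return(empty)
  direct <- paste(dag$edges$parent, dag$edges$child, sep = "\r")
  rel_of <- stats::setNames(dag$edges$relation, direct)
  key <- paste(reduced$parent, reduced$child, sep = "\r")
  reduced$relation <- ifelse(key %in% direct, rel_of[key], "indirect")
  reduced <- reduced[order(reduced$parent, reduced$child), , drop = FALSE]
  rownames(reduced) <- NULL
  reduced
}

#' Attach genes to their most specific displayed terms
#'
#' Gene g connects to displayed term t iff t is in g's displayed term set and
#' no ontology descendant of t in that set exists (e.g. a gene annotated to
#' both 'nucleosome organization' and its displayed child 'nucleosome
#' positioning' attaches only to the child). Each edge carries the union of
#' references of the direct annotations at or below the attached term that
#' support the (possibly propagated) attachment.
#'
#' @param display_terms Character vector of displayed term ids.
#' @param gene_terms Named list gene_id -> displayed term set (propagated
#'   annotations intersected with `display_terms` for enrichment; the slim
#'   map for annotation analysis).
#' @param dag A `go_dag`.
#' @param annots The `annotation_set` (source of reference strings).
#' @return data.frame(term_id, gene_id, references).
#' @export
attach_genes <- function(display_terms, gene_terms, dag, annots) {
  anc <- all_ancestors(dag)
  rows <- list()
  direct <- annots$direct
  for (g in names(gene_terms)) {
    ts <- intersect(gene_terms[[g]], display_terms)
    if (length(ts) == 0) next
    # drop any term that has a displayed descendant also carrying the gene:
    # t is kept iff no other t' in ts has t among its ancestors
    covered <- unique(unlist(anc[ts], use.names = FALSE))
    keep <- setdiff(ts, covered)
    dg <- direct[direct$gene_id == g, , drop = FALSE]
    for (t in keep) {
      below <- c(t, go_descendants(dag, t))
      refs <- dg$references[dg$term_id %in% below]
      refs <- sort(unique(unlist(strsplit(refs, "|", fixed = TRUE))))
      rows[[length(rows) + 1L]] <- data.frame(
        term_id = t, gene_id = g,
        references = paste(refs, collapse = "|"),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(term_id = character(), gene_id = character(),
                      references = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$term_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Linear [0,1] color scales. Terms: intensity tracks -log10(p) across the
# displayed range (0.5 when all p coincide). Genes: diverging scale centered
# at 0 for signed contrasts, sequential 0..max for expression values.
scale_unit <- function(v) {
  rng <- range(v, finite = TRUE)
  if (!is.finite(rng[1]) || rng[1] == rng[2]) return(rep(0.5, length(v)))
  (v - rng[1]) / (rng[2] - rng[1])
}

#' Fill node color values
#'
#' Term nodes: `color_value = (-log10 p - min) / (max - min)` over the
#' displayed terms (0.5 when all p are equal); only in enrichment mode.
#' Gene nodes: a symmetric diverging scale centered at 0 for contrast values
#' (0.5 + c / (2 * max|c|)), or a sequential 0-to-max scale for expression;
#' genes without a value get no color.
#'
#' @param graph A `go_network` from [build_graph()] (also called internally).
#' @param expression Optional expression table (first column gene id).
#' @param celltype Optional column of `expression` to color by.
#' @return The graph with `color_value` columns filled.
#' @export
colorize_graph <- function(graph, expression = NULL, celltype = NULL) {
  tn <- graph$term_nodes
  if (nrow(tn) > 0 && !all(is.na(tn$p))) {
    tn$color_value <- scale_unit(-log10(tn$p))
  }
  graph$term_nodes <- tn
  gn <- graph$gene_nodes
  if (!is.null(expression) && !is.null(celltype)) {
    if (!celltype %in% names(expression)[-1]) {
      stop("unknown celltype in expression table: ", celltype)
    }
    vals <- stats::setNames(expression[[celltype]], expression[[1]])
    gn$expression <- unname(vals[gn$gene_id])
    mx <- max(gn$expression, na.rm = TRUE)
    if (is.finite(mx) && mx > 0) gn$color_value <- gn$expression / mx
  } else if (any(!is.na(gn$contrast))) {
    mx <- max(abs(gn$contrast), na.rm = TRUE)
    if (mx > 0) {
      gn$color_value <- pmin(1, pmax(0, 0.5 + gn$contrast / (2 * mx)))
    } else {
      gn$color_value <- ifelse(is.na(gn$contrast), NA_real_, 0.5)
    }
  }
  graph$gene_nodes <- gn
  graph
}

#' Build the gene-term output graph
#'
#' Composes [select_display_terms()], [term_subgraph()], [attach_genes()] and
#' [colorize_graph()] into the final `go_network`: term nodes with p/q and
#' annotated input genes, gene nodes with tokens, cross-references, contrast
#' and resolution status (unresolved tokens appear as attribute-poor
#' orphans), a transitively reduced term-term edge set, and term -> gene
#' attachment edges.
#'
#' @param mode `"enrichment"` or `"annotation"`.
#' @param entries Resolved entries from [resolve_entries()].
#' @param annots Propagated `annotation_set`.
#' @param dag A `go_dag`.
#' @param namespace GO namespace.
#' @param enrichment_results Result data.frame (enrichment mode).
#' @param slim A `slim_spec` (annotation mode).
#' @param expression,celltype Optional expression coloring (see
#'   [colorize_graph()]).
#' @return Object of class `go_network`: list(term_nodes, gene_nodes,
#'   term_edges, gene_edges, mode, namespace).
#' @export
build_graph <- function(mode = c("enrichment", "annotation"), entries, annots,
                        dag, namespace, enrichment_results = NULL, slim = NULL,
                        expression = NULL, celltype = NULL) {
  mode <- match.arg(mode)
  display <- select_display_terms(mode, enrichment_results, slim)

  resolved <- entries[!is.na(entries$primary_id), , drop = FALSE]
  gene_ids <- resolved$primary_id
  if (mode == "enrichment") {
    gene_terms <- lapply(stats::setNames(gene_ids, gene_ids), function(g) {
      ts <- annots$propagated[[g]]
      if (is.null(ts)) character(0) else intersect(ts, display)
    })
  } else {
    gene_terms <- annotate_against_slim(gene_ids, annots, slim)
  }

  term_edges <- term_subgraph(display, dag)
  gene_edges <- attach_genes(display, gene_terms, dag, annots)

  # term nodes
  display <- sort(unique(display))
  tn <- data.frame(term_id = display,
                   name = dag$terms[display, "name"],
                   namespace = dag$terms[display, "namespace"],
                   p = NA_real_, q = NA_real_, color_value = NA_real_,
                   stringsAsFactors = FALSE)
  rownames(tn) <- tn$term_id
  if (mode == "enrichment" && nrow(enrichment_results) > 0) {
    er <- enrichment_results
    tn[er$term_id, "p"] <- er$p
    tn[er$term_id, "q"] <- er$q
  }
  tn$annotated_input_genes <- lapply(display, function(t) {
    sort(names(gene_terms)[vapply(gene_terms, function(ts) t %in% ts, logical(1))])
  })

  # gene nodes: every submitted entry, resolved or not
  gn <- data.frame(gene_id = ifelse(is.na(entries$primary_id),
                                    entries$token, entries$primary_id),
                   token = entries$token,
                   uniprot = entries$uniprot, ensembl = entries$ensembl,
                   mgi = entries$mgi, contrast = entries$contrast,
                   expression = NA_real_, color_value = NA_real_,
                   status = entries$status, stringsAsFactors = FALSE)
  gn <- gn[!duplicated(gn$gene_id), , drop = FALSE]
  rownames(gn) <- NULL

  graph <- structure(list(term_nodes = tn, gene_nodes = gn,
                          term_edges = term_edges, gene_edges = gene_edges,
                          mode = mode, namespace = namespace),
                     class = "go_network")
  colorize_graph(graph, expression = expression, celltype = celltype)
}

#' @export
print.go_network <- function(x, ...) {
  cat(sprintf("go_network (%s, %s): %d term nodes, %d gene nodes, %d term edges, %d gene edges\n",
              x$mode, x$namespace, nrow(x$term_nodes), nrow(x$gene_nodes),
              nrow(x$term_edges), nrow(x$gene_edges)))
  invisible(x)
}

#' Check the structural invariants of a gene-term graph
#'
#' Verifies: term edges form a DAG equal to its own transitive reduction and
#' oriented general -> specific under the ontology; no gene attaches to two
#' comparable terms (most-specific property); every gene edge runs from a
#' term node to a gene node; every displayed term and submitted gene is
#' present as a node.
#'
#' @param graph A `go_network`.
#' @param dag The `go_dag` it was built from.
#' @return `TRUE` invisibly; stops with an informative error otherwise.
#' @export
check_graph_invariants <- function(graph, dag) {
  te <- graph$term_edges
  if (nrow(te) > 0) {
    red <- transitive_reduction(te)  # errors on a cycle
    if (nrow(red) != nrow(te)) stop("term edges are not transitively reduced")
    anc <- all_ancestors(dag)
    for (i in seq_len(nrow(te))) {
      if (!(te$parent[i] %in% anc[[te$child[i]]])) {
        stop(sprintf("term edge %s -> %s does not run general -> specific",
                     te$parent[i], te$child[i]))
      }
    }
  }
  ge <- graph$gene_edges
  if (nrow(ge) > 0) {
    if (!all(ge$term_id %in% graph$term_nodes$term_id)) stop("gene edge with unknown source term")
    if (!all(ge$gene_id %in% graph$gene_nodes$gene_id)) stop("gene edge with unknown target gene")
    anc <- all_ancestors(dag)
    for (g in unique(ge$gene_id)) {
      ts <- ge$term_id[ge$gene_id == g]
      for (t in ts) {
        if (length(intersect(anc[[t]], ts)) > 0) {
          stop(sprintf("gene %s attached to comparable terms (%s and an ancestor)", g, t))
        }
      }
    }
  }
  invisible(TRUE)
}
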
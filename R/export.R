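# Serialization of analysis results: CSV table, indented text hierarchy,
# Cytoscape JSON (.cyjs). All files are UTF-8 with LF line endings and carry
# no timestamps, so identical runs produce byte-identical output.

#' Bundle a run's outputs for export
#'
#' @param graph A `go_network` (may be `NULL` for CSV-only enrichment runs).
#' @param results Enrichment result data.frame (enrichment mode only).
#' @param entries Resolved entries.
#' @param metadata Named list of run parameters (mode, namespace, threshold,
#'   background descriptor, ...).
#' @return Object of class `export_bundle`.
#' @export
export_bundle <- function(graph = NULL, results = NULL, entries = NULL,
                          metadata = list()) {
  structure(list(graph = graph, results = results, entries = entries,
                 metadata = metadata),
            class = "export_bundle")
}

P_FLOOR <- 1e-308

clamp_p <- function(p) {
  tiny <- !is.na(p) & p < P_FLOOR
  if (any(tiny)) {
    warning(sprintf("%d p-value(s) below %g clamped", sum(tiny), P_FLOOR))
    p[tiny] <- P_FLOOR
  }
  p
}

num_chr <- function(v) ifelse(is.na(v), "", format(v, digits = 17, trim = TRUE, scientific = NA))

token_of <- function(bundle) {
  e <- bundle$entries
  if (is.null(e)) return(function(g) g)
  map <- stats::setNames(e$token, ifelse(is.na(e$primary_id), e$token, e$primary_id))
  function(g) ifelse(g %in% names(map), map[g], g)
}

# One row per displayed term with counts and genes. In annotation mode the
# statistical columns stay empty and x counts attached input genes.
csv_frame <- function(bundle) {
  mode <- bundle$metadata$mode
  tok <- token_of(bundle)
  if (identical(mode, "enrichment")) {
    r <- bundle$results
    data.frame(term_id = r$term_id, name = r$name, namespace = r$namespace,
               p = num_chr(clamp_p(r$p)), q = num_chr(clamp_p(r$q)),
               x = r$x, n = r$n, N = r$N, M = r$M,
               genes = vapply(r$genes, function(g) paste(sort(tok(g)), collapse = "|"), ""),
               stringsAsFactors = FALSE)
  } else {
    tn <- bundle$graph$term_nodes
    tn <- tn[order(tn$term_id), , drop = FALSE]
    data.frame(term_id = tn$term_id, name = tn$name, namespace = tn$namespace,
               p = "", q = "",
               x = vapply(tn$annotated_input_genes, length, 0L),
               n = "", N = "", M = "",
               genes = vapply(tn$annotated_input_genes,
                              function(g) paste(sort(tok(g)), collapse = "|"), ""),
               stringsAsFactors = FALSE)
  }
}

#' Export results as CSV
#'
#' One row per displayed term: term_id, name, namespace, p, q, x, n, N, M
#' and the annotated input genes (pipe-separated tokens, sorted). Rows follow
#' the enrichment result order (ascending q, p, term_id) or term_id order in
#' annotation mode. RFC 4180 quoting.
#'
#' @param bundle An `export_bundle`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_csv <- function(bundle, path) {
  df <- csv_frame(bundle)
  con <- file(path, "wb")  # binary: LF endings on every platform
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, quote = TRUE, eol = "\n")
  invisible(path)
}

#' Export results as an indented text hierarchy
#'
#' Depth-first traversal of the reduced term DAG from its roots; each term
#' is indented two spaces per depth with its id, name and (enrichment) p and
#' q; attached genes follow on indented continuation lines prefixed `-`.
#' Terms with several displayed parents are printed under each, marked
#' `[repeat]` after the first occurrence. Orphan genes appear in a trailing
#' section.
#'
#' @inheritParams export_csv
#' @return `path`, invisibly.
#' @export
export_txt <- function(bundle, path) {
  g <- bundle$graph
  if (is.null(g)) stop("text export requires a built graph")
  tok <- token_of(bundle)
  tn <- g$term_nodes
  te <- g$term_edges
  ge <- g$gene_edges
  out <- c(sprintf("# %s analysis, namespace %s", g$mode, g$namespace),
           sprintf("# %d term(s), %d gene(s)", nrow(tn), nrow(g$gene_nodes)))
  kids <- split(te$child, factor(te$parent, levels = tn$term_id))
  roots <- setdiff(tn$term_id, te$child)
  seen <- character(0)
  fmt_term <- function(t, depth) {
    ind <- strrep("  ", depth)
    stat <- ""
    if (g$mode == "enrichment" && !is.na(tn[t, "p"])) {
      stat <- sprintf(" (p=%.3g, q=%.3g)", tn[t, "p"], tn[t, "q"])
    }
    rep_mark <- if (t %in% seen) " [repeat]" else ""
    line <- sprintf("%s%s %s%s%s", ind, t, tn[t, "name"], stat, rep_mark)
    genes <- sort(tok(ge$gene_id[ge$term_id == t]))
    glines <- if (length(genes) && !(t %in% seen)) {
      sprintf("%s  - %s", ind, genes)
    } else character(0)
    first <- !(t %in% seen)
    seen <<- c(seen, t)
    body <- c(line, glines)
    if (first) {
      for (k in sort(kids[[t]])) body <- c(body, fmt_term(k, depth + 1))
    }
    body
  }
  for (r in sort(roots)) out <- c(out, fmt_term(r, 0))
  orphan_genes <- setdiff(g$gene_nodes$gene_id, ge$gene_id)
  if (length(orphan_genes) > 0) {
    out <- c(out, "", "# orphan genes (no displayed annotation)",
             sort(unname(tok(orphan_genes))))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}

drop_na <- function(lst) lst[!vapply(lst, function(v) is.null(v) || (length(v) == 1 && is.na(v)), logical(1))]

#' Export the graph as Cytoscape JSON (.cyjs)
#'
#' Writes the Cytoscape `elements` structure (`nodes` and `edges` arrays)
#' readable by the desktop Cytoscape application (>= 3.x). Each node's
#' `data` carries id, label, `node_type` (`"term"`/`"gene"`) and the graph
#' attributes (p, q, color_value, cross-references, contrast, status, as
#' applicable); each edge's `data` carries id, source, target and either the
#' ontology relation or the supporting GO references. No position fields are
#' emitted; desktop viewers lay the network out themselves.
#'
#' @inheritParams export_csv
#' @return `path`, invisibly.
#' @export
export_cyjs <- function(bundle, path) {
  g <- bundle$graph
  if (is.null(g)) stop("cyjs export requires a built graph")
  tn <- g$term_nodes
  nodes <- lapply(seq_len(nrow(tn)), function(i) {
    row <- tn[i, ]
    list(data = drop_na(list(
      id = row$term_id, label = row$name, node_type = "term",
      namespace = row$namespace,
      p = if (!is.na(row$p)) clamp_p(row$p) else NA,
      q = if (!is.na(row$q)) clamp_p(row$q) else NA,
      color_value = row$color_value,
      genes = if (length(row$annotated_input_genes[[1]])) I(row$annotated_input_genes[[1]]) else NULL)))
  })
  gn <- g$gene_nodes
  nodes <- c(nodes, lapply(seq_len(nrow(gn)), function(i) {
    row <- gn[i, ]
    list(data = drop_na(list(
      id = row$gene_id, label = row$token, node_type = "gene",
      uniprot = row$uniprot, ensembl = row$ensembl, mgi = row$mgi,
      contrast = row$contrast, expression = row$expression,
      color_value = row$color_value, status = row$status)))
  }))
  te <- g$term_edges
  edges <- lapply(seq_len(nrow(te)), function(i) {
    list(data = list(id = sprintf("tt%d", i), source = te$parent[i],
                     target = te$child[i], relation = te$relation[i]))
  })
  ge <- g$gene_edges
  edges <- c(edges, lapply(seq_len(nrow(ge)), function(i) {
    list(data = list(id = sprintf("tg%d", i), source = ge$term_id[i],
                     target = ge$gene_id[i], references = ge$references[i]))
  }))
  doc <- list(format_version = "1.0",
              generated_by = "termnet",
              data = list(name = sprintf("%s %s", g$mode, g$namespace)),
              elements = list(nodes = nodes, edges = edges))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17), null = "null")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(json, con, sep = "\n")
  invisible(path)
}
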
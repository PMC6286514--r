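GO_NAMESPACES <- c("biological_process", "molecular_function", "cellular_component")
GO_RELATIONS <- c("is_a", "part_of")

#' Construct a GO DAG object
#'
#' Internal constructor shared by [parse_obo()] and the fixture generator.
#' Edges are directed general -> specific (parent -> child). Obsolete terms
#' must already have been removed; the edge set is validated to be acyclic.
#'
#' @param terms data.frame with columns `term_id`, `name`, `namespace`.
#' @param edges data.frame with columns `parent`, `child`, `relation`.
#' @param subsets named list: term_id -> character vector of subset labels.
#' @param alt_ids named character vector: alternate accession -> primary id.
#' @return An object of class `go_dag`.
#' @keywords internal
new_go_dag <- function(terms, edges, subsets = list(), alt_ids = character()) {
  stopifnot(is.data.frame(terms), is.data.frame(edges))
  terms <- terms[!duplicated(terms$term_id), , drop = FALSE]
  rownames(terms) <- terms$term_id
  bad_ns <- setdiff(unique(terms$namespace), GO_NAMESPACES)
  if (length(bad_ns) > 0) {
    stop("unknown GO namespace(s): ", paste(bad_ns, collapse = ", "))
  }
  if (nrow(edges) > 0) {
    missing <- setdiff(unique(c(edges$parent, edges$child)), terms$term_id)
    if (length(missing) > 0) {
      stop("edge endpoint(s) not in term set: ", paste(utils::head(missing, 5), collapse = ", "))
    }
    edges <- edges[!duplicated(edges[c("parent", "child")]), , drop = FALSE]
  }
  ids <- terms$term_id
  fp <- factor(edges$parent, levels = ids)
  fc <- factor(edges$child, levels = ids)
  dag <- structure(list(
    terms = terms,
    edges = edges,
    subsets = subsets,
    alt_ids = alt_ids,
    children = split(as.character(edges$child), fp),
    parents = split(as.character(edges$parent), fc)
  ), class = "go_dag")
  cyc <- find_cycle(ids, dag$children)
  if (!is.null(cyc)) {
    stop("ontology relations contain a cycle: ", paste(cyc, collapse = " -> "))
  }
  dag
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("go_dag: %d terms, %d edges (%s)\n",
              nrow(x$terms), nrow(x$edges),
              paste(unique(x$terms$namespace), collapse = ", ")))
  invisible(x)
}

# Kahn topological sort; returns NULL if acyclic, otherwise one cycle as a
# character vector of term ids.
find_cycle <- function(ids, children) {
  indeg <- stats::setNames(integer(length(ids)), ids)
  for (kids in children) {
    if (length(kids)) indeg[kids] <- indeg[kids] + 1L
  }
  queue <- ids[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]
    seen <- seen + 1L
    for (w in children[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (seen == length(ids)) return(NULL)
  # walk within the residual subgraph until a node repeats
  resid <- names(indeg)[indeg > 0L]
  v <- resid[[1]]; path <- character()
  while (!(v %in% path)) {
    path <- c(path, v)
    v <- intersect(children[[v]], resid)[[1]]
  }
  c(path[which(path == v):length(path)], v)
}

# Topological order of a children-list adjacency (parents before children).
topo_order <- function(ids, children) {
  indeg <- stats::setNames(integer(length(ids)), ids)
  for (kids in children) {
    if (length(kids)) indeg[kids] <- indeg[kids] + 1L
  }
  queue <- ids[indeg == 0L]
  out <- character(0)
  while (length(queue) > 0) {
    v <- queue[[1]]; queue <- queue[-1]
    out <- c(out, v)
    for (w in children[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) != length(ids)) stop("graph is not acyclic")
  out
}

resolve_term_id <- function(dag, term_id) {
  if (term_id %in% dag$terms$term_id) return(term_id)
  if (term_id %in% names(dag$alt_ids)) return(unname(dag$alt_ids[[term_id]]))
  stop("unknown term id: ", term_id)
}

#' Parse an OBO ontology file into a GO DAG
#'
#' Reads OBO 1.2/1.4 flavor text. Only `[Term]` stanzas are interpreted, and
#' within them the tags `id`, `name`, `namespace`, `is_a`,
#' `relationship: part_of`, `subset`, `is_obsolete` and `alt_id`. Obsolete
#' terms are dropped entirely (GO convention); relationship types other than
#' `is_a`/`part_of` are ignored, as are `part_of` edges whose endpoints lie in
#' different namespaces, so that per-namespace analysis stays closed.
#' Edges are directed from the more general term (the `is_a`/`part_of`
#' target) to the more specific term.
#'
#' @param path Path to an OBO file.
#' @return A `go_dag` object.
#' @export
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("format-version: 1.2", "",
#'   "[Term]", "id: GO:0900001", "name: root", "namespace: biological_process", "",
#'   "[Term]", "id: GO:0900002", "name: leaf", "namespace: biological_process",
#'   "is_a: GO:0900001 ! root"), obo)
#' dag <- parse_obo(obo)
#' go_ancestors(dag, "GO:0900002")
parse_obo <- function(path) {
  if (!file.exists(path)) stop("cannot read OBO file: ", path)
  lines <- readLines(path, warn = FALSE)
  # stanza boundaries
  starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  if (length(term_starts) == 0) stop("no [Term] stanzas found in ", path)
  bounds <- c(starts, length(lines) + 1L)

  terms <- list(); edges <- list(); subsets <- list(); alt_ids <- character()
  n_obsolete <- 0L
  for (s in term_starts) {
    end <- min(bounds[bounds > s]) - 1L
    body <- lines[(s + 1L):end]
    body <- body[nzchar(body) & !startsWith(body, "!")]
    tag_split <- regmatches(body, regexpr(": ", body), invert = TRUE)
    tags <- vapply(tag_split, `[`, "", 1L)
    vals <- vapply(tag_split, function(x) if (length(x) > 1) x[[2]] else "", "")
    vals <- sub("\\s*!.*$", "", vals)          # trailing comments
    vals <- trimws(vals)
    getv <- function(tag) vals[tags == tag]

    id <- getv("id")[1]
    if (is.na(id)) next
    if (any(tags == "is_obsolete" & vals == "true")) {
      n_obsolete <- n_obsolete + 1L
      next
    }
    ns <- getv("namespace")[1]
    terms[[id]] <- data.frame(term_id = id,
                              name = if (length(getv("name"))) getv("name")[1] else id,
                              namespace = if (!is.na(ns)) ns else "biological_process",
                              stringsAsFactors = FALSE)
    for (p in getv("is_a")) {
      edges[[length(edges) + 1L]] <- c(parent = p, child = id, relation = "is_a")
    }
    for (rel in getv("relationship")) {
      parts <- strsplit(rel, "\\s+")[[1]]
      if (length(parts) >= 2 && parts[[1]] == "part_of") {
        edges[[length(edges) + 1L]] <- c(parent = parts[[2]], child = id, relation = "part_of")
      }
    }
    ss <- getv("subset")
    if (length(ss)) subsets[[id]] <- ss
    for (a in getv("alt_id")) alt_ids[[a]] <- id
  }
  if (n_obsolete > 0) {
    message(sprintf("parse_obo: dropped %d obsolete term(s)", n_obsolete))
  }
  terms_df <- do.call(rbind, terms)
  if (length(edges) > 0) {
    edges_df <- as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
  } else {
    edges_df <- data.frame(parent = character(), child = character(),
                           relation = character(), stringsAsFactors = FALSE)
  }
  # drop edges touching obsolete/unknown terms
  keep <- edges_df$parent %in% terms_df$term_id & edges_df$child %in% terms_df$term_id
  edges_df <- edges_df[keep, , drop = FALSE]
  # drop cross-namespace part_of edges
  if (nrow(edges_df) > 0) {
    ns_of <- stats::setNames(terms_df$namespace, terms_df$term_id)
    cross <- edges_df$relation == "part_of" &
      ns_of[edges_df$parent] != ns_of[edges_df$child]
    if (any(cross)) {
      message(sprintf("parse_obo: dropped %d cross-namespace part_of edge(s)", sum(cross)))
      edges_df <- edges_df[!cross, , drop = FALSE]
    }
  }
  alt_ids <- alt_ids[unname(alt_ids) %in% terms_df$term_id]
  new_go_dag(terms_df, edges_df, subsets, alt_ids)
}

bfs_reach <- function(adj, start) {
  seen <- character(0)
  frontier <- adj[[start]]
  while (length(frontier) > 0) {
    frontier <- setdiff(unique(frontier), seen)
    if (length(frontier) == 0) break
    seen <- c(seen, frontier)
    frontier <- unlist(adj[frontier], use.names = FALSE)
  }
  seen
}

#' Ancestors of a GO term
#'
#' All terms reachable from `term_id` walking child -> parent over both
#' `is_a` and `part_of` edges; the term itself is excluded. Alternate
#' accessions are resolved to their primary id first.
#'
#' @param dag A `go_dag`.
#' @param term_id GO accession.
#' @return Character vector of ancestor term ids.
#' @export
go_ancestors <- function(dag, term_id) {
  bfs_reach(dag$parents, resolve_term_id(dag, term_id))
}

#' Descendants of a GO term
#'
#' Mirror of [go_ancestors()] in the general -> specific direction.
#'
#' @inheritParams go_ancestors
#' @return Character vector of descendant term ids.
#' @export
go_descendants <- function(dag, term_id) {
  bfs_reach(dag$children, resolve_term_id(dag, term_id))
}

# Ancestor sets for every term at once, computed in topological order.
# Returns a named list term_id -> character vector of ancestors.
all_ancestors <- function(dag) {
  ord <- topo_order(dag$terms$term_id, dag$children)
  anc <- stats::setNames(vector("list", length(ord)), ord)
  for (v in ord) {
    ps <- dag$parents[[v]]
    anc[[v]] <- if (length(ps) == 0) character(0) else
      unique(c(ps, unlist(anc[ps], use.names = FALSE)))
  }
  anc
}

#' Transitive reduction of a DAG edge set
#'
#' Returns the unique minimal subset of `edges` whose transitive closure
#' equals that of the input: an edge u -> v is removed exactly when some
#' other path from u to v exists. Input must be acyclic.
#'
#' @param edges data.frame whose first two columns are tail (parent) and head
#'   (child) of each directed edge; extra columns (e.g. `relation`) are
#'   carried through on surviving rows.
#' @return data.frame of the surviving edge rows.
#' @export
#' @examples
#' e <- data.frame(parent = c("A", "B", "A"), child = c("B", "C", "C"))
#' transitive_reduction(e)  # drops A -> C
transitive_reduction <- function(edges) {
  if (!is.data.frame(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0) return(edges)
  from <- as.character(edges[[1]]); to <- as.character(edges[[2]])
  ids <- unique(c(from, to))
  children <- split(to, factor(from, levels = ids))
  cyc <- find_cycle(ids, children)
  if (!is.null(cyc)) stop("input edges contain a cycle: ", paste(cyc, collapse = " -> "))
  ord <- topo_order(ids, children)
  # descendants bottom-up
  desc <- stats::setNames(vector("list", length(ids)), ids)
  for (v in rev(ord)) {
    kids <- children[[v]]
    desc[[v]] <- if (length(kids) == 0) character(0) else
      unique(c(kids, unlist(desc[kids], use.names = FALSE)))
  }
  keep <- logical(nrow(edges))
  for (u in ids) {
    kids <- unique(children[[u]])
    if (length(kids) == 0) next
    via <- unlist(desc[kids], use.names = FALSE)  # reachable through a child
    direct_keep <- setdiff(kids, via)
    keep[from == u & to %in% direct_keep] <- TRUE
  }
  edges[keep, , drop = FALSE]
}

#' Terms carrying a subset (GO slim) label
#'
#' @param dag A `go_dag`.
#' @param subset_name Subset label, e.g. `"goslim_generic"`.
#' @return Character vector of term ids (empty if the label is unused).
#' @export
subset_terms <- function(dag, subset_name) {
  hits <- vapply(dag$subsets, function(s) subset_name %in% s, logical(1))
  names(dag$subsets)[hits]
}

#' Serialize a GO DAG back to OBO text
#'
#' Writes a minimal OBO 1.2 document containing every term with its name,
#' namespace, subset labels and `is_a`/`part_of` lines. Round-trips through
#' [parse_obo()].
#'
#' @param dag A `go_dag`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", "ontology: synthetic"), con)
  for (id in dag$terms$term_id) {
    row <- dag$terms[id, ]
    out <- c("", "[Term]", paste0("id: ", id), paste0("name: ", row$name),
             paste0("namespace: ", row$namespace))
    for (s in dag$subsets[[id]]) out <- c(out, paste0("subset: ", s))
    ed <- dag$edges[dag$edges$child == id, , drop = FALSE]
    if (nrow(ed) > 0) {
      ed <- ed[order(ed$parent), , drop = FALSE]
      for (i in seq_len(nrow(ed))) {
        out <- c(out, if (ed$relation[i] == "is_a") paste0("is_a: ", ed$parent[i])
                 else paste0("relationship: part_of ", ed$parent[i]))
      }
    }
    writeLines(out, con)
  }
  invisible(path)
}
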
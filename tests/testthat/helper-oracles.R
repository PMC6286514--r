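# Independent oracles and tiny in-code fixture builders shared by the suite.

# --- oracles ---------------------------------------------------------------

# Exact-style hypergeometric upper tail by term-wise log-space enumeration;
# independent of phyper.
oracle_hyper_tail <- function(x, n, N, M) {
  ks <- x:min(n, N)
  if (x == 0) return(1)
  sum(exp(lchoose(n, ks) + lchoose(M - n, N - ks) - lchoose(M, N)))
}

# Naive O(m^2) Benjamini-Hochberg step-up: q_(i) = min_{j>=i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Boolean transitive closure (reachability with >= 1 step) of an edge list
# over the given node set, via repeated squaring.
oracle_closure <- function(nodes, from, to) {
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (length(from)) A[cbind(match(from, nodes), match(to, nodes))] <- TRUE
  R <- A
  repeat {
    R2 <- R | ((R %*% R) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

# Random DAG over n nodes: edges only from lower to higher label.
random_dag_edges <- function(n, p) {
  from <- character(0); to <- character(0)
  nodes <- sprintf("T%02d", seq_len(n))
  for (j in 2:n) {
    pick <- which(stats::runif(j - 1) < p)
    from <- c(from, nodes[pick])
    to <- c(to, rep(nodes[j], length(pick)))
  }
  data.frame(parent = from, child = to, stringsAsFactors = FALSE)
}

# --- tiny literal fixtures -------------------------------------------------

# Write a small OBO document from stanza descriptions.
write_tiny_obo <- function(stanzas, path = tempfile(fileext = ".obo")) {
  lines <- c("format-version: 1.2")
  for (s in stanzas) lines <- c(lines, "", "[Term]", s)
  writeLines(lines, path)
  path
}

# Chain A -> B -> C in one namespace, with ids GO:0900001..3.
chain_dag <- function() {
  p <- write_tiny_obo(list(
    c("id: GO:0900001", "name: A", "namespace: biological_process"),
    c("id: GO:0900002", "name: B", "namespace: biological_process",
      "is_a: GO:0900001"),
    c("id: GO:0900003", "name: C", "namespace: biological_process",
      "is_a: GO:0900002")))
  parse_obo(p)
}

# Diamond A -> {B, C} -> D.
diamond_dag <- function() {
  p <- write_tiny_obo(list(
    c("id: GO:0900001", "name: A", "namespace: biological_process"),
    c("id: GO:0900002", "name: B", "namespace: biological_process",
      "is_a: GO:0900001"),
    c("id: GO:0900003", "name: C", "namespace: biological_process",
      "is_a: GO:0900001"),
    c("id: GO:0900004", "name: D", "namespace: biological_process",
      "is_a: GO:0900002", "relationship: part_of GO:0900003")))
  parse_obo(p)
}

# Write a tiny GAF from (gene, term, ref, qualifier) rows.
write_tiny_gaf <- function(rows, path = tempfile(fileext = ".gaf")) {
  lines <- "!gaf-version: 2.1"
  for (r in rows) {
    lines <- c(lines, paste(
      "SYN", r$gene, paste0("sym_", r$gene), if (is.null(r$qualifier)) "" else r$qualifier,
      r$term, if (is.null(r$ref)) "PMID:1" else r$ref,
      if (is.null(r$evidence)) "IEA" else r$evidence,
      "", "P", "", "", "protein", "taxon:9606", "20240101", "SYN", "", "",
      sep = "\t"))
  }
  writeLines(lines, path)
  path
}

# A complete small analysis world built from one fixture_spec.
fixture_world <- function(seed = 1, n_terms = 40, n_genes = 120, annot_rate = 3,
                          spike = NULL) {
  spec <- fixture_spec(n_terms = n_terms, edge_prob = 0.05, n_genes = n_genes,
                       annot_rate = annot_rate, spike = spike, seed = seed)
  ont <- make_ontology(spec)
  ann <- make_annotations(spec, ont$dag)
  list(spec = spec, dag = ont$dag, obo = ont$path,
       annots = ann$annots, gaf = ann$path)
}
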
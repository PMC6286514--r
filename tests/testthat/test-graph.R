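# helper: entries data.frame for already-primary gene ids
plain_entries <- function(genes, contrast = NA_real_) {
  data.frame(token = genes, contrast = contrast, primary_id = genes,
             uniprot = genes, ensembl = NA_character_, mgi = NA_character_,
             status = "resolved", stringsAsFactors = FALSE)
}

test_that("display-term selection matches the analysis mode", {
  res <- data.frame(term_id = c("GO:0900002", "GO:0900003"), stringsAsFactors = FALSE)
  expect_equal(select_display_terms("enrichment", enrichment_results = res),
               c("GO:0900002", "GO:0900003"))
  slim <- structure(list(terms = c("GO:0900001", "GO:0900002", "GO:0900003")),
                    class = "slim_spec")
  expect_equal(select_display_terms("annotation", slim = slim), slim$terms)
  expect_error(select_display_terms("enrichment"), "requires")
  # empty enrichment -> empty display set
  expect_equal(length(select_display_terms("enrichment",
                                           enrichment_results = res[0, , drop = FALSE])), 0)
})

test_that("term subgraph bridges omitted intermediates and stays reduced", {
  chain <- chain_dag()
  # all three displayed: direct edges survive, transitive edge never appears
  e1 <- term_subgraph(c("GO:0900001", "GO:0900002", "GO:0900003"), chain)
  expect_equal(nrow(e1), 2)
  expect_setequal(paste(e1$parent, e1$child),
                  c("GO:0900001 GO:0900002", "GO:0900002 GO:0900003"))
  expect_setequal(e1$relation, "is_a")
  # middle term hidden: ends stay connected through an 'indirect' edge
  e2 <- term_subgraph(c("GO:0900001", "GO:0900003"), chain)
  expect_equal(nrow(e2), 1)
  expect_equal(e2$relation, "indirect")
  expect_equal(e2$parent, "GO:0900001")
  # unrelated displayed terms stay orphans
  dia <- diamond_dag()
  e3 <- term_subgraph(c("GO:0900002", "GO:0900003"), dia)
  expect_equal(nrow(e3), 0)
  # part_of relation is carried through
  e4 <- term_subgraph(c("GO:0900003", "GO:0900004"), dia)
  expect_equal(e4$relation, "part_of")
})

test_that("reachability among displayed terms mirrors the ontology partial order", {
  w <- fixture_world(seed = 14)
  anc <- termnet:::all_ancestors(w$dag)
  set.seed(15)
  for (rep in 1:5) {
    display <- sample(w$dag$terms$term_id, 15)
    edges <- term_subgraph(display, w$dag)
    reach <- oracle_closure(display, edges$parent, edges$child)
    for (a in display) for (b in display) {
      expect_equal(unname(reach[a, b]), a %in% anc[[b]],
                   info = sprintf("%s -> %s", a, b))
    }
  }
})

test_that("genes attach only to their most specific displayed terms with merged references", {
  chain <- chain_dag()
  gaf <- write_tiny_gaf(list(list(gene = "g1", term = "GO:0900003", ref = "PMID:7"),
                             list(gene = "g1", term = "GO:0900002", ref = "PMID:8"),
                             list(gene = "g2", term = "GO:0900002", ref = "PMID:9")))
  ann <- propagate_annotations(parse_gaf(gaf, chain), chain)
  display <- c("GO:0900002", "GO:0900003")
  gt <- lapply(ann$propagated, intersect, display)
  ge <- attach_genes(display, gt, chain, ann)
  # g1 carries both displayed terms but attaches only to the more specific one
  expect_equal(ge$term_id[ge$gene_id == "g1"], "GO:0900003")
  expect_equal(ge$term_id[ge$gene_id == "g2"], "GO:0900002")
  # references at or below the attachment point are merged
  expect_equal(ge$references[ge$gene_id == "g1"], "PMID:7")
  # incomparable displayed terms -> two edges
  dia <- diamond_dag()
  gaf2 <- write_tiny_gaf(list(list(gene = "h1", term = "GO:0900002"),
                              list(gene = "h1", term = "GO:0900003")))
  ann2 <- propagate_annotations(parse_gaf(gaf2, dia), dia)
  gt2 <- lapply(ann2$propagated, intersect, c("GO:0900002", "GO:0900003"))
  ge2 <- attach_genes(c("GO:0900002", "GO:0900003"), gt2, dia, ann2)
  expect_equal(nrow(ge2), 2)
  # empty displayed set -> orphan
  ge3 <- attach_genes(character(0), gt2, dia, ann2)
  expect_equal(nrow(ge3), 0)
})

test_that("color scales hit their endpoints and degenerate to 0.5", {
  g <- structure(list(
    term_nodes = data.frame(term_id = c("a", "b"), name = c("a", "b"),
                            namespace = "biological_process",
                            p = c(1e-4, 1e-2), q = c(1e-3, 1e-2),
                            color_value = NA_real_, stringsAsFactors = FALSE),
    gene_nodes = data.frame(gene_id = c("g1", "g2", "g3"), token = c("g1", "g2", "g3"),
                            uniprot = NA, ensembl = NA, mgi = NA,
                            contrast = c(2, -2, NA), expression = NA_real_,
                            color_value = NA_real_, status = "resolved",
                            stringsAsFactors = FALSE),
    term_edges = data.frame(), gene_edges = data.frame(),
    mode = "enrichment", namespace = "biological_process"), class = "go_network")
  out <- colorize_graph(g)
  expect_equal(out$term_nodes$color_value, c(1, 0))
  # symmetric contrasts land symmetric about 0.5; missing contrast -> no color
  expect_equal(out$gene_nodes$color_value[1:2], c(1, 0))
  expect_true(is.na(out$gene_nodes$color_value[3]))
  # all-equal p: every term 0.5
  g$term_nodes$p <- c(0.01, 0.01)
  expect_equal(colorize_graph(g)$term_nodes$color_value, c(0.5, 0.5))
})

test_that("built graphs satisfy every structural invariant, orphans included", {
  w <- fixture_world(seed = 1, n_terms = 40, n_genes = 150)
  target <- pick_spike_target(w$annots, "biological_process", min_genes = 15)
  spec <- fixture_spec(n_terms = 40, edge_prob = 0.05, n_genes = 150, annot_rate = 3,
                       seed = 1, spike = list(target_term = target, k_genes = 20,
                                              coverage = 0.8))
  inp <- make_spiked_input(spec, w$dag, w$annots)
  entries <- plain_entries(inp$genes)
  # tack on an unresolvable token
  entries <- rbind(entries, data.frame(token = "GHOST", contrast = NA_real_,
                                       primary_id = NA_character_, uniprot = NA_character_,
                                       ensembl = NA_character_, mgi = NA_character_,
                                       status = "unresolved", stringsAsFactors = FALSE))
  bg <- build_background("all_annotated", inp$genes, w$annots, "biological_process")
  res <- run_enrichment(inp$genes, bg, w$annots, w$dag, "biological_process", 0.05)
  g <- build_graph("enrichment", entries, w$annots, w$dag, "biological_process",
                   enrichment_results = res)
  expect_true(check_graph_invariants(g, w$dag))
  # every displayed term and every submitted token is a node
  expect_setequal(g$term_nodes$term_id, res$term_id)
  expect_true("GHOST" %in% g$gene_nodes$gene_id)
  expect_equal(nrow(g$gene_nodes), nrow(entries))
  expect_equal(g$gene_nodes$status[g$gene_nodes$gene_id == "GHOST"], "unresolved")
  expect_equal(sum(g$gene_edges$gene_id == "GHOST"), 0)

  # annotation mode keeps unused slim terms as orphan nodes
  slim <- resolve_slim("goslim_generic", w$dag, "biological_process")
  ga <- build_graph("annotation", entries, w$annots, w$dag, "biological_process",
                    slim = slim)
  expect_true(check_graph_invariants(ga, w$dag))
  expect_setequal(ga$term_nodes$term_id, slim$terms)
  expect_true(all(is.na(ga$term_nodes$p)))
})

test_that("annotation mode with nothing resolvable yields a slim-orphan graph", {
  w <- fixture_world(seed = 16, n_genes = 40)
  slim <- resolve_slim("goslim_generic", w$dag, "biological_process")
  entries <- data.frame(token = "GHOST", contrast = NA_real_,
                        primary_id = NA_character_, uniprot = NA_character_,
                        ensembl = NA_character_, mgi = NA_character_,
                        status = "unresolved", stringsAsFactors = FALSE)
  g <- build_graph("annotation", entries, w$annots, w$dag, "biological_process",
                   slim = slim)
  expect_setequal(g$term_nodes$term_id, slim$terms)
  expect_equal(nrow(g$gene_edges), 0)
  expect_equal(g$gene_nodes$gene_id, "GHOST")
})
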
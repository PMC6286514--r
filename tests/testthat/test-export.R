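# build a small but complete enrichment world once per file
export_world <- function(seed = 1) {
  w <- fixture_world(seed = seed, n_terms = 40, n_genes = 150)
  target <- pick_spike_target(w$annots, "biological_process", min_genes = 15)
  spec <- fixture_spec(n_terms = 40, edge_prob = 0.05, n_genes = 150, annot_rate = 3,
                       seed = seed, spike = list(target_term = target, k_genes = 20,
                                                 coverage = 0.8))
  inp <- make_spiked_input(spec, w$dag, w$annots)
  entries <- data.frame(token = inp$genes, contrast = NA_real_, primary_id = inp$genes,
                        uniprot = inp$genes, ensembl = NA_character_,
                        mgi = NA_character_, status = "resolved",
                        stringsAsFactors = FALSE)
  bg <- build_background("all_annotated", inp$genes, w$annots, "biological_process")
  res <- run_enrichment(inp$genes, bg, w$annots, w$dag, "biological_process", 0.05)
  graph <- build_graph("enrichment", entries, w$annots, w$dag, "biological_process",
                       enrichment_results = res)
  bundle <- export_bundle(graph, res, entries,
                          metadata = list(mode = "enrichment",
                                          namespace = "biological_process"))
  list(w = w, res = res, graph = graph, bundle = bundle, entries = entries)
}

test_that("CSV export has one row per term and re-parses to identical content", {
  ew <- export_world()
  f <- tempfile(fileext = ".csv")
  export_csv(ew$bundle, f)
  back <- utils::read.csv(f, stringsAsFactors = FALSE, colClasses = "character")
  expect_equal(nrow(back), nrow(ew$res))
  expect_equal(back$term_id, ew$res$term_id)
  expect_equal(as.numeric(back$p), ew$res$p, tolerance = 1e-14)
  expect_equal(as.numeric(back$q), ew$res$q, tolerance = 1e-14)
  expect_equal(as.integer(back$x), ew$res$x)
  # union of gene cells = non-orphan genes of the graph
  genes <- unique(unlist(strsplit(back$genes, "|", fixed = TRUE)))
  expect_setequal(genes, unique(ew$graph$gene_edges$gene_id))
})

test_that("CSV quoting survives commas in term names", {
  ew <- export_world()
  b <- ew$bundle
  b$results$name[1] <- "positive regulation, of something"
  f <- tempfile(fileext = ".csv")
  export_csv(b, f)
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$name[1], "positive regulation, of something")
  expect_equal(nrow(back), nrow(b$results))
})

test_that("annotation-mode CSV leaves statistics empty but fills genes", {
  w <- fixture_world(seed = 13, n_genes = 60)
  genes <- utils::head(namespace_universe(w$annots, "biological_process"), 10)
  entries <- data.frame(token = genes, contrast = NA_real_, primary_id = genes,
                        uniprot = genes, ensembl = NA_character_,
                        mgi = NA_character_, status = "resolved",
                        stringsAsFactors = FALSE)
  slim <- resolve_slim("goslim_generic", w$dag, "biological_process")
  g <- build_graph("annotation", entries, w$annots, w$dag, "biological_process",
                   slim = slim)
  b <- export_bundle(g, NULL, entries, metadata = list(mode = "annotation"))
  f <- tempfile(fileext = ".csv")
  export_csv(b, f)
  back <- utils::read.csv(f, stringsAsFactors = FALSE, colClasses = "character")
  expect_equal(nrow(back), length(slim$terms))
  expect_true(all(back$p == "" & back$q == "" & back$M == ""))
  expect_true(any(nzchar(back$genes)))
})

test_that("TXT hierarchy indents by depth, repeats multi-parent terms, lists orphans", {
  chain <- chain_dag()
  gaf <- write_tiny_gaf(list(list(gene = "g1", term = "GO:0900003")))
  ann <- propagate_annotations(parse_gaf(gaf, chain), chain)
  entries <- data.frame(token = c("g1", "LONER"), contrast = NA_real_,
                        primary_id = c("g1", NA), uniprot = NA_character_,
                        ensembl = NA_character_, mgi = NA_character_,
                        status = c("resolved", "unresolved"), stringsAsFactors = FALSE)
  slim <- resolve_slim(c("GO:0900001", "GO:0900003"), chain, "biological_process")
  g <- build_graph("annotation", entries, ann, chain, "biological_process", slim = slim)
  f <- tempfile(fileext = ".txt")
  export_txt(export_bundle(g, NULL, entries, metadata = list(mode = "annotation")), f)
  lines <- readLines(f)
  root_line <- grep("^GO:0900001", lines)
  leaf_line <- grep("^  GO:0900003", lines)
  expect_length(root_line, 1)
  expect_length(leaf_line, 1)
  expect_gt(leaf_line, root_line)
  expect_true(any(grepl("^    - g1$", lines)))
  expect_true(any(grepl("orphan genes", lines)))
  expect_true(any(grepl("^LONER$", lines)))

  # multi-parent term printed under each parent with a repeat marker
  dia <- diamond_dag()
  ge <- propagate_annotations(parse_gaf(write_tiny_gaf(list(
    list(gene = "g1", term = "GO:0900004"))), dia), dia)
  slim2 <- resolve_slim(c("GO:0900002", "GO:0900003", "GO:0900004"), dia,
                        "biological_process")
  g2 <- build_graph("annotation", entries[1, ], ge, dia, "biological_process",
                    slim = slim2)
  f2 <- tempfile(fileext = ".txt")
  export_txt(export_bundle(g2, NULL, entries[1, ], metadata = list(mode = "annotation")), f2)
  l2 <- readLines(f2)
  expect_length(grep("GO:0900004", l2), 2)
  expect_length(grep("\\[repeat\\]", l2), 1)
})

test_that("cyjs export round trips node ids, edges and attribute values exactly", {
  ew <- export_world()
  f <- tempfile(fileext = ".cyjs")
  export_cyjs(ew$bundle, f)
  doc <- jsonlite::fromJSON(f, simplifyVector = FALSE)
  nodes <- doc$elements$nodes
  edges <- doc$elements$edges
  ids <- vapply(nodes, function(n) n$data$id, "")
  expect_setequal(ids, c(ew$graph$term_nodes$term_id, ew$graph$gene_nodes$gene_id))
  pairs <- vapply(edges, function(e) paste(e$data$source, e$data$target), "")
  expect_setequal(pairs, c(paste(ew$graph$term_edges$parent, ew$graph$term_edges$child),
                           paste(ew$graph$gene_edges$term_id, ew$graph$gene_edges$gene_id)))
  # attribute fidelity: q round trips at full precision
  qs <- stats::setNames(ew$res$q, ew$res$term_id)
  for (n in nodes) {
    if (identical(n$data$node_type, "term")) {
      expect_identical(n$data$q, unname(qs[[n$data$id]]))
    } else {
      expect_identical(n$data$status, "resolved")
    }
  }
  # node_type present on every node, no position fields
  expect_true(all(vapply(nodes, function(n) n$data$node_type %in% c("term", "gene"), logical(1))))
  expect_false(any(vapply(nodes, function(n) "position" %in% names(n), logical(1))))
})

test_that("tiny p-values are clamped with a warning on CSV export", {
  ew <- export_world()
  b <- ew$bundle
  b$results$p[1] <- 1e-320
  f <- tempfile(fileext = ".csv")
  expect_warning(export_csv(b, f), "clamped")
  back <- utils::read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$p[1], 1e-308)
})
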
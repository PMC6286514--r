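# Deterministic synthetic fixtures: ontologies, GAF annotation corpora,
# mapping tables, expression tables and spiked input lists. Everything is a
# pure function of (spec, seed) and is written in the exact formats the
# parsers consume, so the whole pipeline is testable offline.
#
# Terms are ranked 1..n_terms and candidate edges only run from lower to
# higher rank, which guarantees acyclicity without rejection sampling; every
# non-root term receives at least one parent so the namespace has a single
# root. Accessions are deliberately fake (GO:09xxxxx, synthetic
# UniProt-patterned gene ids) to avoid collision with real data.

#' Specification for the synthetic fixture generator
#'
#' @param n_terms Number of ontology terms.
#' @param edge_prob Probability of an edge between each rank-ordered term
#'   pair. With rank-ordered candidates the expected number of parents of a
#'   term grows with its rank, giving shallow generic terms and
#'   well-connected specific ones.
#' @param part_of_fraction Fraction of edges labeled `part_of` (rest `is_a`).
#' @param n_genes Number of genes in the annotation corpus.
#' @param annot_rate Expected number of direct annotations per gene
#'   (Poisson).
#' @param spike Optional list(target_term, k_genes, coverage): build an input
#'   list of `k_genes` genes of which a fraction `coverage` is drawn from the
#'   target term's propagated gene set.
#' @param seed RNG seed; all artifacts are deterministic given (spec, seed).
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_terms = 50, edge_prob = 0.05, part_of_fraction = 0.2,
                         n_genes = 500, annot_rate = 3, spike = NULL, seed = 1) {
  stopifnot(n_terms >= 1, n_genes >= 1,
            edge_prob >= 0, edge_prob <= 1,
            part_of_fraction >= 0, part_of_fraction <= 1,
            annot_rate >= 0)
  structure(list(n_terms = n_terms, edge_prob = edge_prob,
                 part_of_fraction = part_of_fraction, n_genes = n_genes,
                 annot_rate = annot_rate, spike = spike, seed = seed),
            class = "fixture_spec")
}

fixture_term_id <- function(i) sprintf("GO:09%05d", i)
fixture_gene_id <- function(i) sprintf("P9%04d", i)

#' Generate a synthetic ontology
#'
#' Builds a single-rooted DAG in one namespace, tags about 20% of terms with
#' `"goslim_generic"`, writes it as OBO 1.2 and returns the parsed DAG.
#' Identical (spec, seed) gives byte-identical OBO output.
#'
#' @param spec A `fixture_spec`.
#' @param path Output OBO path (default: a tempfile).
#' @param namespace Namespace for all generated terms.
#' @return list(dag, path).
#' @export
make_ontology <- function(spec, path = tempfile(fileext = ".obo"),
                          namespace = "biological_process") {
  set.seed(spec$seed)
  n <- spec$n_terms
  ids <- fixture_term_id(seq_len(n))
  edges <- list()
  for (child in seq_len(n)[-1]) {
    lower <- seq_len(child - 1)
    pick <- lower[stats::runif(length(lower)) < spec$edge_prob]
    if (length(pick) == 0) pick <- sample(lower, 1)  # keep the DAG rooted
    for (p in pick) {
      edges[[length(edges) + 1L]] <- c(parent = ids[[p]], child = ids[[child]])
    }
  }
  edges_df <- if (length(edges)) {
    as.data.frame(do.call(rbind, edges), stringsAsFactors = FALSE)
  } else {
    data.frame(parent = character(), child = character(), stringsAsFactors = FALSE)
  }
  edges_df$relation <- ifelse(stats::runif(nrow(edges_df)) < spec$part_of_fraction,
                              "part_of", "is_a")
  slim <- ids[stats::runif(n) < 0.2]
  terms_df <- data.frame(term_id = ids,
                         name = sprintf("synthetic term %d", seq_len(n)),
                         namespace = namespace, stringsAsFactors = FALSE)
  subsets <- stats::setNames(lapply(slim, function(i) "goslim_generic"), slim)
  dag <- new_go_dag(terms_df, edges_df, subsets)
  write_obo(dag, path)
  list(dag = dag, path = path)
}

#' Generate a synthetic GAF annotation corpus
#'
#' Each gene receives Poisson(`annot_rate`) direct annotations to uniformly
#' chosen terms, written as GAF 2.1 with synthetic PMID references.
#'
#' @param spec A `fixture_spec`.
#' @param dag The DAG from [make_ontology()].
#' @param path Output GAF path (default: a tempfile).
#' @return list(annots — parsed and propagated annotation_set, path).
#' @export
make_annotations <- function(spec, dag, path = tempfile(fileext = ".gaf")) {
  set.seed(spec$seed + 1L)
  ids <- dag$terms$term_id
  ns_code <- c(biological_process = "P", molecular_function = "F",
               cellular_component = "C")
  lines <- c("!gaf-version: 2.1")
  ref_n <- 0L
  for (gi in seq_len(spec$n_genes)) {
    gene <- fixture_gene_id(gi)
    k <- stats::rpois(1, spec$annot_rate)
    if (k == 0) next
    terms <- sample(ids, min(k, length(ids)))
    for (t in terms) {
      ref_n <- ref_n + 1L
      lines <- c(lines, paste(
        "SYN", gene, sprintf("SYM%04d", gi), "", t,
        sprintf("PMID:%d", ref_n), "IEA", "", ns_code[[dag$terms[t, "namespace"]]],
        sprintf("synthetic gene %d", gi), "", "protein", "taxon:9606",
        "20240101", "SYN", "", "", sep = "\t"))
    }
  }
  con <- file(path, "wb")
  writeLines(lines, con, sep = "\n")
  close(con)
  annots <- propagate_annotations(parse_gaf(path, dag), dag)
  list(annots = annots, path = path)
}

#' Generate a spiked input gene list
#'
#' The positive control for enrichment: `round(k_genes * coverage)` genes
#' drawn from the spike target's propagated gene set, topped up to `k_genes`
#' with uniform background fillers. Spiked genes get contrast +1, fillers -1.
#' With coverage 0 the list is a pure negative control.
#'
#' @param spec A `fixture_spec` whose `spike` field is set.
#' @param dag The DAG.
#' @param annots Propagated annotations from [make_annotations()].
#' @param path Output gene-list path (default: a tempfile).
#' @return list(genes — character vector, path, target_term).
#' @export
make_spiked_input <- function(spec, dag, annots, path = tempfile(fileext = ".txt")) {
  if (is.null(spec$spike)) stop("fixture_spec has no spike settings")
  set.seed(spec$seed + 2L)
  sp <- spec$spike
  ns <- dag$terms[sp$target_term, "namespace"]
  index <- term_gene_index(annots, ns)
  pool <- index[[sp$target_term]]
  n_spike <- round(sp$k_genes * sp$coverage)
  if (length(pool) < n_spike) {
    stop(sprintf("spike target %s annotates only %d gene(s), need %d; pick another term or seed",
                 sp$target_term, length(pool), n_spike))
  }
  spiked <- if (n_spike > 0) sample(pool, n_spike) else character(0)
  universe <- namespace_universe(annots, ns)
  filler_pool <- setdiff(universe, spiked)
  fillers <- sample(filler_pool, sp$k_genes - n_spike)
  genes <- c(spiked, fillers)
  contrasts <- c(rep(1, length(spiked)), rep(-1, length(fillers)))
  con <- file(path, "wb")
  writeLines(sprintf("%s %g", genes, contrasts), con, sep = "\n")
  close(con)
  list(genes = genes, path = path, target_term = sp$target_term)
}

#' Pick a suitable spike target term
#'
#' A term whose propagated gene count is at least `min_genes` but below
#' `max_frac` of the namespace universe, so the spike is detectable without
#' being trivially the root. The eligible term with the smallest gene count
#' is chosen (most specific signal); ties break on term id.
#'
#' @param annots Propagated annotations.
#' @param namespace Namespace.
#' @param min_genes Minimum propagated gene count.
#' @param max_frac Maximum fraction of the universe the term may annotate.
#' @return A term id, or error if none qualifies.
#' @export
pick_spike_target <- function(annots, namespace, min_genes = 20, max_frac = 0.3) {
  index <- term_gene_index(annots, namespace)
  sizes <- lengths(index)
  uni <- length(namespace_universe(annots, namespace))
  ok <- sizes >= min_genes & sizes <= max_frac * uni
  if (!any(ok)) stop("no term qualifies as spike target; enlarge the corpus")
  cand <- sort(names(sizes)[ok][sizes[ok] == min(sizes[ok])])
  cand[[1]]
}

#' Generate a synthetic identifier mapping table
#'
#' Each gene gets a symbol alias, its UniProt-shaped primary id, and an
#' Ensembl-shaped cross-reference on a regular chromosome. A fraction
#' `ambiguity_rate` of symbols additionally map to a second, non-SwissProt
#' primary id, so the SwissProt priority rule decides.
#'
#' @param genes Character vector of primary gene ids.
#' @param ambiguity_rate Fraction of ambiguous symbols.
#' @param seed RNG seed.
#' @param path Output TSV path (default: a tempfile).
#' @return list(table — data.frame, path).
#' @export
make_mapping_table <- function(genes, ambiguity_rate = 0, seed = 1,
                               path = tempfile(fileext = ".tsv")) {
  set.seed(seed + 3L)
  n <- length(genes)
  sym <- sprintf("SYM%04d", seq_len(n))
  ens <- sprintf("ENSG09%06d", seq_len(n))
  rows <- list(
    data.frame(alias = sym, primary_id = genes, id_kind = "symbol",
               swissprot = TRUE, regular_chromosome = TRUE, stringsAsFactors = FALSE),
    data.frame(alias = ens, primary_id = genes, id_kind = "ensembl",
               swissprot = FALSE, regular_chromosome = TRUE, stringsAsFactors = FALSE))
  amb <- which(stats::runif(n) < ambiguity_rate)
  if (length(amb) > 0) {
    decoy <- sprintf("Q8%04d", amb)  # TrEMBL-like decoy, not SwissProt
    rows[[3]] <- data.frame(alias = sym[amb], primary_id = decoy,
                            id_kind = "symbol", swissprot = FALSE,
                            regular_chromosome = TRUE, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$alias, tab$primary_id), , drop = FALSE]
  out <- tab
  out$swissprot <- as.integer(out$swissprot)
  out$regular_chromosome <- as.integer(out$regular_chromosome)
  con <- file(path, "wb")
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  close(con)
  list(table = tab, path = path)
}

#' Generate a synthetic expression table
#'
#' Genes x cell types, TPM values drawn log-normally so a realistic fraction
#' falls below the 1-TPM background threshold.
#'
#' @param genes Character vector of gene ids.
#' @param celltypes Character vector of column names.
#' @param seed RNG seed.
#' @param path Output TSV path (default: a tempfile).
#' @return list(table — data.frame with first column `gene_id`, path).
#' @export
make_expression_table <- function(genes, celltypes = c("Tcell", "Bcell", "Monocyte"),
                                  seed = 1, path = tempfile(fileext = ".tsv")) {
  set.seed(seed + 4L)
  tab <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (ct in celltypes) {
    tab[[ct]] <- round(stats::rlnorm(length(genes), meanlog = 0.5, sdlog = 1.5), 3)
  }
  con <- file(path, "wb")
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  close(con)
  list(table = tab, path = path)
}
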
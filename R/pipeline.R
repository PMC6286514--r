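# End-to-end pipeline and command-line interface.
#
# Workflow: parse gene list -> resolve IDs -> (enrichment | slim annotation)
# -> build graph -> export. A CSV-only enrichment run skips graph
# construction entirely.

#' Assemble a run configuration
#'
#' @param mode `"enrich"` or `"annotate"`.
#' @param species `"human"` or `"mouse"`.
#' @param namespace GO namespace.
#' @param obo_path,gaf_path,mapping_path,input_path Input files.
#' @param q_threshold FDR threshold (enrichment only).
#' @param background Background spec: `"annotated"`, `"list:<file>"`, or
#'   `"expression:<celltype>"`.
#' @param tpm_threshold TPM cutoff for expression backgrounds.
#' @param slim Slim spec (annotation only): subset label, file, or GO ids.
#' @param expression_path Optional expression TSV (background and/or gene
#'   coloring).
#' @param celltype Optional celltype column for gene coloring.
#' @param output_format `"csv"`, `"txt"`, `"cyjs"` or `"all"`.
#' @param out_prefix Prefix for output files
#'   (`<prefix>.csv/.txt/.cyjs/.idmap.tsv`).
#' @param exclude_evidence Evidence codes to drop when reading the GAF.
#' @return Object of class `run_config`.
#' @export
run_config <- function(mode = c("enrich", "annotate"), species = "human",
                       namespace = "biological_process",
                       obo_path, gaf_path, mapping_path = NULL, input_path,
                       q_threshold = 0.05, background = "annotated",
                       tpm_threshold = 1.0, slim = "goslim_generic",
                       expression_path = NULL, celltype = NULL,
                       output_format = c("all", "csv", "txt", "cyjs"),
                       out_prefix = "termnet_out",
                       exclude_evidence = character()) {
  mode <- match.arg(mode)
  output_format <- match.arg(output_format)
  namespace <- match.arg(namespace, GO_NAMESPACES)
  structure(list(mode = mode, species = species, namespace = namespace,
                 obo_path = obo_path, gaf_path = gaf_path,
                 mapping_path = mapping_path, input_path = input_path,
                 q_threshold = q_threshold, background = background,
                 tpm_threshold = tpm_threshold, slim = slim,
                 expression_path = expression_path, celltype = celltype,
                 output_format = output_format, out_prefix = out_prefix,
                 exclude_evidence = exclude_evidence),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes parse -> resolve -> (enrich | annotate) -> graph -> export and
#' writes the requested outputs plus the ID-mapping TSV. Progress counts
#' (entries submitted/resolved, terms tested/displayed) go to standard error.
#' In CSV-only enrichment mode the graph stage is skipped.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with elements entries, results, graph, files.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  for (f in c(config$obo_path, config$gaf_path, config$input_path)) {
    if (!file.exists(f)) stop("input file not found: ", f)
  }
  dag <- parse_obo(config$obo_path)
  annots <- propagate_annotations(
    parse_gaf(config$gaf_path, dag, exclude_evidence = config$exclude_evidence), dag)
  entries <- parse_gene_list(config$input_path)
  table <- if (!is.null(config$mapping_path)) read_mapping_table(config$mapping_path)
           else data.frame(alias = character(), primary_id = character(),
                           id_kind = character(), swissprot = logical(),
                           regular_chromosome = logical(), stringsAsFactors = FALSE)
  entries <- resolve_entries(entries, config$species, table)
  message(sprintf("entries: %d submitted, %d resolved, %d ambiguous, %d unresolved",
                  nrow(entries), sum(entries$status == "resolved"),
                  sum(entries$status == "ambiguous_resolved"),
                  sum(entries$status == "unresolved")))
  input_genes <- entries$primary_id[!is.na(entries$primary_id)]

  expression <- if (!is.null(config$expression_path)) {
    utils::read.delim(config$expression_path, stringsAsFactors = FALSE, check.names = FALSE)
  } else NULL

  results <- NULL; slim <- NULL; graph <- NULL
  if (config$mode == "enrich") {
    bg <- parse_background_spec(config$background)
    background <- switch(bg$kind,
      all_annotated = build_background("all_annotated", input_genes, annots, config$namespace),
      custom_list = {
        custom <- parse_gene_list(bg$arg)
        custom <- resolve_entries(custom, config$species, table)
        build_background("custom_list", input_genes, annots, config$namespace,
                         custom_genes = custom$primary_id[!is.na(custom$primary_id)])
      },
      expression_threshold = {
        if (is.null(expression)) stop("expression background requires an expression table")
        build_background("expression_threshold", input_genes, annots, config$namespace,
                         expression = expression, celltype = bg$arg,
                         tpm_threshold = config$tpm_threshold)
      })
    results <- run_enrichment(input_genes, background, annots, dag,
                              config$namespace, config$q_threshold)
    message(sprintf("enrichment: %d term(s) tested, %d pass q <= %g",
                    nrow(attr(results, "tested")), nrow(results), config$q_threshold))
  } else {
    slim <- resolve_slim(config$slim, dag, config$namespace)
    message(sprintf("annotation: %d slim term(s)", length(slim$terms)))
  }

  need_graph <- !(config$mode == "enrich" && config$output_format == "csv")
  if (need_graph) {
    graph <- build_graph(if (config$mode == "enrich") "enrichment" else "annotation",
                         entries, annots, dag, config$namespace,
                         enrichment_results = results, slim = slim,
                         expression = expression, celltype = config$celltype)
    message(sprintf("graph: %d term node(s), %d gene node(s), %d + %d edge(s)",
                    nrow(graph$term_nodes), nrow(graph$gene_nodes),
                    nrow(graph$term_edges), nrow(graph$gene_edges)))
  }

  bundle <- export_bundle(graph = graph, results = results, entries = entries,
                          metadata = list(
                            mode = if (config$mode == "enrich") "enrichment" else "annotation",
                            namespace = config$namespace,
                            species = config$species,
                            q_threshold = if (config$mode == "enrich") config$q_threshold else NA,
                            background = if (config$mode == "enrich") config$background else NA,
                            package_version = as.character(utils::packageVersion("termnet"))))

  files <- character(0)
  fmts <- if (config$output_format == "all") c("csv", "txt", "cyjs") else config$output_format
  for (fmt in fmts) {
    out <- paste0(config$out_prefix, ".", fmt)
    switch(fmt,
           csv = export_csv(bundle, out),
           txt = export_txt(bundle, out),
           cyjs = export_cyjs(bundle, out))
    files <- c(files, out)
  }
  idmap <- paste0(config$out_prefix, ".idmap.tsv")
  write_id_mapping(entries, idmap)
  files <- c(files, idmap)
  invisible(list(entries = entries, results = results, graph = graph, files = files))
}

parse_background_spec <- function(spec) {
  if (spec == "annotated") return(list(kind = "all_annotated", arg = NULL))
  if (startsWith(spec, "list:")) return(list(kind = "custom_list", arg = sub("^list:", "", spec)))
  if (startsWith(spec, "expression:")) {
    return(list(kind = "expression_threshold", arg = sub("^expression:", "", spec)))
  }
  stop("unknown background spec: ", spec,
       " (use 'annotated', 'list:<file>' or 'expression:<celltype>')")
}

CLI_Q_CHOICES <- c(0.05, 0.01, 0.001, 0.0001)

#' Command-line entry point
#'
#' Subcommands `enrich` and `annotate` with shared flags. Invoked by the
#' `inst/exec/termnet` script; tests call it directly with an argument
#' vector. The q-value threshold is restricted to the four standard choices
#' 0.05 (*), 0.01 (**), 0.001 (***), 0.0001 (****); use the library API for
#' other values.
#'
#' @param args Character vector of command-line arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Integer exit status, invisibly: 0 success, 1 data error,
#'   2 usage error.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: termnet <enrich|annotate> --obo F --gaf F --input F [options]"
  if (length(args) < 1 || !(args[[1]] %in% c("enrich", "annotate"))) {
    message(usage)
    return(invisible(2L))
  }
  mode <- args[[1]]
  opts <- list(
    optparse::make_option("--obo", type = "character", help = "OBO ontology file"),
    optparse::make_option("--gaf", type = "character", help = "GAF association file"),
    optparse::make_option("--input", type = "character", help = "gene list file"),
    optparse::make_option("--mapping", type = "character", default = NULL,
                          help = "ID mapping table (TSV)"),
    optparse::make_option("--species", type = "character", default = "human",
                          help = "human or mouse [default %default]"),
    optparse::make_option("--namespace", type = "character",
                          default = "biological_process",
                          help = "GO namespace [default %default]"),
    optparse::make_option("--q", type = "double", default = 0.05,
                          help = "q-value threshold: 0.05, 0.01, 0.001 or 0.0001"),
    optparse::make_option("--background", type = "character", default = "annotated",
                          help = "annotated | list:<file> | expression:<celltype>"),
    optparse::make_option("--tpm-threshold", type = "double", default = 1.0,
                          dest = "tpm_threshold", help = "expression background cutoff [default %default]"),
    optparse::make_option("--slim", type = "character", default = "goslim_generic",
                          help = "subset label or custom term-list file"),
    optparse::make_option("--expression", type = "character", default = NULL,
                          help = "expression TSV (background / coloring)"),
    optparse::make_option("--celltype", type = "character", default = NULL,
                          help = "celltype column for gene coloring"),
    optparse::make_option("--format", type = "character", default = "all",
                          help = "csv | txt | cyjs | all [default %default]"),
    optparse::make_option("--out", type = "character", default = "termnet_out",
                          help = "output file prefix [default %default]"))
  parser <- optparse::OptionParser(option_list = opts, usage = usage)
  parsed <- tryCatch(optparse::parse_args(parser, args = args[-1]),
                     error = function(e) e)
  if (inherits(parsed, "error")) {
    message("argument error: ", conditionMessage(parsed))
    return(invisible(2L))
  }
  for (req in c("obo", "gaf", "input")) {
    if (is.null(parsed[[req]])) {
      message("missing required flag --", req)
      return(invisible(2L))
    }
  }
  if (mode == "enrich" && !parsed$q %in% CLI_Q_CHOICES) {
    message("--q must be one of ", paste(CLI_Q_CHOICES, collapse = ", "))
    return(invisible(2L))
  }
  if (!parsed$format %in% c("csv", "txt", "cyjs", "all")) {
    message("--format must be csv, txt, cyjs or all")
    return(invisible(2L))
  }
  config <- tryCatch(
    run_config(mode = mode, species = parsed$species, namespace = parsed$namespace,
               obo_path = parsed$obo, gaf_path = parsed$gaf,
               mapping_path = parsed$mapping, input_path = parsed$input,
               q_threshold = parsed$q, background = parsed$background,
               tpm_threshold = parsed$tpm_threshold, slim = parsed$slim,
               expression_path = parsed$expression, celltype = parsed$celltype,
               output_format = parsed$format, out_prefix = parsed$out),
    error = function(e) e)
  if (inherits(config, "error")) {
    message("configuration error: ", conditionMessage(config))
    return(invisible(2L))
  }
  res <- tryCatch(run_pipeline(config), error = function(e) e)
  if (inherits(res, "error")) {
    message("error: ", conditionMessage(res))
    return(invisible(1L))
  }
  invisible(0L)
}
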
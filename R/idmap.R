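# Identifier resolution: submitted tokens -> species primary IDs.
#
# Primary IDs are UniProt accessions for human and MGI accessions for mouse.
# Tokens already in primary form pass through untouched; everything else is
# looked up in a local mapping table and ranked by the reliability rules:
# SwissProt-flagged UniProt rows beat others, regular-chromosome Ensembl rows
# beat assembly patches, and residual ties break lexicographically on
# primary_id with the entry flagged ambiguous_resolved.

UNIPROT_RE <- "^([OPQ][0-9][A-Z0-9]{3}[0-9]|[A-NR-Z][0-9]([A-Z][A-Z0-9]{2}[0-9]){1,2})(-[0-9]+)?$"
MGI_RE <- "^MGI:[0-9]+$"
ENSEMBL_RE <- "^ENS[A-Z]*G[0-9]{6,}$"

#' Parse a submitted gene list
#'
#' One entry per non-empty line; the first whitespace-separated field is the
#' token, an optional second field is a per-gene contrast value (any decimal,
#' e.g. a log-fold change, used only for node coloring). Duplicate tokens
#' collapse to one entry with a warning.
#'
#' @param text Either a character scalar containing the whole list, a
#'   character vector of lines, or a file path.
#' @return data.frame with columns `token` and `contrast` (NA when absent).
#' @export
#' @examples
#' parse_gene_list("TP53 1.5\nCD4 -2")
parse_gene_list <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text)) {
    lines <- readLines(text, warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- trimws(lines)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  idx <- which(keep)
  if (length(idx) == 0) stop("empty gene list")
  tokens <- character(0); contrasts <- numeric(0)
  for (i in idx) {
    parts <- strsplit(lines[[i]], "\\s+")[[1]]
    ctr <- NA_real_
    if (length(parts) >= 2) {
      ctr <- suppressWarnings(as.numeric(parts[[2]]))
      if (is.na(ctr) || !is.finite(ctr)) {
        stop(sprintf("line %d: contrast value '%s' is not a finite decimal", i, parts[[2]]))
      }
    }
    tokens <- c(tokens, parts[[1]])
    contrasts <- c(contrasts, ctr)
  }
  dup <- duplicated(tokens)
  if (any(dup)) {
    warning(sprintf("gene list: collapsed %d duplicate token(s): %s",
                    sum(dup), paste(unique(tokens[dup]), collapse = ", ")))
    contrasts <- contrasts[!dup]
    tokens <- tokens[!dup]
  }
  data.frame(token = tokens, contrast = contrasts, stringsAsFactors = FALSE)
}

#' Read a local identifier mapping table
#'
#' TSV with header `alias`, `primary_id`, `id_kind`, `swissprot`,
#' `regular_chromosome` (booleans as 0/1). `id_kind` is one of symbol,
#' uniprot, mgi, ensembl. An alias may map to several primary ids; ambiguity
#' is resolved by [resolve_entries()].
#'
#' @param path TSV file path.
#' @return data.frame of the table.
#' @export
read_mapping_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("alias", "primary_id", "id_kind", "swissprot", "regular_chromosome")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0) {
    stop("mapping table lacks column(s): ", paste(missing, collapse = ", "))
  }
  tab$swissprot <- tab$swissprot %in% c("1", "TRUE", "true")
  tab$regular_chromosome <- tab$regular_chromosome %in% c("1", "TRUE", "true")
  tab
}

is_primary_shaped <- function(token, species) {
  if (species == "human") grepl(UNIPROT_RE, token) else grepl(MGI_RE, token)
}

#' Resolve submitted tokens to primary IDs
#'
#' Tokens already in primary-ID form (UniProt for human, MGI for mouse) pass
#' through without conversion. Other tokens are looked up in `table`
#' (case-insensitively for symbols, case-sensitively for accession-shaped
#' tokens) and candidates ranked: SwissProt-flagged rows first, then
#' regular-chromosome rows, then lexicographic primary_id. A unique winner
#' after the two priority rules gives status `resolved`; a residual tie is
#' broken lexicographically and flagged `ambiguous_resolved`; a token with no
#' candidate is kept with status `unresolved` so it stays visible downstream.
#'
#' @param entries data.frame from [parse_gene_list()].
#' @param species `"human"` or `"mouse"`.
#' @param table Mapping table from [read_mapping_table()].
#' @return data.frame with columns token, contrast, primary_id, uniprot,
#'   ensembl, mgi, status; one row per submitted token, in submission order.
#' @export
resolve_entries <- function(entries, species, table) {
  if (!species %in% c("human", "mouse")) stop("unknown species: ", species)
  n <- nrow(entries)
  out <- data.frame(token = entries$token, contrast = entries$contrast,
                    primary_id = NA_character_, uniprot = NA_character_,
                    ensembl = NA_character_, mgi = NA_character_,
                    status = "unresolved", stringsAsFactors = FALSE)
  sym_rows <- table$id_kind == "symbol"
  for (i in seq_len(n)) {
    tok <- entries$token[[i]]
    if (is_primary_shaped(tok, species)) {
      out$primary_id[[i]] <- tok
      out$status[[i]] <- "resolved"
    } else {
      accession_shaped <- grepl(UNIPROT_RE, tok) || grepl(MGI_RE, tok) || grepl(ENSEMBL_RE, tok)
      hit <- if (accession_shaped) table$alias == tok else
        sym_rows & toupper(table$alias) == toupper(tok)
      cand <- table[hit, , drop = FALSE]
      if (nrow(cand) == 0) next
      # priority 1: SwissProt subset; priority 2: regular chromosome
      if (any(cand$swissprot)) cand <- cand[cand$swissprot, , drop = FALSE]
      if (any(cand$regular_chromosome)) cand <- cand[cand$regular_chromosome, , drop = FALSE]
      winners <- sort(unique(cand$primary_id))
      out$primary_id[[i]] <- winners[[1]]
      out$status[[i]] <- if (length(winners) > 1) "ambiguous_resolved" else "resolved"
    }
    # cross-references for the chosen primary id
    prim <- out$primary_id[[i]]
    xr <- table[table$primary_id == prim, , drop = FALSE]
    pick <- function(kind) {
      v <- xr$alias[xr$id_kind == kind]
      if (length(v) == 0) NA_character_ else sort(v)[[1]]
    }
    out$uniprot[[i]] <- if (species == "human") prim else pick("uniprot")
    out$mgi[[i]] <- if (species == "mouse") prim else pick("mgi")
    out$ensembl[[i]] <- pick("ensembl")
  }
  out
}

#' Write the ID-mapping export file
#'
#' TSV with columns input_token, primary_id, uniprot, ensembl, mgi, status;
#' one row per entry in submission order; unresolved entries keep empty ID
#' cells.
#'
#' @param entries Resolved entries from [resolve_entries()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_id_mapping <- function(entries, path) {
  df <- data.frame(input_token = entries$token,
                   primary_id = entries$primary_id,
                   uniprot = entries$uniprot,
                   ensembl = entries$ensembl,
                   mgi = entries$mgi,
                   status = entries$status,
                   stringsAsFactors = FALSE)
  for (cn in names(df)) df[[cn]][is.na(df[[cn]])] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}
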
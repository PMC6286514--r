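---
title: "Methods: GO enrichment, annotation mapping and gene-term graphs in termnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GO enrichment, annotation mapping and gene-term graphs in termnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(termnet)
```

## Scope and model

`termnet` analyzes a submitted gene/protein list against the Gene Ontology
in one of two modes. **Enrichment** asks, term by term, whether the list
contains more genes annotated with the term than a background would predict.
**Annotation** skips statistics entirely and maps each gene's annotations
onto a fixed GO subset (a slim). Both modes end in the same artifact: a
directed graph whose nodes are GO terms and genes, with term–term edges
following the ontology's general-to-specific order and term–gene edges
attaching each gene to its most specific displayed terms.

The three GO namespaces (biological process, molecular function, cellular
component) are analyzed separately; keeping the domains apart keeps the
output graph legible and the statistics well-defined. Only `is_a` and
`part_of` relations are loaded from the OBO file. Other relationship types
(`regulates`, `occurs_in`, ...) are deliberately ignored: they do not obey
the true-path rule in the form annotation propagation needs. `part_of`
edges crossing namespaces are dropped so each namespace remains a
self-contained DAG. Obsolete terms are removed from the DAG entirely, and
annotations citing them are dropped with a warning; alternate accessions
(`alt_id`) are indexed as aliases of their primary id.

## Annotation propagation

GAF files record *direct* annotations. Under the true-path rule, a gene
annotated to a term is implicitly annotated to all of its ancestors, so the
propagated set for gene $g$ is $\bigcup_{t \in direct(g)} (\{t\} \cup
\mathrm{anc}(t))$, computed once per corpus in topological order.
Consequences worth noting: counts are monotone up the DAG (an ancestor
never annotates fewer genes than a descendant), and propagation is
idempotent. NOT-qualified GAF lines are excluded — a NOT annotation is
evidence *against* membership and must never be counted as positive.
Duplicate (gene, term) lines merge their reference and evidence sets. All
evidence codes are kept by default; `parse_gaf(exclude_evidence = "IEA")`
drops a user-chosen code list for analyses that want curated-only evidence.

## The enrichment test

For a term annotating $n$ of the $M$ background genes, with $N$ input genes
inside the background of which $x$ carry the term, the p-value is the
hypergeometric upper tail

$$p = P(X \ge x), \qquad X \sim \mathrm{Hypergeom}(M, n, N),$$

equivalently the one-sided Fisher exact test on the 2×2 table. We use
$P(X \ge x)$, which includes the observed count, rather than the strict
survival function $P(X > x)$; the inclusive tail is the standard
over-representation convention (the strict tail would assign $p < 1$ to
$x = 0$, which is not a meaningful rejection of anything). Computation goes
through `stats::phyper` at `x − 1` in the upper tail, which is accurate in
log-space internally and safe for backgrounds up to at least $10^5$ genes;
the test suite checks it exhaustively against term-wise tail enumeration
over all tables with $M \le 60$.

**Multiple-testing family.** By default the family is every namespace term
represented in the input ($x \ge 1$). This keeps the family size $m$
interpretable — terms that could not possibly be flagged do not dilute the
adjustment — and matches common practice in GO tools.
`run_enrichment(family = "annotated")` widens the family to all terms with
$n \ge 1$ for users who prefer the fully agnostic family. Adjustment is
Benjamini–Hochberg step-up ($q_{(i)} = \min_{j \ge i} p_{(j)} m / j$, capped
at 1); results are filtered to $q \le$ threshold and sorted by
$(q, p, \mathrm{term\ id})$, the id acting as a deterministic tie-break.

**Background.** Three constructions: all annotated genes in the namespace;
a custom list; or an expression threshold — genes with TPM strictly above a
cutoff (default 1) in a chosen cell/tissue type, read from a genes ×
cell-types TSV. Every background is intersected with the namespace
annotation universe so $M$ counts only genes that can contribute to some
$n$; a background gene no term annotates would deflate every p-value
spuriously. Input genes falling outside the background are excluded from
the counts (reported via a message and an attribute) but retained as graph
nodes, mirroring the retention of unresolvable tokens.

## Identifier resolution

Submitted tokens may be symbols, UniProt accessions or MGI accessions.
Primary-ID-shaped tokens (UniProt pattern for human, `MGI:\d+` for mouse)
pass through untouched. Anything else is looked up in a local mapping-table
TSV — symbols case-insensitively, accession-shaped tokens case-sensitively —
and ranked: SwissProt-flagged candidates beat TrEMBL-only ones (SwissProt
records are curated), regular-chromosome Ensembl genes beat assembly
patches, and a residual tie breaks lexicographically on primary id with the
entry flagged `ambiguous_resolved` rather than silently `resolved`. The flag
matters because symbol ambiguity is real (a symbol like AIM1 names two
unrelated genes); an analysis should be able to tell a clean mapping from a
guess. Tokens with no candidate stay in the pipeline as `unresolved` and
appear in the graph as attribute-poor orphan gene nodes. All mapping is
offline against the provided table; no network lookups.

## Graph construction

Given the display set (enrichment survivors, or all slim terms):

1. **Term–term edges.** An edge is drawn for every displayed pair (a, b)
   with a an ontology ancestor of b, then the set is transitively reduced.
   We connect ancestor pairs rather than only directly adjacent ontology
   terms: with literal direct edges only, two displayed terms separated by
   a non-displayed intermediate would fall into separate components, which
   defeats the purpose of a hierarchy-preserving view. The reduction of a
   DAG is unique, so the result is well-defined; surviving edges that
   coincide with a direct ontology edge keep their `is_a`/`part_of` label,
   and edges spanning hidden intermediates are labeled `indirect`, since
   claiming either concrete relation for a composite path would be wrong.
2. **Gene attachment.** A gene connects to displayed term t iff t is in the
   gene's displayed annotation set and no displayed descendant of t is. The
   edge carries the union of references of the direct annotations at or
   below t, so a propagated attachment still points back at its evidence.
3. **Orphans.** Displayed terms with no genes and genes with no displayed
   terms (including unresolved tokens) remain as isolated nodes.
4. **Colors.** Term color values are the min–max normalized
   $-\log_{10} p$ over displayed terms (0.5 when all p coincide — a flat
   field rather than an arbitrary endpoint). We color by p, not q: color is
   a within-graph visual ranking and p preserves resolution between terms
   that share a q after step-up averaging. Gene colors come from contrast
   values on a diverging scale centered at 0 (0.5 + c / 2·max|c|, clipped),
   or from expression on a sequential 0-to-max scale; genes without values
   stay uncolored.

Transitive reduction is computed by a descendant-set sweep in reverse
topological order: an edge u→v is redundant exactly when v is reachable
through another child of u. This is $O(V \cdot d \cdot \bar{s})$ with small
constants at ontology scale, and the test suite verifies
closure-preservation and minimality against a matrix-closure oracle on
random DAGs.

## Exports

CSV (RFC 4180) carries one row per displayed term with the contingency
counts and pipe-separated gene tokens; in annotation mode the statistical
cells are empty and `x` counts attached input genes. The TXT format is a
depth-first indented rendering of the reduced DAG (two spaces per level,
multi-parent terms repeated under each parent with a `[repeat]` marker,
orphan genes in a trailing section). The `.cyjs` export emits the Cytoscape
`elements` dialect with node/edge `data` maps and no positions — layout
belongs to the viewer. Numbers are serialized at 17 significant digits so
doubles round-trip exactly; p-values below 1e−308 are clamped with a
warning. No output contains timestamps, so identical runs are byte-identical
— a property the test suite asserts.

## Synthetic fixtures

The generator emulates the input universe end to end: a single-rooted
ontology of `n_terms` terms whose candidate edges only run from lower to
higher rank (acyclicity by construction, no rejection sampling), ~20% of
terms tagged `goslim_generic`; a GAF corpus with Poisson(`annot_rate`)
direct annotations per gene to uniform terms; mapping tables with a
controlled fraction of ambiguous symbols (exactly one SwissProt-flagged
candidate each); log-normal expression tables; and spiked input lists —
`k_genes · coverage` genes drawn from a target term's propagated gene set
plus uniform fillers, contrasts +1/−1 marking the two groups.

Default conditions used across tests and the acceptance script: 40–50
terms, `edge_prob = 0.05` (expected in-degree grows with rank, giving few
generic and many specific terms), `part_of_fraction = 0.2`, 120–500 genes,
`annot_rate = 3`. Spike experiments use the study conditions coverage 0.8,
k = 20, 500 genes; the negative control draws 20-gene inputs uniformly from
the background over 500 runs. The spike target is chosen programmatically:
the smallest-count term annotating at least k·coverage genes but under 30%
of the universe, i.e. a specific but detectable signal.

What the fixtures deliberately do **not** mimic: real GO's depth and
fan-out distributions, annotation bias toward well-studied genes,
inter-term correlation structure beyond the DAG itself, or realistic
evidence-code mixtures. Passing tests therefore demonstrate correctness of
the machinery (counting, testing, reduction, attachment, serialization),
not calibration claims about real human or mouse corpora.

## Numerical and degenerate-input choices

- `hypergeom_pvalue` validates $0 \le x \le \min(n,N)$, $x \ge n+N-M$,
  $n, N \le M$ and returns exactly 1 at $x = 0$.
- `fdr_adjust` rejects p-values outside (0, 1].
- An empty display set builds a graph of gene orphans only; an empty gene
  list is an input error; an empty resolved background is an input error.
- Result ordering and all tie-breaks are lexicographic, never RNG-based;
  the pipeline contains no randomness.
- The CLI restricts q to the four conventional thresholds (0.05, 0.01,
  0.001, 0.0001); the API accepts any value in (0, 1).

## Known limitations

Depletion (under-representation) is not tested; no term-redundancy
reduction (elim/weight-style algorithms) beyond the structural transitive
reduction; GPAD/GPI and OWL inputs are unsupported; mapping quality is
bounded by the supplied table (no secondary-accession history). Whether
color intensity should track p or q, and whether the original
over-representation convention in comparable services is inclusive or
strict at x, are judgment calls documented above rather than settled facts.
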
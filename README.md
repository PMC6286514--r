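# termnet

Gene Ontology (GO) enrichment and annotation analysis with network output,
fully offline.

Researchers interpreting gene or protein lists from -omics experiments
(differential expression signatures, mass-spectrometry hit lists) commonly ask
two related questions: *which GO terms are statistically over-represented in
my list?* (enrichment analysis) and *how does my list distribute over a fixed
set of general GO categories?* (annotation against a GO slim). `termnet`
answers both and renders the result not as a flat table but as a directed
gene–term graph that preserves the ontology's hierarchy and the gene-to-term
relationships, exportable to Cytoscape.

## The statistics and the graph

For each GO term, over-representation is assessed with the one-sided
hypergeometric (Fisher exact) test on the contingency table

|                    | in input | not in input | total |
|--------------------|----------|--------------|-------|
| annotated          | x        | n − x        | n     |
| not annotated      | N − x    | M − N − (n−x)| M − n |
| total              | N        | M − N        | M     |

where M is the background size, n the background genes annotated with the
term (after true-path propagation of annotations to all ancestor terms), N
the input genes in the background and x the input genes carrying the term.
The p-value is the upper tail P(X ≥ x) for X ~ Hypergeometric(M, n, N);
all tested terms are adjusted with the Benjamini–Hochberg step-up procedure
and filtered at a user q-value threshold. The background is configurable:
all annotated genes, a custom list, or all genes expressed above a TPM
cutoff (default 1 TPM) in a chosen cell/tissue type.

The displayed terms are then wired into a DAG: every ancestor–descendant
pair among them is connected and the edge set is **transitively reduced**,
so reachability is preserved with a minimal number of edges (edges spanning
hidden intermediate terms are labeled `indirect`). Each gene attaches only
to its **most specific** displayed terms, and anything unconnected —
unused slim terms, tokens that failed identifier resolution — is retained
as an orphan node.

Identifier resolution converts submitted symbols/accessions to primary IDs
(UniProt for human, MGI for mouse) through a local mapping table, preferring
SwissProt entries and regular-chromosome Ensembl genes, and keeps failed
tokens visible.

## Worked example

Everything below runs offline on generated data:

```r
library(termnet)

spec <- fixture_spec(n_terms = 40, n_genes = 150, annot_rate = 3, seed = 1)
ont  <- make_ontology(spec)                 # OBO file + parsed DAG
ann  <- make_annotations(spec, ont$dag)     # GAF corpus, propagated

target <- pick_spike_target(ann$annots, "biological_process", min_genes = 15)
spec$spike <- list(target_term = target, k_genes = 20, coverage = 0.8)
inp <- make_spiked_input(spec, ont$dag, ann$annots)

bg  <- build_background("all_annotated", inp$genes, ann$annots, "biological_process")
res <- run_enrichment(inp$genes, bg, ann$annots, ont$dag, "biological_process", 0.05)
head(res[, c("term_id", "p", "q", "x", "n", "N", "M")])
#>      term_id            p            q  x  n  N   M
#> 1 GO:0900013 1.447056e-17 5.498812e-16 16 16 20 138
#> 2 GO:0900009 2.252793e-06 4.280306e-05 16 44 20 138
```

The spiked term (GO:0900013) ranks first: 16 of the 20 input genes carry it
although only 16 of the 138 background genes do. Its ancestor GO:0900009 is
dragged along with a weaker q, as propagation dictates. Building and
exporting the graph:

```r
entries <- resolve_entries(parse_gene_list(inp$path), "human",
                           make_mapping_table(bg$genes, seed = 1)$table)
g <- build_graph("enrichment", entries, ann$annots, ont$dag,
                 "biological_process", enrichment_results = res)
g
#> go_network (enrichment, biological_process): 2 term nodes, 20 gene nodes,
#>   1 term edges, 16 gene edges

b <- export_bundle(g, res, entries, metadata = list(mode = "enrichment"))
export_csv(b, "run.csv"); export_txt(b, "run.txt"); export_cyjs(b, "run.cyjs")
```

The single term–term edge runs from the general ancestor to the specific
spiked term; genes attach only to the most specific of the two, and the
`.cyjs` file opens directly in desktop Cytoscape.

## Command line

```sh
inst/exec/termnet enrich --obo go.obo --gaf annotations.gaf \
    --input genes.txt --mapping idmap.tsv --q 0.05 --format all --out run
inst/exec/termnet annotate --obo go.obo --gaf annotations.gaf \
    --input genes.txt --slim goslim_generic --out slimrun
```

Outputs: `<out>.csv`, `<out>.txt` (indented hierarchy), `<out>.cyjs`,
`<out>.idmap.tsv`. The q threshold is restricted to 0.05 / 0.01 / 0.001 /
0.0001 on the command line; the R API accepts any value in (0, 1).

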
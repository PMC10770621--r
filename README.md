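# cardiotarget

Multi-omics prioritization of therapeutically actionable cardiac protein
targets from single-nucleus RNA-seq summaries.

Heart failure involves coordinated expression changes across more than a
dozen cardiac cell types — cardiomyocytes, fibroblasts, endothelial cells,
mast cells, adipocytes and others. Several large single-nucleus RNA-seq
(snRNA-seq) atlases of diseased human hearts publish per-cell-type
expression summaries, but turning them into a short list of druggable
protein targets requires a reproducible chain of statistics:
standardization, set intersection, over-representation analysis, network
centrality, and causal path scoring. `cardiotarget` implements that chain
as a tested R package for computational biologists working on target
discovery in cardiovascular disease, with a synthetic-data generator so
every stage is verifiable without any database downloads.

## The method

The pipeline runs five stages, each exposed as ordinary R functions:

1. **Cell-type Z-scores and cross-dataset integration.** For gene *g* in
   cell type *c* of one dataset, *z = (x − μ_g) / σ_g*, where *μ_g* and
   *σ_g* are the mean and population SD of *g*'s mean log-normalized
   expression across all cell types of that dataset. An entry is
   significantly over-expressed when *z ≥ 2* and two-tailed *p ≤ 0.001*
   (under-expression symmetric with *z ≤ −2*). Genes significant in at
   least one cell type of **every** dataset form the integrated set; each
   gene is assigned to the cell type with the largest mean |z|.
2. **Over-representation analysis.** Annotation terms (GMT gene sets) are
   tested with the cumulative hypergeometric upper tail
   *P(X ≥ k)* for *X ~ Hypergeom(N, K, n)*, where the universe *N* is
   restricted to genes with at least one annotation in the source.
   Benjamini–Hochberg correction runs per source; significance at
   *q < 0.001*.
3. **Protein interaction network.** STRING-like confidence edges are kept
   at confidence ≥ 0.9 between integrated genes; degree, betweenness
   (fractional, unordered pairs, unnormalized) and eigenvector centrality
   (principal eigenvector of the largest component, unit Euclidean norm)
   rank the nodes, and the network is validated by overlap with a
   reference proteome.
4. **Causal shortest paths to phenotypes.** In a SIGNOR-like signed
   directed network, each step's reliability *r* becomes a distance
   *d = 1 − r*, and a path scores *Dpath = Σ (1 − r)*. Every network
   protein is scored against seven phenotype nodes (cell proliferation,
   cell death, cell differentiation, glycolysis, inflammation,
   angiogenesis, DNA repair). Proteins reaching at least five phenotypes
   are prioritized; phenotype distance distributions are compared with
   Welch tests under Bonferroni correction (*p < 0.001*, 95 % CI), and
   cell types are ranked by their proteins' mean distances.
5. **Drug annotation.** Prioritized targets are joined against a
   drug–target–mechanism table restricted to phase III/IV clinical-trial
   records. The packaged table covers the 15 late-stage drugs for
   ADRA1A, PPARG and ROCK2 (5 mechanisms, 13 cardiovascular
   indications).

## Worked example

Simulate a three-dataset study with planted ground truth (65 cell-type
markers, 2 network hubs, 3 "golden" targets wired to six phenotypes), run
the full pipeline, and compare against the truth:

```r
library(cardiotarget)

cfg <- simulation_config(seed = 42)
sim <- simulate_inputs(cfg, "example_inputs")

expr_files <- list.files("example_inputs", "^expression_.*[.]tsv$",
                         full.names = TRUE)
ids <- sub("^expression_(.*)[.]tsv$", "\\1", basename(expr_files))
res <- run_pipeline(pipeline_config(
  expression  = setNames(as.list(expr_files), ids),
  annotations = "example_inputs/annotations.gmt",
  ppi         = "example_inputs/ppi_edges.tsv",
  causal      = "example_inputs/causal_edges.tsv",
  drugs       = "example_inputs/drug_table.tsv",
  out_dir     = "example_report"))
#> [expression] reading 3 dataset(s) and computing Z-scores
#> [expression] 65 integrated gene(s)
#> [enrichment] testing 1 annotation source(s)
#> [enrichment] 13 significant term(s)
#> [network] confidence cutoff 0.9
#> [network] 60 node(s), 80 edge(s)
#> [distance] scoring causal paths to 7 phenotype(s)
#> [distance] 3 prioritized target(s)
#> [drugs] minimum clinical phase 3
#> [drugs] 6 drug record(s)

res$distance$prioritized
#>    protein n_phenotypes mean_dpath rank
#> 1 GENE1959            6  0.1144734    1
#> 2 GENE0971            6  0.1168132    2
#> 3 GENE0021            6  0.1300769    3

sim$truth$golden_targets
#>       gene n_phenotypes
#> 1 GENE0021            6
#> 2 GENE0971            6
#> 3 GENE1959            6
```

Reading the output: all 65 planted markers survive the per-dataset
significance calls and the three-way intersection; the 13 planted
annotation terms (one per cell type) are the significant enrichment hits;
60 of the markers stay connected in the confidence-filtered interaction
network; and the three prioritized proteins — those with finite causal
distances to at least five of the seven phenotypes, ranked by phenotype
count then mean *Dpath* — are exactly the three planted golden targets.
The report directory holds every per-stage table (`zscores.tsv`,
`integrated_genes.tsv`, `enrichment.tsv`, `centrality.tsv`,
`distance_matrix.tsv`, `prioritized_targets.tsv`, `drug_annotation.tsv`),
a `summary.tsv` with all thresholds echoed for provenance, and a
`warnings.tsv` sidecar enumerating dropped genes and unreachable
proteins.

The same stages run on real exports: point `pipeline_config()` at your
own expression summaries, GMT files, STRING and SIGNOR exports, and drug
tables. A thin command-line wrapper with `simulate` and `run-all`
subcommands lives in `inst/scripts/cardiotarget.R`.

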
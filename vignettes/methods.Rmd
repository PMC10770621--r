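---
title: "Methods: from cell-type expression summaries to actionable targets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from cell-type expression summaries to actionable targets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiotarget)
```

`cardiotarget` chains five analyses — cell-type Z-scores, set
intersection across datasets, hypergeometric over-representation,
interaction-network centrality, and reliability-weighted causal path
scoring — into a ranked table of drug-annotated protein targets. This
vignette documents the model behind each stage, the tunable parameters
and their defaults, the synthetic-data design, and the numerical
conventions that make runs deterministic.

## Stage 1: cell-type Z-scores and integration

Each input dataset is a *pseudo-profile*: for every (gene, cell type)
pair, the mean log-normalized expression over that cell type's nuclei,
the percentage of nuclei expressing the gene, and the nucleus count. The
package deliberately starts from these summaries; raw count processing,
clustering and cell-type annotation are upstream concerns.

Within one dataset, a gene's expression across the `C` cell types is
standardized against its own profile:

$$z_{gc} = \frac{x_{gc} - \mu_g}{\sigma_g},$$

with `μ_g` and `σ_g` the mean and **population** SD (divide by `C`) of
gene `g` across cell types. The population form is used because the
cell-type profiles of a dataset are the complete population being
standardized, not a sample from a larger one, and because it makes the
two-cell-type case exactly `z = (−1, +1)`; `sd_type = "sample"` is
available. Two-tailed p-values come from the standard normal applied to
`z`. This is a *relative specificity* score: it asks in which cell types
a gene is unusually high or low compared to its own typical level, not
whether it differs between conditions.

Significance is the conjunction `z ≥ z_hi` **and** `p ≤ p_max` for
over-expression (symmetric for under-expression), with defaults
`z_hi = 2`, `z_lo = −2`, `p_max = 0.001`. Two properties of this rule
deserve emphasis:

* **The p rule binds.** `p ≤ 0.001` is equivalent to `|z| ≥ 3.29`, which
  is stricter than `|z| ≥ 2`. Both thresholds are kept explicit and
  configurable rather than silently merged, because they are commonly
  reported together in this form; setting `p_max = 1` recovers the pure
  `|z| ≥ 2` rule.
* **The cell-type count caps |z|.** Among `C` values, a single outlier
  can reach at most `|z| = sqrt(C − 1)` under the population SD
  (`3.46` for the 13 cardiac cell types). The conjunction default is
  therefore only satisfiable at all for `C ≥ 12`, and markers must
  dominate the within-gene spread by an order of magnitude to clear
  `3.29`. Analyses with fewer cell populations should relax `p_max`.

A gene constant across cell types (`σ_g = 0`) is classed `undefined`
with a warning, never an exception, and can never be significant. A gene
is significant *in a dataset* if significant in at least one cell type;
genes significant in **every** dataset form the integrated set
(`intersect_datasets()`). By default, genes whose direction disagrees
between datasets are excluded and logged
(`require_consistent_direction = TRUE`); switching the flag off retains
them with direction `"mixed"`. Each integrated gene's primary cell type
is the one with the largest mean `|z|` over all datasets where it is
significant there, ties broken lexicographically; all significant cell
types are reported, so per-cell-type tallies may intentionally sum to
more than the number of genes. The percent-expressing filter
(`pct_min = 50`, strict `>`) applies only to the per-cell-type mean-Z
summary, never to significance calls.

## Stage 2: over-representation analysis

Enrichment of a gene query in an annotation term uses the cumulative
hypergeometric upper tail, `P(X ≥ k)` for
`X ~ Hypergeom(N, K, n)` — equivalently the one-sided Fisher exact
p-value, which is why no separate Fisher variant exists. Three scoping
rules, each standard practice and each configurable:

* the universe `N` of a source is the union of its term gene sets (only
  genes with at least one annotation enter the statistical domain), and
  query genes outside it are dropped from `n` and reported;
* terms with zero overlap are not tested — they cannot be enriched and
  would only inflate the correction burden (`test_zero_overlap = TRUE`
  reverses this, a documented deviation risk when comparing with tools
  whose family size is unknown);
* Benjamini–Hochberg correction runs within each source separately,
  mirroring per-source result blocks of multi-database enrichment tools
  (`pool_sources = TRUE` pools).

Significance defaults to `q < 0.001`. The pipeline issues one query per
cellular compartment — integrated genes grouped by primary cell type —
plus the full set, because marker signal for one compartment dilutes
quickly inside a combined query.

## Stage 3: interaction network and centralities

Confidence-scored undirected edges (unit or milli scale, auto-detected
since any score above 1 is unambiguous in real exports) are filtered at
`cutoff = 0.9`. The comparison is inclusive (`≥`), matching the
convention that 0.9 *is* highest confidence; both endpoints must be in
the integrated gene set, self-loops are dropped, duplicate pairs
collapse to their maximum confidence, and nodes left without edges are
excluded. Whether isolated-but-confident nodes should count as network
members is genuinely open; dropping them is the documented choice, and
raising the cutoff then never increases node or edge counts.

Centralities follow the conventions that reproduce values on the scale
reported by desktop network tools on networks of about 150 nodes:

* **degree** — raw edge count; the network mean is `2E/N`;
* **betweenness** — unordered endpoint pairs, endpoints excluded,
  fractional counting over equal-length shortest paths, unnormalized,
  computed per connected component;
* **eigenvector** — principal eigenvector of the adjacency matrix of
  the largest connected component (ties on component size resolved
  toward the component holding the lexicographically smallest node),
  nonnegative entries, unit Euclidean norm (`normalization = "max"`
  rescales the top node to 1). Nodes outside the component get 0 and are
  flagged.

The eigenvector is computed by power iteration on `A + I` from a fixed
uniform start vector: the identity shift keeps the spectrum positive so
the iteration cannot oscillate on bipartite components, and the fixed
start makes results bit-reproducible run to run (convergence tolerance
`1e-13` on the vector change, budget 100,000 iterations, hard error
reporting the residual on failure). Tests verify agreement with a dense
symmetric eigendecomposition to `1e-8` and invariance under node
relabeling.

Network-level validation counts the overlap of node symbols with a
reference proteome and reports it as a rounded integer percentage.

## Stage 4: causal distances to phenotypes

A signed directed causal network carries per-edge reliabilities
`r ∈ (0, 1]`; each step contributes distance `d = 1 − r` and a path
scores `Dpath = Σ (1 − r)`. Search follows edge direction only (the
active-flow model); regulation signs annotate the returned path (their
product is its net sign) but never constrain the optimum, since both
positive and negative regulation of a phenotype count as regulation.

`shortest_causal_path()` is a Dijkstra search over the nonnegative step
distances with a total tie-breaking order: smaller `Dpath`, then fewer
steps, then the lexicographically smallest node sequence. Distances
within `1e-12` are treated as tied. Both secondary criteria are
monotone along path extension, so the greedy argument is unchanged and
the returned path is unique and deterministic — equal-scoring routes
cannot flip between runs or platforms. Unreachable pairs are explicit
(`Inf`) and excluded from every mean; summing infinities would destroy
all summaries. `source == phenotype` returns `Dpath = 0` with a warning.

The seven default phenotype nodes are cell proliferation, cell death,
cell differentiation, glycolysis, inflammation, angiogenesis and DNA
repair (`cvd_phenotypes()`), all hallmark processes with cardiovascular
relevance; the list is configurable.

A protein qualifies for a phenotype when `Dpath ≤ dmax`; the default
`dmax = Inf` makes qualification plain reachability, because no finite
cap is canonical, and `dmax` exists for users who want one. Proteins
qualifying for at least `min_phenotypes = 5` of 7 phenotypes are
prioritized, ranked by descending phenotype count, ascending mean
`Dpath`, then name. Phenotype distance distributions are compared
pairwise on reachable values with Welch's unequal-variance t-test
(`method = "wilcoxon"` swaps in Mann–Whitney), Bonferroni-corrected over
all `C(P, 2)` pairs at `alpha = 0.001` with a 95 % CI of the mean
difference; pairs with fewer than two reachable values are skipped with
a warning. Welch is the default because distance distributions have no
reason to share variances and the comparison targets means. Cell types
are scored by the mean over their proteins of each protein's mean
reachable distance, ranked ascending.

## Stage 5: drug annotation

A pure table join: drug records filtered to `max_phase ≥ 3` (phase
III/IV) and joined on target symbol, with distinct drug / mechanism /
indication counts and a Sankey-ready (indication, target, drug)
expansion. A file join is used instead of live database queries because
database snapshots drift; the packaged table
(`cvd_trial_drugs()`) covers the 15 late-stage drugs for ADRA1A, PPARG
and ROCK2, and users supply their own tables for other snapshots. Gene
and protein identifiers are opaque case-sensitive symbols throughout;
no identifier mapping is attempted.

## The synthetic-data generator

`simulation_config()` defines the study conditions; all generators are
pure functions of (config, seed), with fixed per-generator sub-seed
offsets so adding one generator never perturbs another's stream. The
defaults emulate the real inputs' scale: 3 datasets, 13 cell types,
2,000 genes, 5 markers per cell type, a PPI network on the order of 100
nodes after filtering, and a layered causal network over the 7
phenotypes. The full pipeline on these defaults runs in a few seconds.

Expression: each gene draws a baseline mean log-normalized expression
from Gamma(shape 4, scale 0.5) — mean 2, SD 1, nonnegative — shared
across datasets because the same biology underlies them, plus
independent per-dataset cell-type jitter of SD 0.15. Markers are shifted
in their cell type by `marker_effect_size` units of the baseline
distribution's SD (default 4, i.e. a 4-unit shift against 0.15 jitter).
The shift is expressed in baseline-SD units rather than jitter units
deliberately: the `sqrt(C − 1)` cap means a marker is only separable
under the default conjunction when its shift dwarfs the within-gene
spread, so an effect calibrated to the jitter could never be recovered —
a property of the statistic, not of the generator. Under-expressed
markers get an elevated baseline everywhere except their cell type so
the depleted value stays nonnegative. Percent-expressing values are
uniform, biased above 50 for marker genes.

Annotations plant one term per cell type (its markers plus random
padding to 15 genes) among 50 random background terms; the PPI generator
wires 2 hub proteins to ~60 % of nodes with confidences at or above 0.9
over a sparse background whose confidences mostly fall below the cutoff;
the causal generator builds disjoint per-phenotype intermediate chains,
wires 3 golden targets into 6 chains near the phenotype with
reliabilities in [0.9, 1], and wires background proteins into at most 4
chains at the far end. Chains are disjoint, so reachability counts are
exact by construction, and golden targets are drawn from proteins known
to survive the PPI cutoff — prioritization operates on network nodes, so
a golden target outside the network would be unrecoverable by design
rather than by failure. A drug generator adds late-stage records for the
golden targets plus early-phase and off-target decoys.

What the generator does **not** emulate: UMI counts, dropout,
nucleus-level variation, correlated gene programs, annotation ontology
structure, degree-correlated confidence scores, or feedback loops in
signaling. Passing tests therefore demonstrate that the statistics
recover the structure they assume, under that structure — not that the
assumptions hold in real atlases.

## Problem sizes and reproducibility

The test suite validates kernels against independent oracles at sizes
where enumeration is exact: hypergeometric tails against explicit draw
counting for all universes up to 12; betweenness against exhaustive
shortest-path counting on 200 random graphs of up to 8 nodes;
eigenvectors against dense eigendecomposition at up to 50 nodes; and
weighted shortest paths against exhaustive simple-path enumeration on
200 random directed graphs of up to 10 nodes. Statistical calibration
uses 500 seeded replicates (two phenotypes, 30 reachable distances
each): null data must trigger the Bonferroni rule in at most 0.5 % of
replicates, and a planted 1.0-vs-2.0 shift with jitter SD 0.1 must be
flagged in at least 99 %. These sizes were chosen so the whole suite
runs in well under a minute per file while keeping every oracle exact.

Determinism is a contract: generators are pure in (config, seed), the
pipeline consumes no randomness, tie-breaks are total orders, and
reruns on fixed inputs are byte-identical (verified file by file in the
tests). `scripts/acceptance.R` reruns the main computations from scratch
against the installed package and writes the resulting quantities as
JSON.

## Known limitations

* The Z-score is relative within a dataset: it cannot distinguish
  disease-driven change from constitutive cell-type specificity, and
  with few cell types (`C < 12`) the default conjunction is
  unsatisfiable outright.
* Per-cell-type gene tallies depend on the multi-assignment convention;
  single-assignment counts are recoverable from the primary assignment
  column.
* Betweenness and eigenvector conventions vary across network tools;
  the ones here are documented above and configurable where they
  plausibly differ, but cross-tool numeric identity is not guaranteed.
* Causal-path scores depend entirely on the reliability annotations of
  the supplied network snapshot; per-protein distances are not
  comparable across snapshots.
* The drug join is only as current as the supplied table; the packaged
  table is a fixed snapshot whose per-drug indication pairing is a
  synthetic allocation (see its header).
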
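---
title: "Building pathway-level functional networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building pathway-level functional networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathwaynet)
```

## The model

pathwaynet represents cellular organization as a network whose nodes are
*pathways* — curated gene sets — rather than individual molecules. Two
pathways are linked when their functions, summarized as Gene Ontology (GO)
Biological Process term profiles, are semantically similar. Because a pathway
already encodes a coherent, context-dependent set of molecular interactions,
this high-level network sidesteps the false-positive/false-negative problem
of protein–protein interaction data while still exposing the modular
organization of function, and it gives diseases a natural mapping: a disease
perturbs the pathway nodes its genes are over-represented in, and a real
disease module shows up as a set of nodes lying unusually close together.

The pipeline has four phases.

**1. Curation.** Starting from a pathway collection (GMT), exact duplicate
gene sets are collapsed (keeping the lexicographically smallest id), pathways
whose *names* match disease, drug-metabolism or addiction terms are removed
(the network should depict healthy function; the term lists are data, not
algorithm, and are user-configurable via `default_exclusion_terms()`), and
pathways with fewer than four GO-annotated genes are dropped because
enrichment analysis below that size is meaningless. Annotations come from a
GAF file with `NOT`-qualified rows discarded, electronically inferred (IEA)
annotations removed as lower-confidence, and the remainder propagated over
both `is_a` and `part_of` ancestors (the true-path rule). Propagation over
both relation types follows standard GO practice; the alternative
(`is_a`-only) was rejected because the Wang measure itself weights both
relations, so the annotation and similarity layers should see the same
graph.

**2. Functional profiles.** Each pathway's annotated genes are tested for
GO-term over-representation with the one-sided Fisher's exact test
(hypergeometric upper tail) against the union of annotated genes across all
curated pathways, with Benjamini–Hochberg correction inside each pathway's
test family and an adjusted-p threshold of 0.01. The enriched list is then
*minimized* by a greedy set cover over the pathway's genes: repeatedly select
the most significant term still covering an uncovered gene (ties: more new
genes, then term id). Terms describing the same genes at lower significance
are thereby discarded. The output keeps every selection that contributed new
genes — a later, more general term may subsume an earlier, more specific
pick's genes, and the specific term is retained deliberately, since the point
of the profile is the most significant description of each gene, not the
smallest possible cover. Genes covered by no enriched term are excluded from
the cover target and reported.

**3. The network.** Redundancy *between* pathways is reduced with a
proportional greedy set cover: iteratively select the pathway with the most
uncovered genes, breaking ties toward the pathway whose size is closest to a
target (default: the median size of the candidate set, computed from the
data), and stop once 99.95% of the gene universe is covered — the last
fraction is what lets oversized, unspecific pathways drop out. Pathway–
pathway similarity is then the best-match average (BMA) of Wang term
similarities between minimal profiles. Wang similarity scores a term pair by
their shared ancestors' S-values, where S decays by 0.8 per `is_a` edge and
0.6 per `part_of` edge along the best path (the canonical Wang weights;
only their ordering is prescribed by the method). The Resnik alternative —
normalized information content of the most informative common ancestor — and
the plain pairwise-average aggregation are implemented for comparison;
`separation_report()` contrasts within-pathway and between-pathway
similarity distributions for all six combinations. BMA is the default
because a pathway enriched with two unrelated functions still matches an
identically annotated pathway at 1.0, where the pairwise average gives 0.5.
Finally, edges are pruned with a 50-threshold scan on the grid k/51: the
retained cut maximizes (fraction of nodes keeping an edge) − (fraction of
edges kept), ties toward the larger threshold, with thresholds that empty
the edge set excluded as useless.

**4. Disease modules.** Disease gene sets (at least four genes) are mapped
onto the network nodes by the same one-sided Fisher test at raw p < 0.01 —
raw, not adjusted, because the mapping stage is a per-disease screen rather
than a per-pathway family of thousands of GO tests. For each disease with at
least two mapped nodes, the unweighted shortest-path lengths between its
nodes are compared against a pooled null of 100 equal-size random node sets
with a two-sample Kolmogorov–Smirnov test; clustering means the observed
mean is below the null mean with small KS p. Hop counts are used (not
similarity-weighted distances) because the thresholded graph is the object
of interest and integer bins make the distributions directly comparable;
pairs split across components are excluded from both observed and null
distributions and reported separately, rather than being assigned infinite
length.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha_go` | 0.01 | BH-adjusted p cut-off for enriched GO terms |
| `alpha_disease` | 0.01 | raw p cut-off for disease–pathway association |
| `min_annotated` | 4 | minimum annotated genes per pathway |
| `coverage_fraction` | 0.9995 | gene-coverage stop rule of the set cover |
| `target_size` | median | preferred pathway size for cover tie-breaks |
| `wang_weights` | 0.8 / 0.6 | `is_a` / `part_of` decay per edge |
| `n_thresholds` | 50 | evenly spaced candidate edge cut-offs in (0,1) |
| `disease_reps` | 100 | random node sets per disease null |

All of these are arguments of `pipeline_config()`; nothing numeric is
hardcoded in stage code.

## The synthetic study generator

Real pathway, ontology and disease databases cannot be bundled, so
`generate_study()` builds a self-contained study with the statistical
*shape* the pipeline assumes. The standard fixture (`synth_config()` with
seed 17) generates:

- a 60-term rooted DAG: four branches (one per functional theme, mirroring
  the handful of major domains — metabolism, signaling, immunity, DNA
  processes — a global collection organizes into), each with one *signature*
  sub-branch plus four other sub-branches and deeper descendants; ~15% of
  edges are `part_of`; extra within-branch edges make it a DAG rather than a
  tree;
- 400 genes, each with a home sub-branch and about 3 direct annotations (its
  home term's ancestor path plus occasional noise). Three terms per gene
  preserves the annotation *density* of real data at this ontology scale: a
  real genome averages ~8 direct Biological Process terms against more than
  ten thousand, and transplanting the raw count onto 60 terms saturates
  every term so that nothing is specific. 12% of genes carry only IEA
  evidence and vanish at the filtering stage;
- 4 themes × 20 pathways with median size 23 and a lognormal upper tail.
  Each ordinary pathway concentrates on one sub-branch, draws a shared
  7-gene signature core (the within-theme redundancy real collections show)
  and some branch-wide and background genes. Two *cross-talk* pathways per
  theme couple the signature pools of two themes and carry a few connector
  genes found nowhere else, so the 99.95% cover must retain them — they are
  what keeps the pruned network connected across its modules. Exact
  duplicates (10%), disease/drug/addiction-named decoys and sub-floor tiny
  pathways exercise every curation branch;
- 8 planted diseases (45 genes drawn evenly from 4–6 source pathways in
  distinct sub-branches of one theme, so each source shows an enrichable
  overlap) and 8 null diseases (uniform gene draws). Planted diseases carry
  cancer-system names so name-based system selection can be exercised.

Ground truth (theme, sub-branch, status, disease sources) is emitted
alongside the data, so tests never reverse-engineer the generator. The whole
study is a pure function of the configuration: identical config and seed
give byte-identical files.

What the generator does **not** emulate: identifier mapping noise, the full
size of real collections (thousands of pathways, tens of thousands of
terms), annotation-date and evidence-code detail beyond the binary IEA
split, and the continuous heterogeneity of real semantic-similarity
spectra. Passing tests therefore demonstrate the pipeline's correctness and
its qualitative behavior (modularity, disease clustering, calibrated nulls)
at desk scale, not quantitative agreement with any real database release.

## Numerical choices and degenerate inputs

- Greedy covers break residual ties lexicographically, so every trace is
  reproducible; re-running any stage with identical inputs gives identical
  output.
- The threshold grid is k/51 (k = 1..50), strictly inside (0, 1); a cut that
  removes every edge is never chosen.
- `power_law_test()` follows the discrete maximum-likelihood + KS recipe via
  igraph's plfit; the goodness-of-fit p comes from the asymptotic Kolmogorov
  distribution over the fitted tail. A freely estimated lower cut-off can
  always retreat to an extreme tail that fits, so rejecting a power law for
  the *whole* degree distribution requires passing a fixed `xmin`.
- Self-similarity is always 1 (common-ancestor sets include the terms
  themselves); Resnik scores are divided by the corpus maximum IC so both
  term measures share the [0, 1] edge-weight scale and one threshold scan
  applies to either.
- `ks_cluster_test()` uses the asymptotic two-sample KS p (ties make the
  exact computation unavailable); with fewer than ~20 observed pairs it is
  somewhat anti-conservative, which matters for diseases mapping only 2–4
  nodes. The type-I calibration in the test suite therefore uses 10-node
  sets.
- Empty inputs (no pathways, empty gene sets, all-IEA tables) raise
  immediate, named errors rather than propagating empty frames.

## Problem sizes

The test suite runs the full pipeline on the standard fixture (96 generated
pathways, 400 genes, 60 terms) in a few seconds; oracle-equivalence checks
use instances of at most 20 elements where exhaustive enumeration is exact;
null calibrations use 500 simulated null diseases and 500 random node sets.
These sizes were chosen so that every brute-force oracle is literally
exhaustive and the whole suite stays interactive.

## Known limitations

- At desk scale the similarity spectrum is nearly discrete (few distinct
  profile patterns), so the threshold scan — which settles just below the
  smallest per-node best edge — keeps inter-module links only when their
  weights are symmetric to within one grid step. The pruned standard-fixture
  network can therefore split into a small number of theme components,
  whereas a realistic continuous spectrum generically yields one giant
  component. This sharpens with scale and is a property of the emulation,
  not of the method.
- Gene identity is the symbol string as given; users of real data must map
  identifiers beforehand.
- Evidence handling is binary (IEA vs everything else); finer evidence-code
  policies are out of scope.
- Disease/phenotype distinction is carried as a `kind` label only; no
  ontology of diseases is consulted.
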
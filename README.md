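# pathwaynet

Molecular interaction networks describe cellular function one edge at a
time, and inherit every false-positive and context-blind interaction in the
underlying data. `pathwaynet` builds the complementary high-level view: a
network whose **nodes are whole pathways** (curated gene sets) and whose
**edges are semantic similarities** between the pathways' Gene Ontology
Biological Process profiles. On such a network, functional modules appear as
linked communities, and a disease can be mapped as the set of pathway nodes
its genes are over-represented in — with "disease module" given a testable
meaning: the mapped nodes lie closer together than random same-size node
sets.

The package is aimed at systems biologists who have a pathway collection
(GMT), a GO release (OBO + GAF) and disease–gene annotations (TSV), and want
a reproducible, tested implementation of the whole construction rather than
a pile of scripts.

## What it computes

1. **Curation** — deduplicate pathways, drop disease/drug/addiction-named
   pathways (the network depicts healthy function), filter IEA evidence,
   propagate annotations over `is_a`/`part_of` ancestors, and remove
   pathways with fewer than 4 annotated genes.
2. **Functional profiles** — one-sided Fisher's exact over-representation
   per pathway with Benjamini–Hochberg correction (adjusted p < 0.01), then
   a greedy set cover that keeps the most significant terms covering each
   pathway's genes: the minimal functional profile.
3. **Network** — proportional set cover for a reduced-redundancy node set
   (greedy by uncovered genes, ties toward a target size, stop at 99.95%
   coverage); Wang term similarity (S-value decay 0.8 per `is_a`, 0.6 per
   `part_of` edge) aggregated by best-match average (BMA):

   `sim(P,Q) = (Σ_{a∈P} max_{b∈Q} s(a,b) + Σ_{b∈Q} max_{a∈P} s(a,b)) / (|P|+|Q|)`

   Resnik (normalized MICA information content) and pairwise-average
   aggregation are available for comparison. Edges are pruned at the
   threshold maximizing nodes-retained minus edges-retained over a
   50-point scan.
4. **Disease modules** — Fisher mapping of disease genes onto nodes (raw
   p < 0.01), shortest-path distributions vs 100 random same-size node
   sets, two-sample Kolmogorov–Smirnov clustering test. Network statistics
   (clustering coefficient, degree-preserving randomization, power-law
   test) come with it.

A deterministic synthetic-study generator (`generate_study()`) emulates the
statistical shape of real pathway/ontology/disease databases — redundant
long-tailed pathway sets, a two-relation ontology DAG, IEA strata, planted
and null diseases — so the entire pipeline is testable offline.

## Worked example

```r
library(pathwaynet)

study  <- generate_study(synth_config(seed = 17))   # the standard fixture
result <- run_pipeline(study$obo, study$gaf, study$gmt, study$diseases,
                       pipeline_config(seed = 17))
result
#> <pathnet_result>
#>   pathways: 27 (of 96 initial)
#>   network: 27 nodes, 64 edges at threshold 0.7647
#>   diseases tested: 8 (7 clustered at p < 0.01)

tidy(result)      # the curation ledger
#> # A tibble: 7 x 4
#>   stage                      removed reason                             retained
#> 1 deduplicate                      8 identical gene sets                      88
#> 2 filter_name_disease              2 name matches disease term                86
#> 3 filter_name_drug                 2 name matches drug term                   84
#> 4 filter_name_addiction            2 name matches addiction term              82
#> 5 filter_annotation_coverage       2 fewer than 4 annotated genes             80
#> 6 profile_pathways                 0 no enriched GO term                      80
#> 7 proportional_set_cover          53 redundant (not selected by set cover)    27

glance(result)    # network summary
#> # A tibble: 1 x 7
#>   n_nodes n_connected n_edges threshold clustering n_profiled_terms ...
#> 1      27          27      64     0.765      0.789               46

head(result$disease_tests[order(result$disease_tests$p), ], 3)
#>   disease_id n_nodes n_pairs ks_stat        p observed_mean null_mean
#> 1 DIS:P005         6      15   0.622  2.26e-5          1         2.35
#> 2 DIS:P001         8      28   0.445  3.80e-5          1.21      2.37
#> 3 DIS:P008         5      10   0.633  5.75e-5          1         2.38
```

Reading the numbers: 96 generated pathways are curated and redundancy-
reduced to a 27-node network; the chosen edge threshold (0.765) keeps 64 of
351 possible edges while every node keeps at least one, and the clustering
coefficient 0.789 far exceeds degree-preserving chance (≈0.16) — the
network is modular. Planted diseases map to 5–8 nodes whose mean pairwise
distance is ~1 hop versus ~2.4 for random node sets, so the KS test calls
them clustered at p ≪ 0.01.

Plots: `autoplot(result$scan)` shows the node/edge retention scan;
`autoplot(separation_report(...))` contrasts within- vs between-pathway
similarities; `plot_disease_paths()` draws observed vs null path
histograms.

For real data, replace the generated inputs with file paths to your GMT,
OBO, GAF and disease TSV; every reader accepts either. See the methods
vignette (`vignettes/pathway-network-methods.Rmd`) for the model,
parameter meanings, and design notes.

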
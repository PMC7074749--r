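# fragnet

Co-occurrence networks and association rule mining for microbial
presence-absence data.

## The problem

Community fingerprints of environmental microbial assemblages — T-RFLP
terminal restriction fragments, or OTU/ASV incidence tables — record only
whether each taxon ("fragment") was detected in each sample. Even from
such binary data, the spatial distribution of taxa across many samples
carries a signal about who interacts with whom: taxa that share a niche or
exchange metabolites co-occur, competitors exclude each other, and a taxon
that *never* occurs without a partner betrays a one-sided dependency such
as cross-feeding. `fragnet` turns a fragments × samples presence-absence
matrix into these putative interaction networks and analyses their
structure, down to keystone-taxon candidates. It is aimed at microbial
ecologists working with spatially resolved incidence data, e.g. along a
contamination plume sampled at bulk and single-particle scale.

## What it computes

For a binary matrix `X` (rows = fragments, columns = `S` samples):

* **Co-occurrence analysis.** Every unordered fragment pair is summarised
  by the 2×2 table (a, b, c, d) = (both present, only first, only second,
  neither) and tested with the two-sided Fisher exact test
  (p = Σ Pr(tables with the same margins whose probability ≤ the observed
  table's)). All n(n−1)/2 p-values get Benjamini–Hochberg adjustment; a
  pair is *correlated* when p_adj < α (default 0.05). An empirical FDR is
  estimated by re-running the whole decision rule on 100 fixed-margin
  (curveball) randomizations of `X`. Correlated pairs are classified as
  **co-occurrence** or **mutual exclusion** against an occupancy-preserving
  null: each fragment's row is redistributed uniformly while keeping its
  occupancy, under which the pair overlap is hypergeometric with mean
  n_A·n_B/S; a pair is positive (negative) when > 95% of 1000 null draws
  fall below (above) the observed overlap.
* **Association rule mining.** Directed rules A→B with confidence
  support(A,B)/support(A) exactly 1, i.e. samples(A) ⊆ samples(B): A never
  occurs without B. These capture one-sided dependencies invisible to the
  symmetric co-occurrence test.
* **Network analysis.** Signed undirected co-occurrence and directed rule
  networks; density 2E/(N(N−1)), mean degree, characteristic path length
  (over connected pairs), mean local clustering, Freeman degree
  centralization, degree heterogeneity (coefficient of variation); mean
  path length and clustering over 100 Erdős–Rényi G(n,m) graphs with
  matching N and E as a baseline; Newman modularity Q = Σ_c (e_cc − a_c²)
  on the positive edges via deterministic fast-greedy optimisation;
  per-core module presence profiles; and hub roles in the rule network —
  fragments appearing *exclusively* as rule targets with high in-degree
  are keystone candidates whose presence is predicted by many alternative
  partners.
* **Synthetic communities.** A generator with planted location-bound
  modules, planted subset-dependency rules, planted exclusions, and
  cell-flip noise, returning full ground truth (recomputed after noise) —
  the validation substrate for every stage.

## Worked example

```r
library(fragnet)

sim <- synthetic_community(bulk_like_config(seed = 1))  # 280 x 72, 5 planted modules
fit <- cooccurrence(sim$matrix, sim$annotation, seed = 1)
fit
#> Co-occurrence analysis: 280 fragments x 72 samples, alpha = 0.05
#>
#> Fragments total:      280 (192 bacterial / 88 archaeal)
#> Potential pairs:      39,060
#> Correlated pairs:     947
#>   positive:           940
#>   negative:           7
#>   unclassified:       0
#> Bacterial pairs:      574 (571 pos / 3 neg)
#> Archaeal pairs:       347 (347 pos / 0 neg)
#> Mixed pairs:          26 (22 pos / 4 neg)

net <- build_cooccurrence_network(fit, sim$annotation)
modularity_partition(net)
#> Modularity Q = 0.811; 15 modules (11 with > 3 fragments)
#> Module sizes: 26, 22, 22, 21, 20, 7, 5, 5, 5, 4, 4, 3, 3, 2, 2

network_topology(net, all_fragments_count = 280, er_reps = 100, seed = 2)
#> Network coverage:            57%
#> Number of nodes/edges:       160/947
#> Density:                     0.0744
#> Avg. number of neighbors:    11.8
#> Characteristic path length:  2.96
#>   on random network:         2.31
#> Clustering coefficient:      0.604
#>   on random network:         0.0747
#> Centralization:              0.052
#> Heterogeneity:               0.691
```

The 947 correlated pairs are almost all positive, and the five largest
recovered modules (26, 22, 22, 21, 20 fragments) are the five planted
20-fragment blocks plus a few background fragments they attracted; the
clustering coefficient (0.60) far exceeds its random-graph baseline
(0.07), the signature of a modular community. The directed rule stage
works the same way:

```r
rules <- association_rules(sim$matrix, sim$annotation)
rule_type_breakdown(rules, sim$annotation, fit$results)
#> Association rules:      29
#>   also sign. correlated: 28  (96.6%)
#> Bacterium->Bacterium:   9 (31.0%)
#> Bacterium->Archaeum:    6 (20.7%)
#> Archaeum->Archaeum:     9 (31.0%)
#> Archaeum->Bacterium:    5 (17.2%)
```

`run_pipeline(pipeline_config(...))` chains all stages and writes the
full report bundle (pair tables, rule tables, GraphML networks, module
partition and per-core profiles, hub report, JSON summary, run log);
`inst/cli/fragnet.R` exposes `simulate` and `run` subcommands for shell
use.

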
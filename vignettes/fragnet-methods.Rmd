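---
title: "Methods: co-occurrence, rules and network topology in fragnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence, rules and network topology in fragnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragnet)
```

`fragnet` infers putative interaction networks from binary
presence-absence matrices of community fingerprints (rows = fragments,
i.e. taxa-level units such as terminal restriction fragments or
OTUs/ASVs; columns = samples). This vignette explains the statistical
procedures, the conventions fixed where several were defensible, the
synthetic data the package validates itself on, and what those
validations do and do not show about real data.

## The co-occurrence model

For fragments A and B with occupancies $n_A$ and $n_B$ over $S$ samples,
the observed joint distribution is the 2×2 table
$(a, b, c, d)$ = (both present, A only, B only, neither), with
$a+b+c+d = S$. Under the null of independent placement given the margins,
$a$ follows the hypergeometric distribution, and the two-sided Fisher
exact p-value is the total probability of all tables with the same
margins whose point probability does not exceed the observed one. Two
numerical details are fixed here: probabilities are compared with a
$1 + 10^{-7}$ relative tolerance (the convention of
`stats::fisher.test`, guarding against ties lost to floating point), and
tables with a zero margin have a single attainable configuration, hence
p = 1. The implementation computes the p-value from
`stats::dhyper` per margin pair and memoises the per-margin table, which
makes the all-pairs scan over hundreds of fragments take well under a
second; it is verified in the test suite against an independent
enumeration oracle over every 2×2 table with up to 30 samples, and
against `stats::fisher.test`.

All $n(n-1)/2$ p-values are adjusted with the Benjamini–Hochberg step-up
procedure, and significance is declared on the adjusted values
(`p_adj < alpha`, default `alpha = 0.05`). Testing the adjusted value is
a deliberate choice: the FDR correction is part of the decision rule, not
a post-hoc annotation.

### Empirical FDR: fixed-margin randomization

Because tens of thousands of dependent tests share one matrix, the
package additionally estimates an empirical false discovery rate: the
matrix is randomized while conserving *all* row sums (fragment
occupancies) and column sums (sample richness), and the full decision
rule — Fisher test, BH adjustment, threshold — is re-run on each of
`fdr_reps = 100` null matrices. The estimate is the mean null
significant-pair count divided by the observed count (defined as 0 when
nothing is observed). Re-running BH per replicate, rather than comparing
raw p-values, keeps the null pipeline identical to the observed one.

The sampler is a curveball chain: each trade picks two fragments and
re-deals the samples held by exactly one of them, preserving both
margins by construction; margin conservation is asserted on every draw in
the tests. The chain length defaults to four times the number of presence
cells — far beyond common mixing recommendations for curveball trading —
and is configurable (`n_trades`). Each replicate runs an independent
chain seeded from the master seed by a fixed offset.

### Sign classification: the occupancy-preserving null

Significant pairs are classified by comparing the observed overlap $a$
with its distribution when each fragment's presence pattern is
independently and uniformly redistributed across samples, keeping its
occupancy. The overlap of two independent uniform random subsets of fixed
sizes $n_A$ and $n_B$ is exactly hypergeometric, so the null is sampled
directly with `rhyper` (`sign_reps = 1000` draws per pair) rather than by
materialising permuted rows; the tests confirm the sampled null mean
converges to $n_A n_B / S$ within 2% relative error at 10,000 draws. With
$P_<$ the fraction of draws strictly below $a$ plus half the ties (and
$P_>$ symmetric), a pair is *positive* (co-occurrence) when
$P_< > 0.95$, *negative* (mutual exclusion) when $P_> > 0.95$, and
*unclassified* otherwise. Strict inequalities with half-tie counting were
chosen because they produce a genuine three-way outcome: some significant
pairs remain unclassified, which matches the arithmetic of reported
domain breakdowns in this literature where positives plus negatives can
fall short of the correlated total. Whether the threshold is `>` or `>=`
is immaterial for continuous-ish proportions but is documented here as
`>`.

## Association rules

A confidence-1 association rule A→B states that no sample contains A
without B, i.e. samples(A) ⊆ samples(B). With the pairwise overlap matrix
$O = XX^T$, the rule holds iff $O_{AB} = n_A$, so the exhaustive scan over
both directions of every pair is one matrix product plus a comparison
(the bit-parallel equivalent of screening each candidate rule for an
exception). `min_support` (default 1, i.e. only zero-occupancy origins
are excluded, since their confidence is undefined) can be raised because
single-occurrence origins generate many fragile rules; the default keeps
them, favouring fidelity of the exhaustive definition. Rules whose target
occurs in every sample are kept but flagged `ubiquitous_target`: such
targets are trivial supersets of everything, and whether they dominate a
data set is itself diagnostic. Soundness and completeness are tested
against a brute-force double-loop oracle on a thousand random 12×12
matrices, and set-theoretic invariants (transitive closure; reciprocal
rules exactly for identical sample sets) are asserted on random matrices.

Rules are directed, but direction does not identify the direction of a
biological dependency; the package therefore reports the rule network's
role structure rather than interpreting individual arrows. Fragments
participating *only* as rule targets, with high in-degree, are the
keystone candidates: many, apparently interchangeable, partners predict
their presence. `hub_roles()` ranks exclusive targets by in-degree and
exclusive origins by out-degree (`top_k = 25`), breaking ties
lexicographically by fragment id so reports are deterministic.

## Network topology

Both networks are reduced to their undirected simple view for the
topology panel (reciprocal rule pairs merge, so the undirected edge count
can be smaller than the rule count). Conventions, chosen to match the
widely used NetworkAnalyzer/Cytoscape definitions:

* density $2E/(N(N-1))$; average neighbors = mean degree $2E/N$;
* characteristic path length = mean shortest-path distance over
  *connected ordered pairs* — disconnected pairs are excluded rather than
  infinite, which keeps the statistic finite on modular, disconnected
  networks;
* clustering coefficient = mean local clustering with degree < 2 nodes
  contributing 0 and included in the mean (one convention had to be
  fixed; at realistic densities the alternative of excluding such nodes
  is within the Monte-Carlo noise of the random baselines);
* centralization = Freeman degree centralization
  $\sum_i (d_{max} - d_i) / ((N-1)(N-2))$, 1 for a star, 0 for a regular
  graph (undefined below 3 nodes, reported as an error);
* heterogeneity = population coefficient of variation of the degree
  distribution.

All five are verified against an independent plain-R implementation
(all-pairs BFS, neighborhood triangle counting) on random graphs of up to
50 nodes. The Erdős–Rényi baseline draws `er_reps = 100` uniform G(n,m)
graphs with the observed node and edge counts and averages path length
and clustering; in the dense regime the baseline clustering converges to
the graph density, which the tests assert within three Monte-Carlo
standard errors.

### Modularity

Community structure is evaluated on the *positive* co-occurrence edges
only — mutual exclusion and unclassified pairs do not indicate shared
niches — using Newman's $Q = \sum_c (e_{cc} - a_c^2)$ and the
deterministic fast-greedy agglomerative optimiser
(`igraph::cluster_fast_greedy`). The dendrogram cut is selected by
evaluating $Q$ at every achievable community count and taking the
maximum, preferring the fewest communities on ties (this matters for
degenerate graphs like a single clique, where several cuts tie at
$Q = 0$). The reported $Q$ is additionally verified in the tests by
direct evaluation of the formula on the returned membership — for every
partition, not just the optimum — via `modularity_score()`.

## Spatial profiles

`module_core_profile()` computes, per module and per core (sample
group), each member fragment's presence fraction over all samples of that
core — depth sections within a core are pooled, since the profile is a
per-location summary — and the module mean. Fragments outside any module
are reported under a pseudo-module `"unassigned"` for completeness.
Fractions conserve occupancy (the core-weighted sum of fractions equals
the fragment's total occupancy), which the tests assert.

## The synthetic community generator

The generator emulates the structure of a two-scale fingerprinting study
of a contaminated aquifer: a "bulk-like" preset (280 fragments × 72
samples over five cores, 27% archaeal fragments) and a "particle-like"
preset (620 fragments × 104 samples = 13 core sections × 8 particles,
48% archaeal). These shapes sit inside the 274–627 fragments and 72/104
samples of the emulated study design and are the problem sizes the test
suite runs at. Planted structure:

* **Modules**: blocks of 20 fragments tied to one core, present with
  `p_in = 0.9` inside (0.85 in the particle preset) and `p_out = 0.05`
  (0.1) outside. These values give within-module Fisher tests near-unit
  power at 72–104 samples while leaving cross-module pairs mostly
  non-significant — strong but not caricatural location structure.
* **Dependency rules**: hub-shaped, several origins nested inside one
  target's sample set (target occupancy ≈ half the samples, origins ≈ a
  third of the target's set), since the rule-network signature of
  interest is the exclusive-target hub. In the particle preset, origins
  are forced archaeal and targets bacterial, and archaeal background
  occupancy (0.06) is set below bacterial (0.20) — mirroring the
  empirical situation in which sparser archaea and ubiquitous bacteria
  bias chance rules in the same archaeum→bacterium direction.
* **Exclusions**: pairs with disjoint random sample sets of about a third
  of the samples each, large enough for the Fisher test to reach
  significance at these sample counts.
* **Noise**: i.i.d. cell flips at `noise_rate = 0.02` by default. Ground
  truth (in particular which planted rules survive) is recomputed on the
  final matrix by a direct subset check, because a single flip destroys a
  confidence-1 rule; at `noise_rate = 0` the surviving set provably
  equals the planted set.

What the generator does *not* emulate: abundances (everything is
binary), phylogenetic correlation between fragments, spatially explicit
particle geometry, detection thresholds that censor low-abundance taxa,
and enzyme-specific fragment sets. Passing the recovery tests therefore
shows that the statistical machinery recovers planted presence-absence
structure of realistic size and noise — it does not show that real
communities satisfy the generative assumptions, and inferred edges on
real data remain hypotheses requiring experimental verification.

## Determinism and seeds

Every stochastic stage accepts a seed and restores the caller's RNG
state. The pipeline derives per-stage seeds from one master seed by fixed
offsets, so a full run is reproducible end to end; the tests assert
byte-identical output bundles for repeated runs. Seeds derived from the
master stay within 32-bit integer range.

## Known limitations

* The Fisher test conditions on margins; fragments with extreme occupancy
  (0, 1, or all samples) can never reach significance, and ubiquitous
  fragments make rule targets trivially. Both are reported, not hidden.
* Confidence-1 rules are maximally brittle to false absences: a 2% flip
  rate destroys a substantial share of genuine dependencies (visible in
  the generator's `surviving_rules`). Raising `min_support` trades recall
  for robustness; confidence thresholds below 1 are deliberately out of
  scope.
* The empirical-FDR null conserves both margins, hence also any
  margin-driven co-occurrence; it measures the excess of the observed
  significant count over margin-explainable structure, not a per-pair
  error rate.
* Fast-greedy modularity is deterministic but greedy; on networks with
  weak structure it can merge small modules. The partition's $Q$ is
  always reported against the direct formula so alternatives can be
  scored with `modularity_score()`.
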
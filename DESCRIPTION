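Package: fragnet
Title: Co-Occurrence Networks and Association Rule Mining for Microbial
    Presence-Absence Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers putative microbial interaction networks from binary
    presence-absence community tables such as T-RFLP fingerprints or
    OTU/ASV incidence matrices. All fragment (taxon) pairs are tested for
    non-random co-occurrence with the two-sided Fisher exact test under
    Benjamini-Hochberg false discovery rate control; an empirical false
    discovery rate is estimated by fixed-margin (curveball) matrix
    randomization, and significant pairs are classified as co-occurrence or
    mutual exclusion against an occupancy-preserving null. One-sided
    dependencies are mined as confidence-1 association rules (fragment A
    never occurs without fragment B). Both relations are assembled into
    signed undirected and directed networks, for which the package computes
    standard topology panels (density, average neighbors, characteristic
    path length, clustering, centralization, heterogeneity), Erdos-Renyi
    G(n,m) baselines, Newman modularity on positive edges, per-location
    module presence profiles, and hub-role reports that flag exclusive
    rule-target hubs as keystone-taxon candidates. A synthetic community
    generator with planted modules, dependency rules and exclusions
    provides full ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    mclust,
    optparse,
    yaml
Config/testthat/edition: 3
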
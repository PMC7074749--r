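#' Build the signed co-occurrence network
#'
#' Significant fragment pairs become undirected edges carrying their sign
#' (`"positive"`, `"negative"`, or `"unclassified"` when the
#' occupancy-preserving null could not call a direction) and adjusted
#' p-value. Nodes are exactly the fragments participating in at least one
#' significant pair.
#'
#' @param results pair table from [all_pairs_test()]/[classify_sign()], or
#'   a [cooccur_fit][cooccurrence].
#' @param annotation optional
#'   [fragment_annotation][as_fragment_annotation]; adds a `domain` vertex
#'   attribute.
#' @return an undirected simple [igraph][igraph::graph] with edge
#'   attributes `sign` and `p_adj`.
#' @export
build_cooccurrence_network <- function(results, annotation = NULL) {
  if (inherits(results, "cooccur_fit")) results <- results$results
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    nodes <- unique(c(sig$fragment_1, sig$fragment_2))
    g <- igraph::graph_from_data_frame(
      data.frame(from = sig$fragment_1, to = sig$fragment_2,
                 sign = sig$sign, p_adj = sig$p_adj,
                 stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  }
  if (!is.null(annotation) && igraph::vcount(g) > 0)
    igraph::V(g)$domain <- fragment_domains(igraph::V(g)$name, annotation)
  g
}

#' Build the directed association rule network
#'
#' Each rule origin -> target becomes a directed edge; nodes are the
#' fragments taking part in at least one rule. Reciprocal rules (identical
#' sample sets) yield two opposite directed edges.
#'
#' @param rules a [rule_set][association_rules].
#' @param annotation optional
#'   [fragment_annotation][as_fragment_annotation]; adds a `domain` vertex
#'   attribute.
#' @return a directed simple [igraph][igraph::graph] with edge attribute
#'   `support` (origin occupancy).
#' @export
build_rule_network <- function(rules, annotation = NULL) {
  if (nrow(rules) == 0) {
    g <- igraph::make_empty_graph(0, directed = TRUE)
  } else {
    nodes <- unique(c(rules$origin, rules$target))
    g <- igraph::graph_from_data_frame(
      data.frame(from = rules$origin, to = rules$target,
                 support = rules$support_origin, stringsAsFactors = FALSE),
      directed = TRUE,
      vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  }
  if (!is.null(annotation) && igraph::vcount(g) > 0)
    igraph::V(g)$domain <- fragment_domains(igraph::V(g)$name, annotation)
  g
}

#' Topology panel of a fragment network
#'
#' Computes the standard undirected topology panel: density
#' 2E/(N(N-1)); average number of neighbors (mean degree); characteristic
#' path length (mean shortest-path distance over connected node pairs;
#' disconnected pairs are excluded, not infinite); clustering coefficient
#' (mean local clustering, with nodes of degree < 2 contributing 0);
#' Freeman degree centralization, sum(max deg - deg) / ((N-1)(N-2)), which
#' is 1 for a star and 0 for a regular graph; and heterogeneity, the
#' population coefficient of variation of the degree distribution.
#' Directed networks are first collapsed to their undirected simple view
#' (reciprocal edge pairs merge), so the undirected edge count may be
#' smaller than the rule count. Optionally an Erdos-Renyi G(n,m) baseline
#' with the same node and edge counts is averaged over `er_reps` draws.
#'
#' @param net an [igraph][igraph::graph] (directed or undirected).
#' @param all_fragments_count optional total number of detected fragments;
#'   yields `coverage`, the fraction of them present in the network.
#' @param er_reps number of G(n,m) baseline draws (0 = skip).
#' @param seed optional seed for the baseline draws.
#' @return a list of class `"topology_summary"`: `n_nodes`, `n_edges`,
#'   `density`, `avg_neighbors`, `characteristic_path_length`,
#'   `clustering_coefficient`, `centralization`, `heterogeneity`,
#'   `coverage` (NA unless `all_fragments_count` given), `random_cpl`,
#'   `random_cc` (NA unless `er_reps` > 0).
#' @export
network_topology <- function(net, all_fragments_count = NULL, er_reps = 0,
                             seed = NULL) {
  g <- igraph::as_undirected(net, mode = "collapse")
  g <- igraph::simplify(g)
  N <- igraph::vcount(g)
  E <- igraph::ecount(g)
  if (N == 0) stop("network is empty", call. = FALSE)
  if (N < 3) stop("centralization undefined for networks with fewer than 3 nodes",
                  call. = FALSE)
  deg <- igraph::degree(g)
  cpl <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  if (!is.finite(cpl))
    stop("characteristic path length undefined: no connected node pair",
         call. = FALSE)
  loc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  loc[is.nan(loc)] <- 0
  er <- if (er_reps > 0) er_baseline(N, E, n_reps = er_reps, seed = seed) else NULL
  out <- list(
    n_nodes = N,
    n_edges = E,
    coverage = if (!is.null(all_fragments_count)) N / all_fragments_count else NA_real_,
    density = 2 * E / (N * (N - 1)),
    avg_neighbors = mean(deg),
    characteristic_path_length = cpl,
    clustering_coefficient = mean(loc),
    centralization = sum(max(deg) - deg) / ((N - 1) * (N - 2)),
    heterogeneity = sd_pop(deg) / mean(deg),
    random_cpl = if (!is.null(er)) er$mean_cpl else NA_real_,
    random_cc = if (!is.null(er)) er$mean_clustering else NA_real_
  )
  class(out) <- "topology_summary"
  out
}

#' @export
print.topology_summary <- function(x, ...) {
  f <- function(v) if (is.na(v)) "-" else signif(v, 3)
  cat("Network coverage:            ", if (is.na(x$coverage)) "-" else
    paste0(round(100 * x$coverage), "%"), "\n", sep = "")
  cat("Number of nodes/edges:       ", x$n_nodes, "/", x$n_edges, "\n", sep = "")
  cat("Density:                     ", f(x$density), "\n", sep = "")
  cat("Avg. number of neighbors:    ", f(x$avg_neighbors), "\n", sep = "")
  cat("Characteristic path length:  ", f(x$characteristic_path_length), "\n", sep = "")
  if (!is.na(x$random_cpl))
    cat("  on random network:         ", f(x$random_cpl), "\n", sep = "")
  cat("Clustering coefficient:      ", f(x$clustering_coefficient), "\n", sep = "")
  if (!is.na(x$random_cc))
    cat("  on random network:         ", f(x$random_cc), "\n", sep = "")
  cat("Centralization:              ", f(x$centralization), "\n", sep = "")
  cat("Heterogeneity:               ", f(x$heterogeneity), "\n", sep = "")
  invisible(x)
}

#' Erdos-Renyi G(n,m) random graphs and baselines
#'
#' `er_random_graph()` draws one graph uniformly among all simple
#' undirected graphs with `n` nodes and `m` distinct edges.
#' `er_baseline()` averages the characteristic path length and mean local
#' clustering (degree < 2 contributing 0) over `n_reps` such draws --
#' the reference panel against which an observed network's path length and
#' clustering are judged.
#'
#' @param n number of nodes.
#' @param m number of edges; must not exceed n(n-1)/2.
#' @param seed optional RNG seed.
#' @return `er_random_graph()`: an igraph; `er_baseline()`: a list with
#'   `mean_cpl`, `mean_clustering`, their standard errors `se_cpl`,
#'   `se_clustering`, and the per-draw vectors `cpl`, `clustering`.
#' @export
er_random_graph <- function(n, m, seed = NULL) {
  if (m > n * (n - 1) / 2)
    stop("more edges requested than distinct node pairs", call. = FALSE)
  with_seed(seed, igraph::sample_gnm(n, m, directed = FALSE))
}

#' @rdname er_random_graph
#' @param n_reps number of draws (default 100).
#' @export
er_baseline <- function(n, m, n_reps = 100, seed = NULL) {
  cpl <- numeric(n_reps)
  cc <- numeric(n_reps)
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      g <- igraph::sample_gnm(n, m, directed = FALSE)
      cpl[r] <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
      loc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
      loc[is.nan(loc)] <- 0
      cc[r] <- mean(loc)
    }
  })
  list(mean_cpl = mean(cpl), mean_clustering = mean(cc),
       se_cpl = stats::sd(cpl) / sqrt(n_reps),
       se_clustering = stats::sd(cc) / sqrt(n_reps),
       cpl = cpl, clustering = cc)
}

#' Newman modularity partition of the positive co-occurrence network
#'
#' Restricts the signed network to its positive edges (mutual exclusions
#' and unclassified pairs are dropped, as only co-presence defines a
#' community), then optimizes Newman's modularity Q = sum_c (e_cc - a_c^2)
#' with the deterministic fast-greedy agglomerative algorithm
#' ([igraph::cluster_fast_greedy()]). e_cc is the fraction of edges inside
#' community c and a_c the fraction of edge ends attached to it.
#'
#' @param net a signed co-occurrence network from
#'   [build_cooccurrence_network()].
#' @return a list of class `"module_partition"`: `membership` (named
#'   integer vector over the positive-subgraph nodes), `q`, `module_sizes`,
#'   `n_modules`, `n_modules_gt3` (modules with more than 3 fragments).
#' @export
modularity_partition <- function(net) {
  if (is.null(igraph::edge_attr(net, "sign")))
    stop("network has no 'sign' edge attribute; build it from pair results",
         call. = FALSE)
  pos <- igraph::subgraph_from_edges(
    net, igraph::E(net)[igraph::E(net)$sign == "positive"],
    delete.vertices = TRUE)
  if (igraph::ecount(pos) == 0)
    stop("no positive edges; modularity undefined", call. = FALSE)
  pos <- igraph::simplify(pos)
  cm <- igraph::cluster_fast_greedy(pos)
  # pick the dendrogram cut with maximal Q; on ties, the fewest communities
  ks <- seq(igraph::count_components(pos), igraph::vcount(pos))
  qs <- vapply(ks, function(k)
    igraph::modularity(pos, igraph::cut_at(cm, no = k)), numeric(1))
  best <- which(qs >= max(qs) - 1e-12)[1]
  membership <- igraph::cut_at(cm, no = ks[best])
  names(membership) <- igraph::V(pos)$name
  sizes <- as.integer(table(membership))
  out <- list(membership = membership,
              q = qs[best],
              module_sizes = sizes,
              n_modules = length(sizes),
              n_modules_gt3 = sum(sizes > 3))
  class(out) <- "module_partition"
  out
}

#' @export
print.module_partition <- function(x, ...) {
  cat("Modularity Q = ", signif(x$q, 3), "; ", x$n_modules, " modules (",
      x$n_modules_gt3, " with > 3 fragments)\n", sep = "")
  cat("Module sizes:", paste(sort(x$module_sizes, decreasing = TRUE),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate Newman's Q for an arbitrary membership
#'
#' Direct evaluation of Q = sum_c (e_cc - a_c^2) on an undirected graph for
#' a given node-to-community assignment; used to audit the partition
#' returned by the optimizer and to score alternative partitions.
#'
#' @param net an undirected [igraph][igraph::graph].
#' @param membership community ids, named by node or in `V(net)` order.
#' @return the modularity score.
#' @export
modularity_score <- function(net, membership) {
  g <- igraph::simplify(igraph::as_undirected(net, mode = "collapse"))
  if (!is.null(names(membership)))
    membership <- membership[igraph::V(g)$name]
  m <- igraph::ecount(g)
  if (m == 0) return(0)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  comm <- as.integer(factor(membership))
  e_within <- sum(comm[ends[, 1]] == comm[ends[, 2]]) / m
  deg <- igraph::degree(g)
  a_c <- vapply(split(deg, comm), sum, numeric(1)) / (2 * m)
  e_within - sum(a_c^2)
}

#' Degree distribution with domain composition
#'
#' For each observed degree value in the (undirected view of the) network,
#' counts nodes and the fraction of them that are bacterial -- the
#' hub-composition profile distinguishing archaeal-hub from bacterial-hub
#' regimes.
#'
#' @param net an [igraph][igraph::graph] whose vertices carry a `domain`
#'   attribute (or supply `annotation`).
#' @param annotation optional
#'   [fragment_annotation][as_fragment_annotation].
#' @return data frame with columns `degree`, `n_nodes`,
#'   `fraction_bacterial`, ordered by degree.
#' @export
degree_domain_profile <- function(net, annotation = NULL) {
  g <- igraph::as_undirected(net, mode = "collapse")
  dom <- if (!is.null(annotation))
    fragment_domains(igraph::V(g)$name, annotation)
  else igraph::V(g)$domain
  if (is.null(dom)) stop("no domain information available", call. = FALSE)
  deg <- igraph::degree(g)
  out <- do.call(rbind, lapply(sort(unique(deg)), function(d) {
    sel <- deg == d
    data.frame(degree = d, n_nodes = sum(sel),
               fraction_bacterial = mean(dom[sel] == "bacterial"))
  }))
  rownames(out) <- NULL
  out
}

#' Hub roles in the association rule network
#'
#' Classifies every fragment of the directed rule network by its role:
#' `target_only` (incoming rules only), `origin_only` (outgoing only),
#' `mixed`, or `isolated`. Exclusive high-in-degree targets are the
#' keystone-taxon candidates: their presence is predicted by many,
#' apparently interchangeable, partner fragments. Returns the top-k
#' exclusive targets (by in-degree) and exclusive origins (by out-degree),
#' ties broken lexicographically by fragment id for determinism, together
#' with the bacterial fraction of each list.
#'
#' @param rnet a rule network from [build_rule_network()].
#' @param k list length (default 25).
#' @param annotation optional
#'   [fragment_annotation][as_fragment_annotation] when the network lacks
#'   a `domain` attribute.
#' @return a list of class `"hub_report"`: `nodes` (data frame fragment,
#'   in_degree, out_degree, role, domain), `top_targets`, `top_origins`,
#'   `fraction_bacterial_targets`, `fraction_bacterial_origins`.
#' @export
hub_roles <- function(rnet, k = 25, annotation = NULL) {
  if (igraph::vcount(rnet) == 0) stop("empty rule network", call. = FALSE)
  ind <- igraph::degree(rnet, mode = "in")
  outd <- igraph::degree(rnet, mode = "out")
  nm <- igraph::V(rnet)$name
  role <- ifelse(ind > 0 & outd == 0, "target_only",
          ifelse(outd > 0 & ind == 0, "origin_only",
          ifelse(ind > 0 & outd > 0, "mixed", "isolated")))
  dom <- if (!is.null(annotation)) fragment_domains(nm, annotation)
         else igraph::V(rnet)$domain
  if (is.null(dom)) dom <- NA_character_
  nodes <- data.frame(fragment = nm, in_degree = as.integer(ind),
                      out_degree = as.integer(outd), role = role,
                      domain = dom, stringsAsFactors = FALSE)
  top_of <- function(df, degcol) {
    df <- df[order(-df[[degcol]], df$fragment), , drop = FALSE]
    utils::head(df, k)
  }
  tt <- top_of(nodes[nodes$role == "target_only", , drop = FALSE], "in_degree")
  to <- top_of(nodes[nodes$role == "origin_only", , drop = FALSE], "out_degree")
  out <- list(nodes = nodes, top_targets = tt, top_origins = to,
              fraction_bacterial_targets =
                if (nrow(tt)) mean(tt$domain == "bacterial") else NA_real_,
              fraction_bacterial_origins =
                if (nrow(to)) mean(to$domain == "bacterial") else NA_real_,
              k = k)
  class(out) <- "hub_report"
  out
}

#' @export
print.hub_report <- function(x, ...) {
  cat("Hub roles over", nrow(x$nodes), "fragments:",
      sum(x$nodes$role == "target_only"), "target-only,",
      sum(x$nodes$role == "origin_only"), "origin-only,",
      sum(x$nodes$role == "mixed"), "mixed\n")
  cat("Top", nrow(x$top_targets), "exclusive targets (bacterial fraction",
      signif(x$fraction_bacterial_targets, 3), "):\n")
  print(utils::head(x$top_targets, 5))
  cat("Top", nrow(x$top_origins), "exclusive origins (bacterial fraction",
      signif(x$fraction_bacterial_origins, 3), "):\n")
  print(utils::head(x$top_origins, 5))
  invisible(x)
}

#' Rule neighborhood of a hub with co-occurrence overlay
#'
#' Extracts the hub fragment and all fragments linked to it by a rule in
#' either direction, every rule edge among those fragments, and -- as an
#' overlay -- every positive significant co-occurrence edge among them.
#' Partners of a keystone candidate that do not co-occur with each other
#' indicate alternative (interchangeable) interaction partners.
#'
#' @param rnet rule network from [build_rule_network()].
#' @param cnet signed co-occurrence network from
#'   [build_cooccurrence_network()].
#' @param hub fragment id; must be a node of `rnet`.
#' @return a list of class `"hub_neighborhood"`: `hub`, `nodes`, `rules`
#'   (data frame origin/target), `overlay` (data frame of positive
#'   co-occurrence pairs among the nodes).
#' @export
hub_neighborhood <- function(rnet, cnet, hub) {
  if (!hub %in% igraph::V(rnet)$name)
    stop("hub fragment not in rule network: ", hub, call. = FALSE)
  nb <- igraph::neighbors(rnet, hub, mode = "all")$name
  nodes <- unique(c(hub, nb))
  sub <- igraph::induced_subgraph(rnet, nodes)
  re <- igraph::as_data_frame(sub, what = "edges")
  overlay <- data.frame(fragment_1 = character(), fragment_2 = character(),
                        stringsAsFactors = FALSE)
  common <- intersect(nodes, igraph::V(cnet)$name)
  if (length(common) >= 2) {
    cs <- igraph::induced_subgraph(cnet, common)
    ce <- igraph::as_data_frame(cs, what = "edges")
    ce <- ce[ce$sign == "positive", , drop = FALSE]
    if (nrow(ce))
      overlay <- data.frame(fragment_1 = ce$from, fragment_2 = ce$to,
                            stringsAsFactors = FALSE)
  }
  structure(list(hub = hub, nodes = nodes,
                 rules = re[, c("from", "to"), drop = FALSE],
                 overlay = overlay),
            class = "hub_neighborhood")
}

#' @export
print.hub_neighborhood <- function(x, ...) {
  cat("Neighborhood of hub '", x$hub, "': ", length(x$nodes) - 1,
      " rule partners, ", nrow(x$rules), " rule edges, ", nrow(x$overlay),
      " positive co-occurrence overlay edges\n", sep = "")
  invisible(x)
}

#' Network export and import
#'
#' `write_graphml()` exports any fragment network with its vertex/edge
#' attributes (domain, sign, p_adj, support, direction) to GraphML;
#' `read_graphml()` reads it back, round-tripping node set, edge set and
#' attributes. `write_edge_list()` writes a plain TSV edge list: for signed
#' networks `fragment_1, fragment_2, sign, p_adj`; for directed rule
#' networks `origin, target, support`.
#'
#' @param net an [igraph][igraph::graph].
#' @param path output file path.
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @export
read_graphml <- function(path) {
  igraph::read_graph(path, format = "graphml")
}

#' @rdname write_graphml
#' @export
write_edge_list <- function(net, path) {
  df <- igraph::as_data_frame(net, what = "edges")
  if (igraph::is_directed(net)) {
    names(df)[1:2] <- c("origin", "target")
  } else {
    names(df)[1:2] <- c("fragment_1", "fragment_2")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
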
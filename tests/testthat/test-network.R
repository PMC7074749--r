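test_that("network construction keeps significant pairs and directions", {
  res <- data.frame(fragment_1 = c("A", "A", "B", "C"),
                    fragment_2 = c("B", "C", "C", "D"),
                    p_adj = c(0.01, 0.01, 0.01, 0.5),
                    significant = c(TRUE, TRUE, TRUE, FALSE),
                    sign = c("positive", "positive", "negative", "unclassified"))
  net <- build_cooccurrence_network(res)
  expect_equal(igraph::vcount(net), 3)  # D drops out with its pair
  expect_equal(igraph::ecount(net), 3)  # triangle
  expect_false(igraph::is_directed(net))

  expect_equal(igraph::vcount(build_cooccurrence_network(res[res$p_adj > 0.1, ])), 0)

  rules <- data.frame(origin = c("A", "C", "X"), target = c("B", "B", "Y"),
                      support_origin = c(2, 3, 1))
  rnet <- build_rule_network(rules)
  expect_true(igraph::is_directed(rnet))
  expect_equal(unname(igraph::degree(rnet, "B", mode = "in")), 2)
  # reciprocal rules keep both directed edges
  rec <- build_rule_network(data.frame(origin = c("A", "B"), target = c("B", "A"),
                                       support_origin = 1))
  expect_equal(igraph::ecount(rec), 2)
})

test_that("topology metrics match closed forms on canonical graphs", {
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- paste0("n", 1:5)
  t5 <- network_topology(k5)
  expect_equal(t5$density, 1)
  expect_equal(t5$characteristic_path_length, 1)
  expect_equal(t5$clustering_coefficient, 1)
  expect_equal(t5$centralization, 0)
  expect_equal(t5$heterogeneity, 0)

  p3 <- igraph::make_graph(~ a - b - c)
  t3 <- network_topology(p3)
  expect_equal(t3$characteristic_path_length, 4 / 3)
  expect_equal(t3$clustering_coefficient, 0)
  expect_equal(t3$avg_neighbors, 4 / 3)

  expect_error(network_topology(igraph::make_graph(~ a - b)), "fewer than 3")
  expect_error(network_topology(igraph::make_empty_graph(4, directed = FALSE)),
               "no connected")
})

test_that("density and mean degree follow their closed forms everywhere", {
  set.seed(31)
  for (k in 1:20) {
    n <- sample(5:40, 1)
    m <- sample(seq_len(n * (n - 1) / 2), 1)
    topo <- network_topology(er_random_graph(n, m, seed = 500 + k))
    expect_equal(topo$density, 2 * m / (n * (n - 1)))
    expect_equal(topo$avg_neighbors, 2 * m / n)
  }
})

test_that("topology agrees with the brute-force BFS/triangle oracle", {
  set.seed(37)
  for (k in 1:20) {
    n <- sample(8:50, 1)
    m <- sample(n:min(3 * n, n * (n - 1) / 2), 1)
    fx <- random_graph_fixture(n, m, seed = 600 + k)
    topo <- network_topology(fx$g)
    oracle <- oracle_topology(fx$adj)
    expect_equal(topo$density, oracle$density)
    expect_equal(topo$avg_neighbors, oracle$avg_neighbors)
    expect_equal(topo$characteristic_path_length, oracle$cpl)
    expect_equal(topo$clustering_coefficient, oracle$clustering)
    expect_equal(topo$centralization, oracle$centralization)
    expect_equal(topo$heterogeneity, oracle$heterogeneity)
  }
})

test_that("directed rule networks collapse reciprocal pairs for topology", {
  rules <- data.frame(origin = c("A", "B", "A", "C"),
                      target = c("B", "A", "C", "D"),
                      support_origin = 1)
  topo <- network_topology(build_rule_network(rules))
  expect_equal(topo$n_edges, 3)  # A<->B merges
  expect_equal(topo$avg_neighbors, 6 / 4)
})

test_that("G(n,m) sampling is exact in edge count and degenerate cases", {
  g <- er_random_graph(4, 6, seed = 1)
  expect_equal(igraph::ecount(g), 6)
  expect_equal(sort(unname(igraph::degree(g))), rep(3, 4))  # forced K4
  expect_error(er_random_graph(4, 7), "more edges")
  expect_identical(igraph::as_edgelist(er_random_graph(30, 60, seed = 9)),
                   igraph::as_edgelist(er_random_graph(30, 60, seed = 9)))
})

test_that("modularity partitions recover planted structure and report true Q", {
  # two disjoint triangles: Q = 0.5, two modules
  res <- data.frame(
    fragment_1 = c("A", "A", "B", "X", "X", "Y"),
    fragment_2 = c("B", "C", "C", "Y", "Z", "Z"),
    p_adj = 0.01, significant = TRUE, sign = "positive")
  net <- build_cooccurrence_network(res)
  mp <- modularity_partition(net)
  expect_equal(mp$q, 0.5)
  expect_equal(mp$n_modules, 2)
  expect_equal(mp$q, modularity_score(net, mp$membership))

  # a single clique cannot be improved by division
  clique <- data.frame(fragment_1 = c("A", "A", "B"), fragment_2 = c("B", "C", "C"),
                       p_adj = 0.01, significant = TRUE, sign = "positive")
  mc <- modularity_partition(build_cooccurrence_network(clique))
  expect_equal(mc$q, 0)
  expect_equal(mc$n_modules, 1)

  # reported Q always equals direct evaluation of the formula
  set.seed(41)
  for (k in 1:10) {
    fx <- random_graph_fixture(20, 40, seed = 700 + k)
    g <- fx$g
    igraph::E(g)$sign <- "positive"
    m <- modularity_partition(g)
    expect_equal(m$q, modularity_score(g, m$membership), tolerance = 1e-12)
    # and scoring a random membership never beats the optimizer by much
    rand_q <- modularity_score(g, setNames(sample(1:3, 20, TRUE),
                                           igraph::V(g)$name))
    expect_gte(m$q, rand_q - 1e-9)
  }

  neg <- data.frame(fragment_1 = "A", fragment_2 = "B", p_adj = 0.01,
                    significant = TRUE, sign = "negative")
  expect_error(modularity_partition(build_cooccurrence_network(neg)),
               "no positive edges")
})

test_that("degree profiles report domain composition per degree level", {
  ann <- as_fragment_annotation(data.frame(
    fragment_id = c("A", "B", "C", "H", "l1", "l2", "l3", "l4"),
    domain = c(rep("bacterial", 3), "archaeal", rep("bacterial", 4))))
  tri <- data.frame(fragment_1 = c("A", "A", "B"), fragment_2 = c("B", "C", "C"),
                    p_adj = 0.01, significant = TRUE, sign = "positive")
  prof <- degree_domain_profile(build_cooccurrence_network(tri, ann))
  expect_equal(prof, data.frame(degree = 2, n_nodes = 3, fraction_bacterial = 1))

  star <- data.frame(origin = paste0("l", 1:4), target = "H", support_origin = 1)
  prof2 <- degree_domain_profile(build_rule_network(star, ann))
  expect_equal(prof2$degree, c(1, 4))
  expect_equal(prof2$n_nodes, c(4, 1))
  expect_equal(prof2$fraction_bacterial, c(1, 0))
})

test_that("hub roles split exclusive targets from exclusive origins", {
  star <- build_rule_network(data.frame(origin = c("A", "C", "D"), target = "B",
                                        support_origin = 1))
  hr <- hub_roles(star, k = 25)
  expect_equal(hr$nodes$role[hr$nodes$fragment == "B"], "target_only")
  expect_equal(hr$top_targets$fragment[1], "B")
  expect_equal(hr$top_targets$in_degree[1], 3)
  expect_setequal(hr$nodes$fragment[hr$nodes$role == "origin_only"],
                  c("A", "C", "D"))

  # a node with one incoming and one outgoing rule is mixed and listed nowhere
  chain <- build_rule_network(data.frame(origin = c("A", "B"), target = c("B", "C"),
                                         support_origin = 1))
  hc <- hub_roles(chain)
  expect_equal(hc$nodes$role[hc$nodes$fragment == "B"], "mixed")
  expect_false("B" %in% c(hc$top_targets$fragment, hc$top_origins$fragment))

  # 30 target-only nodes, k = 25: exactly 25 back, deterministic tie order
  rules <- do.call(rbind, lapply(1:30, function(i) data.frame(
    origin = paste0("o", i), target = sprintf("T%02d", i), support_origin = 1)))
  hr30 <- hub_roles(build_rule_network(rules), k = 25)
  expect_equal(nrow(hr30$top_targets), 25)
  expect_equal(hr30$top_targets$fragment, sprintf("T%02d", 1:25))  # lexicographic ties
})

test_that("hub neighborhoods overlay positive co-occurrence on rule partners", {
  rules <- data.frame(origin = c("A", "B", "C", "D"), target = c("H", "H", "H", "E"),
                      support_origin = 1)
  rnet <- build_rule_network(rules)
  res <- data.frame(fragment_1 = c("A", "A"), fragment_2 = c("B", "D"),
                    p_adj = 0.01, significant = TRUE, sign = "positive")
  cnet <- build_cooccurrence_network(res)
  nb <- hub_neighborhood(rnet, cnet, "H")
  expect_setequal(nb$nodes, c("H", "A", "B", "C"))
  expect_equal(nrow(nb$rules), 3)
  # only A-B lies inside the neighborhood; A-D's partner D is not a rule partner
  expect_equal(pair_key(nb$overlay$fragment_1, nb$overlay$fragment_2), "A B")

  res_none <- res[0, ]
  nb2 <- hub_neighborhood(rnet, build_cooccurrence_network(res_none), "H")
  expect_equal(nrow(nb2$overlay), 0)
  expect_error(hub_neighborhood(rnet, cnet, "ZZZ"), "ZZZ")
})

test_that("rule/co-occurrence intersection counts shared pairs", {
  rules <- structure(data.frame(origin = c("A", "B", "C", "D", "E"),
                                target = c("B", "C", "D", "E", "F")),
                     class = c("rule_set", "data.frame"))
  none <- data.frame(fragment_1 = "X", fragment_2 = "Y", significant = TRUE)
  expect_equal(rule_cooccurrence_intersection(rules, none)$n_intersect, 0)

  all_pairs <- data.frame(fragment_1 = rules$origin, fragment_2 = rules$target,
                          significant = TRUE)
  expect_equal(rule_cooccurrence_intersection(rules, all_pairs)$fraction, 1)

  two <- data.frame(fragment_1 = c("B", "E"), fragment_2 = c("A", "D"),
                    significant = TRUE)  # unordered matching
  expect_equal(rule_cooccurrence_intersection(rules, two)$fraction, 0.4)
})
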
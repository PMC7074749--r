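test_that("matrix reading thresholds, validates and round-trips", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("fragment_id\ts1\ts2", "A\t1\t0", "B\t0\t1"), tmp)
  m <- read_pa_matrix(tmp)
  expect_equal(unname(occupancy(m)), c(1, 1))
  expect_equal(rownames(m), c("A", "B"))

  # any strictly positive value is presence
  writeLines(c("fragment_id\ts1\ts2", "A\t3\t0.5", "B\t0\t2"), tmp)
  expect_equal(as.vector(unclass(read_pa_matrix(tmp))), c(1L, 0L, 1L, 1L))

  # duplicated fragment id names the offender
  writeLines(c("fragment_id\ts1\ts2", "A\t1\t0", "A\t0\t1"), tmp)
  expect_error(read_pa_matrix(tmp), "duplicated fragment id.*A")

  # non-numeric cell names row and column
  writeLines(c("fragment_id\ts1\ts2", "A\t1\tx", "B\t0\t1"), tmp)
  expect_error(read_pa_matrix(tmp), "fragment 'A', sample 's2'")

  # write -> read reproduces ids, order and values for both dialects
  m <- random_pa(15, 9, seed = 42)
  for (dia in c("tsv", "csv")) {
    f <- withr::local_tempfile(fileext = paste0(".", dia))
    write_pa_matrix(m, f, dialect = dia)
    expect_identical(unclass(read_pa_matrix(f, dialect = dia)), unclass(m))
  }
})

test_that("contingency tables count the four sample classes", {
  m <- as_pa_matrix(matrix(c(1, 1, 0, 0, 1, 0, 1, 0), nrow = 2, byrow = TRUE,
                           dimnames = list(c("A", "B"), paste0("s", 1:4))))
  expect_equal(contingency_table(m, "A", "B"), c(a = 1, b = 1, c = 1, d = 1))

  # identical fragments: all mass on a and d
  M <- matrix(0L, 2, 10, dimnames = list(c("A", "B"), paste0("s", 1:10)))
  M[, 1:4] <- 1L
  expect_equal(contingency_table(as_pa_matrix(M), "A", "B"),
               c(a = 4, b = 0, c = 0, d = 6))

  # empty row: a = b = 0
  m <- as_pa_matrix(matrix(c(0, 0, 0, 1, 0, 1), nrow = 2, byrow = TRUE,
                           dimnames = list(c("A", "B"), paste0("s", 1:3))))
  tab <- contingency_table(m, "A", "B")
  expect_equal(unname(tab[c("a", "b")]), c(0, 0))

  expect_error(contingency_table(m, "A", "A"), "distinct")
  expect_error(contingency_table(m, "A", "Z"), "unknown fragment id: Z")
})

test_that("contingency table is symmetric with b and c exchanged", {
  m <- random_pa(10, 12, seed = 7)
  ids <- rownames(m)
  for (k in 1:10) {
    ij <- sample(ids, 2)
    t1 <- contingency_table(m, ij[1], ij[2])
    t2 <- contingency_table(m, ij[2], ij[1])
    expect_equal(unname(t1[c("a", "b", "c", "d")]),
                 unname(t2[c("a", "c", "b", "d")]))
    expect_equal(sum(t1), ncol(m))
  }
})

test_that("annotation and metadata validate their schemas", {
  ann <- as_fragment_annotation(data.frame(
    fragment_id = c("A", "B"), domain = c("bacterial", "archaeal"),
    species = c("Smithella/Desulfobulbaceae", "")))
  expect_equal(fragment_domains(c("B", "A"), ann), c("archaeal", "bacterial"))
  expect_error(fragment_domains(c("A", "Z"), ann), "Z")
  expect_error(as_fragment_annotation(
    data.frame(fragment_id = "A", domain = "fungal")), "bacterial")

  f <- withr::local_tempfile(fileext = ".tsv")
  write_fragment_annotation(ann, f)
  expect_equal(read_fragment_annotation(f)$domain, ann$domain)

  expect_error(as_sample_metadata(data.frame(
    sample_id = "s1", core = "C1", scale = "bulk", particle_index = 3)),
    "particle_index")
  meta <- as_sample_metadata(data.frame(
    sample_id = c("s1", "s2"), core = "C1", scale = "particle",
    particle_index = 1:2))
  g <- withr::local_tempfile(fileext = ".tsv")
  write_sample_metadata(meta, g)
  expect_equal(read_sample_metadata(g)$particle_index, 1:2)
})

test_that("network exports round-trip nodes, edges, signs and direction", {
  res <- data.frame(fragment_1 = c("A", "A", "B"), fragment_2 = c("B", "C", "C"),
                    p_adj = c(0.01, 0.02, 0.2), significant = c(TRUE, TRUE, FALSE),
                    sign = c("positive", "negative", "unclassified"))
  net <- build_cooccurrence_network(res)
  f <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, f)
  back <- read_graphml(f)
  expect_setequal(igraph::V(back)$name, c("A", "B", "C"))
  eb <- igraph::as_data_frame(back)
  expect_setequal(pair_key(eb$from, eb$to), c("A B", "A C"))
  expect_setequal(eb$sign, c("positive", "negative"))

  rules <- association_rules(as_pa_matrix(matrix(
    c(1, 0, 0, 1, 1, 0), 2, byrow = TRUE,
    dimnames = list(c("A", "B"), paste0("s", 1:3)))))
  rnet <- build_rule_network(rules)
  write_graphml(rnet, f)
  back <- read_graphml(f)
  expect_true(igraph::is_directed(back))
  expect_equal(igraph::as_data_frame(back)[, c("from", "to")],
               data.frame(from = "A", to = "B"))

  # empty network still yields a valid file with zero edges
  empty <- build_cooccurrence_network(res[0, ])
  write_graphml(empty, f)
  expect_equal(igraph::ecount(read_graphml(f)), 0)

  g <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(rnet, g)
  el <- read.delim(g)
  expect_equal(el$origin, "A")
  expect_equal(el$target, "B")
})
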
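test_that("fixed-margin randomization conserves both margin vectors", {
  for (seed in 1:5) {
    m <- random_pa(15, 12, fill = 0.3, seed = seed)
    r <- randomize_fixed_margins(m, seed = 100 + seed)
    expect_identical(rowSums(unclass(r)), rowSums(unclass(m)))
    expect_identical(colSums(unclass(r)), colSums(unclass(m)))
  }
  # margins conserved on every draw of a longer series (asserted per draw)
  m <- random_pa(20, 15, fill = 0.35, seed = 9)
  for (rep in 1:20) {
    r <- randomize_fixed_margins(m, seed = rep)
    expect_identical(rowSums(unclass(r)), rowSums(unclass(m)))
    expect_identical(colSums(unclass(r)), colSums(unclass(m)))
  }
})

test_that("the 2x2 identity matrix stays within its two-state space", {
  m <- as_pa_matrix(matrix(c(1, 0, 0, 1), 2,
                           dimnames = list(c("A", "B"), c("s1", "s2"))))
  seen <- vapply(1:20, function(s) {
    r <- unclass(randomize_fixed_margins(m, seed = s))
    paste(r, collapse = "")
  }, character(1))
  expect_true(all(seen %in% c("1001", "0110")))
  expect_gt(length(unique(seen)), 1)  # the chain actually moves
})

test_that("long chains shuffle a random matrix away from its start", {
  m <- random_pa(10, 10, fill = 0.4, seed = 3)
  r <- randomize_fixed_margins(m, seed = 17)
  expect_gt(mean(unclass(r) != unclass(m)), 0)
})

test_that("randomized draws match vegan's curveball null in margins", {
  skip_if_not_installed("vegan")
  m <- random_pa(12, 10, fill = 0.4, seed = 21)
  nm <- vegan::nullmodel(unclass(m), "curveball")
  sims <- stats::simulate(nm, nsim = 5, seed = 33)
  for (k in 1:5) {
    expect_identical(rowSums(sims[, , k]), rowSums(unclass(m)))
    expect_identical(colSums(sims[, , k]), colSums(unclass(m)))
  }
})

test_that("occupancy-null co-occurrence mean converges to nA*nB/S", {
  # pair with occupancies 4 and 6 over 12 samples: expectation 2.0
  M <- matrix(0L, 2, 12, dimnames = list(c("A", "B"), sprintf("s%02d", 1:12)))
  M[1, 1:4] <- 1L; M[2, 3:8] <- 1L
  m <- as_pa_matrix(M)
  res <- all_pairs_test(m)
  res$significant <- TRUE  # force classification of the single pair
  cl <- classify_sign(m, res, n_reps = 10000, seed = 12)
  expect_lt(abs(cl$expected_cooccurrence[1] - 2.0) / 2.0, 0.02)
})

test_that("extreme observed overlaps classify as positive and negative", {
  M <- matrix(0L, 4, 12, dimnames = list(LETTERS[1:4], sprintf("s%02d", 1:12)))
  M[1, 1:6] <- 1L; M[2, 1:6] <- 1L   # identical, occupancy 6 of 12
  M[3, 1:6] <- 1L; M[4, 7:12] <- 1L  # disjoint halves
  m <- as_pa_matrix(M)
  res <- classify_sign(m, all_pairs_test(m), n_reps = 2000, seed = 5)
  key <- pair_key(res$fragment_1, res$fragment_2)
  expect_equal(res$sign[key == "A B"], "positive")
  expect_equal(res$sign[key == "C D"], "negative")
  expect_equal(res$sign[res$significant == FALSE & !key %in% c("A B", "C D")],
               rep("unclassified", sum(!res$significant & !key %in% c("A B", "C D"))))
})

test_that("empirical FDR contrasts independent noise with planted structure", {
  # independent noise: nothing significant after BH, guarded ratio is 0
  noise <- random_pa(25, 30, fill = 0.4, seed = 14)
  f <- estimate_fdr(noise, n_reps = 3, seed = 2)
  if (f$observed_significant == 0) {
    expect_equal(f$estimated_fdr, 0)
  } else {
    expect_gt(f$estimated_fdr, 0.5)  # null calls track observed calls
  }

  # strong planted modules: null calls are a small fraction of observed
  cfg <- synthetic_config(
    n_fragments = 30, n_samples = 40,
    sample_groups = rep(c("C1", "C2"), each = 20),
    module_specs = list(list(size = 10, groups = "C1"),
                        list(size = 10, groups = "C2")),
    background_occupancy = 0.3, noise_rate = 0.02, seed = 3)
  sim <- synthetic_community(cfg)
  fp <- estimate_fdr(sim$matrix, n_reps = 5, seed = 8)
  expect_gt(fp$observed_significant, 0)
  expect_lt(fp$estimated_fdr, 0.2)

  # a single replicate reports that replicate's count as the mean
  f1 <- estimate_fdr(noise, n_reps = 1, seed = 4)
  expect_equal(f1$mean_significant_on_null, f1$null_counts[1])
})
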
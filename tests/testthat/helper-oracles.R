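# Independent brute-force oracles, deliberately implemented with different
# primitives than the package (choose() enumeration, plain-R BFS, double
# loops) so agreement is meaningful.

# two-sided Fisher p by explicit enumeration of all tables with the
# observed margins, probabilities from binomial coefficients
oracle_fisher <- function(a, b, c, d) {
  n1 <- a + b; n2 <- a + c; S <- a + b + c + d
  lo <- max(0, n1 + n2 - S); hi <- min(n1, n2)
  ks <- lo:hi
  probs <- choose(n1, ks) * choose(S - n1, n2 - ks) / choose(S, n2)
  pobs <- probs[a - lo + 1]
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# undirected topology metrics from a symmetric logical adjacency matrix,
# via all-pairs BFS and explicit neighborhood triangle counting
oracle_topology <- function(adj) {
  N <- nrow(adj)
  deg <- rowSums(adj)
  dists <- numeric(0)
  for (i in seq_len(N)) {
    d <- rep(Inf, N); d[i] <- 0
    frontier <- i
    step <- 0
    while (length(frontier)) {
      reach <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & is.infinite(d))
      step <- step + 1
      d[reach] <- step
      frontier <- reach
    }
    dists <- c(dists, d[-i][is.finite(d[-i])])
  }
  loc <- vapply(seq_len(N), function(i) {
    nb <- which(adj[i, ])
    k <- length(nb)
    if (k < 2) return(0)
    sum(adj[nb, nb]) / (k * (k - 1))
  }, numeric(1))
  list(density = sum(adj) / (N * (N - 1)),
       avg_neighbors = mean(deg),
       cpl = mean(dists),
       clustering = mean(loc),
       centralization = sum(max(deg) - deg) / ((N - 1) * (N - 2)),
       heterogeneity = sqrt(mean((deg - mean(deg))^2)) / mean(deg))
}

# confidence-1 rules by scanning every ordered pair and every sample
oracle_rules <- function(M, min_support = 1) {
  out <- list()
  for (i in seq_len(nrow(M))) for (j in seq_len(nrow(M))) {
    if (i == j) next
    si <- which(M[i, ] == 1)
    if (length(si) >= min_support && all(M[j, si] == 1))
      out[[length(out) + 1]] <- c(rownames(M)[i], rownames(M)[j])
  }
  if (!length(out))
    return(data.frame(origin = character(), target = character()))
  df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
  names(df) <- c("origin", "target")
  df[order(df$origin, df$target), , drop = FALSE]
}

# small random pa_matrix fixture
random_pa <- function(n_frag, n_samp, fill = 0.4, seed = 1) {
  set.seed(seed)
  M <- matrix(rbinom(n_frag * n_samp, 1, fill), n_frag,
              dimnames = list(sprintf("F%03d", seq_len(n_frag)),
                              sprintf("S%03d", seq_len(n_samp))))
  as_pa_matrix(M)
}

# random igraph with n nodes, m edges plus its adjacency matrix
random_graph_fixture <- function(n, m, seed) {
  g <- er_random_graph(n, m, seed = seed)
  igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
  adj <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
  list(g = g, adj = adj)
}

pair_key <- function(x, y) paste(pmin(x, y), pmax(x, y))
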
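#' Fisher exact tests on all fragment pairs
#'
#' Tests every unordered pair of fragments for non-random co-occurrence.
#' Each pair is summarised by its 2x2 contingency table over samples (both
#' present / only one / neither), tested with the two-sided Fisher exact
#' test, and adjusted for multiple testing with the Benjamini-Hochberg
#' procedure across all n(n-1)/2 pairs. A pair is significant when its
#' adjusted p-value falls below `alpha`.
#'
#' @param m a [pa_matrix][as_pa_matrix] with at least two fragments.
#' @param alpha significance threshold applied to BH-adjusted p-values
#'   (default 0.05).
#' @return a data frame with one row per unordered pair: `fragment_1`,
#'   `fragment_2`, contingency cells `a`, `b`, `c`, `d`, `p_raw`, `p_adj`,
#'   `significant`, and placeholders `sign` (`"unclassified"`) and
#'   `expected_cooccurrence` (NA) to be filled by [classify_sign()].
#' @seealso [cooccurrence()] for the full analysis including sign
#'   classification and summary.
#' @export
all_pairs_test <- function(m, alpha = 0.05) {
  stopifnot(inherits(m, "pa_matrix"))
  if (nrow(m) < 2) stop("need at least two fragments", call. = FALSE)
  M <- unclass(m)
  S <- ncol(M)
  occ <- rowSums(M)
  O <- tcrossprod(M)
  iu <- which(upper.tri(O), arr.ind = TRUE)
  i <- iu[, 1]; j <- iu[, 2]
  a <- O[iu]
  nA <- occ[i]; nB <- occ[j]
  p <- fisher_p_vec(a, nA, nB, S)
  padj <- bh_adjust(p)
  data.frame(
    fragment_1 = rownames(M)[i],
    fragment_2 = rownames(M)[j],
    a = a, b = nA - a, c = nB - a, d = S - nA - nB + a,
    p_raw = p, p_adj = padj,
    significant = padj < alpha,
    sign = "unclassified",
    expected_cooccurrence = NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Classify significant pairs as co-occurrence or mutual exclusion
#'
#' Compares each significant pair's observed co-occurrence count against an
#' occupancy-preserving null in which each fragment's presence pattern is
#' independently and uniformly redistributed across samples, keeping its
#' total number of occurrences. Under that null the overlap of two rows
#' with occupancies n_A and n_B over S samples is hypergeometric, so null
#' counts are drawn directly from that distribution (`n_reps` draws per
#' pair). A pair is classified positive (co-occurrence) when the fraction
#' of null draws strictly below the observed count -- ties counted half --
#' exceeds `level`, negative (mutual exclusion) when the fraction strictly
#' above exceeds `level`, and remains unclassified otherwise.
#' `expected_cooccurrence` records the null mean, which converges to
#' n_A n_B / S.
#'
#' @param m the [pa_matrix][as_pa_matrix] the tests were computed on.
#' @param results pair test results from [all_pairs_test()].
#' @param n_reps null draws per pair (default 1000).
#' @param level classification threshold on the empirical proportion
#'   (default 0.95).
#' @param seed optional RNG seed for reproducibility.
#' @return `results` with `sign` and `expected_cooccurrence` filled for
#'   significant pairs.
#' @export
classify_sign <- function(m, results, n_reps = 1000, level = 0.95, seed = NULL) {
  stopifnot(inherits(m, "pa_matrix"))
  M <- unclass(m)
  S <- ncol(M)
  occ <- rowSums(M)
  sig <- which(results$significant)
  sign <- results$sign
  expc <- results$expected_cooccurrence
  with_seed(seed, {
    for (k in sig) {
      nA <- occ[[results$fragment_1[k]]]
      nB <- occ[[results$fragment_2[k]]]
      null_a <- stats::rhyper(n_reps, nB, S - nB, nA)
      aobs <- results$a[k]
      ties <- sum(null_a == aobs)
      p_below <- (sum(null_a < aobs) + 0.5 * ties) / n_reps
      p_above <- (sum(null_a > aobs) + 0.5 * ties) / n_reps
      expc[k] <- mean(null_a)
      if (p_below > level) sign[k] <- "positive"
      else if (p_above > level) sign[k] <- "negative"
    }
  })
  results$sign <- sign
  results$expected_cooccurrence <- expc
  results
}

#' Co-occurrence analysis of a presence-absence matrix
#'
#' The main fitting function for the co-occurrence stage: runs the
#' all-pairs Fisher exact test with BH correction ([all_pairs_test()]),
#' classifies significant pairs into positive (co-occurrence) and negative
#' (mutual exclusion) against the occupancy-preserving null
#' ([classify_sign()]), optionally estimates an empirical false discovery
#' rate from fixed-margin matrix randomizations ([estimate_fdr()]), and
#' tabulates a summary with a domain breakdown when an annotation is
#' supplied.
#'
#' @param m a [pa_matrix][as_pa_matrix].
#' @param annotation optional [fragment_annotation][as_fragment_annotation]
#'   for bacterial/archaeal breakdowns.
#' @param alpha significance threshold on BH-adjusted p-values.
#' @param sign_reps,sign_level null draws and threshold for sign
#'   classification (defaults 1000 and 0.95).
#' @param fdr_reps fixed-margin randomizations for the empirical FDR; 0
#'   (default) skips this comparatively expensive step.
#' @param seed optional master seed; stage seeds are derived from it by
#'   fixed offsets, so a given seed reproduces the full analysis.
#' @return an object of class `"cooccur_fit"` with components `results`
#'   (the per-pair table), `summary` (counts mirroring a
#'   correlated-fragments report: potential pairs, correlated pairs,
#'   positive/negative, domain-pair breakdown, empirical FDR), `fdr`
#'   (detail from [estimate_fdr()], or NULL), `alpha`, `n_fragments`,
#'   `n_samples`.
#' @examples
#' sim <- synthetic_community(synthetic_config(
#'   n_fragments = 40, n_samples = 24,
#'   sample_groups = rep(c("C1", "C2"), each = 12),
#'   module_specs = list(list(size = 8, groups = "C1"),
#'                       list(size = 8, groups = "C2")),
#'   seed = 1))
#' fit <- cooccurrence(sim$matrix, sim$annotation, seed = 1)
#' fit
#' @export
cooccurrence <- function(m, annotation = NULL, alpha = 0.05,
                         sign_reps = 1000, sign_level = 0.95,
                         fdr_reps = 0, seed = NULL) {
  results <- all_pairs_test(m, alpha)
  results <- classify_sign(m, results, n_reps = sign_reps, level = sign_level,
                           seed = seed_offset(seed, 1))
  fdr <- NULL
  if (fdr_reps > 0)
    fdr <- estimate_fdr(m, n_reps = fdr_reps, alpha = alpha,
                        seed = seed_offset(seed, 2))
  out <- list(results = results,
              summary = cooccurrence_summary(results, annotation, nrow(m), fdr),
              fdr = fdr, alpha = alpha,
              n_fragments = nrow(m), n_samples = ncol(m),
              call = match.call())
  class(out) <- "cooccur_fit"
  out
}

#' Summary counts for a set of pair test results
#'
#' Tabulates total fragments, potential pairs, correlated (significant)
#' pairs, their positive/negative split, and -- when an annotation is given
#' -- the bacterial/archaeal/mixed pair breakdown with per-class
#' positive/negative counts, plus the empirical FDR when available.
#'
#' @param results pair table from [all_pairs_test()]/[classify_sign()].
#' @param annotation optional [fragment_annotation][as_fragment_annotation].
#' @param n_fragments total number of fragments tested (defaults to the
#'   number of distinct fragments in `results`).
#' @param fdr optional result of [estimate_fdr()].
#' @return a list of class `"cooccurrence_summary"`.
#' @export
cooccurrence_summary <- function(results, annotation = NULL,
                                 n_fragments = NULL, fdr = NULL) {
  frags <- unique(c(results$fragment_1, results$fragment_2))
  if (is.null(n_fragments)) n_fragments <- length(frags)
  sig <- results[results$significant, , drop = FALSE]
  out <- list(
    n_fragments = n_fragments,
    n_potential_pairs = n_fragments * (n_fragments - 1) / 2,
    n_correlated = nrow(sig),
    n_positive = sum(sig$sign == "positive"),
    n_negative = sum(sig$sign == "negative"),
    n_unclassified = sum(sig$sign == "unclassified"),
    randomized_mean_correlated = if (!is.null(fdr)) fdr$mean_significant_on_null else NA_real_,
    estimated_fdr = if (!is.null(fdr)) fdr$estimated_fdr else NA_real_
  )
  if (!is.null(annotation)) {
    d1 <- fragment_domains(sig$fragment_1, annotation)
    d2 <- fragment_domains(sig$fragment_2, annotation)
    cls <- ifelse(d1 == d2,
                  ifelse(d1 == "bacterial", "bacterial", "archaeal"),
                  "mixed")
    all_dom <- fragment_domains(frags, annotation)
    out$n_bacterial_fragments <- sum(all_dom == "bacterial")
    out$n_archaeal_fragments <- sum(all_dom == "archaeal")
    for (k in c("bacterial", "archaeal", "mixed")) {
      out[[paste0("n_", k, "_pairs")]] <- sum(cls == k)
      out[[paste0("n_", k, "_positive")]] <- sum(cls == k & sig$sign == "positive")
      out[[paste0("n_", k, "_negative")]] <- sum(cls == k & sig$sign == "negative")
    }
  }
  class(out) <- "cooccurrence_summary"
  out
}

#' @export
print.cooccurrence_summary <- function(x, ...) {
  cat("Fragments total:      ", x$n_fragments,
      if (!is.null(x$n_bacterial_fragments))
        sprintf(" (%d bacterial / %d archaeal)",
                x$n_bacterial_fragments, x$n_archaeal_fragments), "\n", sep = "")
  cat("Potential pairs:      ", format(x$n_potential_pairs, big.mark = ","), "\n", sep = "")
  cat("Correlated pairs:     ", x$n_correlated, "\n", sep = "")
  cat("  positive:           ", x$n_positive, "\n", sep = "")
  cat("  negative:           ", x$n_negative, "\n", sep = "")
  cat("  unclassified:       ", x$n_unclassified, "\n", sep = "")
  if (!is.na(x$randomized_mean_correlated))
    cat("On randomized data:   ", x$randomized_mean_correlated,
        "  (estimated FDR ", signif(x$estimated_fdr, 3), ")\n", sep = "")
  if (!is.null(x$n_bacterial_pairs)) {
    cat("Bacterial pairs:      ", x$n_bacterial_pairs,
        sprintf(" (%d pos / %d neg)", x$n_bacterial_positive, x$n_bacterial_negative), "\n", sep = "")
    cat("Archaeal pairs:       ", x$n_archaeal_pairs,
        sprintf(" (%d pos / %d neg)", x$n_archaeal_positive, x$n_archaeal_negative), "\n", sep = "")
    cat("Mixed pairs:          ", x$n_mixed_pairs,
        sprintf(" (%d pos / %d neg)", x$n_mixed_positive, x$n_mixed_negative), "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.cooccur_fit <- function(x, ...) {
  cat("Co-occurrence analysis: ", x$n_fragments, " fragments x ",
      x$n_samples, " samples, alpha = ", x$alpha, "\n\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
summary.cooccur_fit <- function(object, ...) object$summary

#' @export
coef.cooccur_fit <- function(object, ...) object$results

#' @export
plot.cooccur_fit <- function(x, annotation = NULL, ...) {
  net <- build_cooccurrence_network(x$results, annotation)
  deg <- igraph::degree(net)
  if (length(deg) == 0) {
    graphics::plot.new()
    graphics::title("Co-occurrence network (no significant pairs)")
    return(invisible(x))
  }
  tab <- table(deg)
  graphics::plot(as.integer(names(tab)), as.integer(tab), log = "y",
                 xlab = "degree", ylab = "number of nodes",
                 main = "Co-occurrence network degree distribution", ...)
  invisible(x)
}

#' Write a pair-results table to TSV
#'
#' Columns: fragment_1, fragment_2, a, b, c, d, p_raw, p_adj, significant,
#' sign, expected_cooccurrence.
#'
#' @param results pair table from [all_pairs_test()]/[classify_sign()].
#' @param path output file path.
#' @export
write_pair_results <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
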
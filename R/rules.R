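#' Mine confidence-1 association rules from a presence-absence matrix
#'
#' An association rule "A -> B" states that whenever fragment A is present
#' in a sample, fragment B is present too; its confidence is the fraction
#' of A-containing samples that also contain B. Only exceptionless rules
#' (confidence exactly 1) are retained, i.e. ordered pairs whose origin's
#' sample set is a subset of the target's sample set. The scan inspects
#' both directions of every fragment pair: with the pairwise co-occurrence
#' counts `O = M M'`, the rule A -> B holds iff `O[A, B]` equals A's
#' occupancy, so the whole scan is a single matrix product plus a
#' comparison. Such rules flag putative one-sided dependencies (e.g.
#' cross-feeding) that symmetric co-occurrence analysis cannot see.
#'
#' @param m a [pa_matrix][as_pa_matrix].
#' @param annotation optional
#'   [fragment_annotation][as_fragment_annotation]; when given, origin and
#'   target domains are attached to each rule.
#' @param min_support minimum origin occupancy for a rule to be considered
#'   (default 1; origins with zero occupancy never form rules since their
#'   confidence is undefined).
#' @return a data frame of class `"rule_set"`, sorted by (origin, target),
#'   with columns `origin`, `target`, `support_origin`, `support_both`,
#'   `confidence` (always 1), `support_target`, and `ubiquitous_target`
#'   (TRUE when the target occurs in every sample, making it a trivial
#'   superset of everything). Attribute `n_fragments` records the matrix
#'   row count.
#' @examples
#' m <- as_pa_matrix(matrix(c(1, 0, 0, 1, 1, 0), nrow = 2, byrow = TRUE,
#'                          dimnames = list(c("A", "B"), c("s1", "s2", "s3"))))
#' association_rules(m)  # exactly A -> B
#' @export
association_rules <- function(m, annotation = NULL, min_support = 1) {
  stopifnot(inherits(m, "pa_matrix"), min_support >= 1)
  M <- unclass(m)
  occ <- rowSums(M)
  O <- tcrossprod(M)
  eligible <- occ >= min_support
  # rule i -> j iff all samples of i are samples of j
  hold <- O == matrix(occ, nrow(M), nrow(M)) & eligible
  diag(hold) <- FALSE
  idx <- which(hold, arr.ind = TRUE)
  rules <- data.frame(
    origin = rownames(M)[idx[, 1]],
    target = rownames(M)[idx[, 2]],
    support_origin = occ[idx[, 1]],
    support_both = O[idx],
    confidence = rep(1, nrow(idx)),
    support_target = occ[idx[, 2]],
    ubiquitous_target = occ[idx[, 2]] == ncol(M),
    stringsAsFactors = FALSE
  )
  rules <- rules[order(rules$origin, rules$target), , drop = FALSE]
  rownames(rules) <- NULL
  if (!is.null(annotation)) {
    rules$origin_domain <- fragment_domains(rules$origin, annotation)
    rules$target_domain <- fragment_domains(rules$target, annotation)
  }
  attr(rules, "n_fragments") <- nrow(M)
  class(rules) <- c("rule_set", "data.frame")
  rules
}

#' @export
print.rule_set <- function(x, ...) {
  cat("Association rules (confidence 1): ", nrow(x), " rules over ",
      length(unique(c(x$origin, x$target))), " fragments\n", sep = "")
  if (nrow(x) > 0) {
    print.data.frame(utils::head(as.data.frame(x), 10))
    if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more\n")
  }
  invisible(x)
}

#' Domain breakdown of an association rule set
#'
#' Counts rules by the domain of their origin and target
#' (bacterium->bacterium, bacterium->archaeum, archaeum->archaeum,
#' archaeum->bacterium) and, when pair test results are supplied, how many
#' rules connect a fragment pair that is also significantly correlated.
#'
#' @param rules a [rule_set][association_rules].
#' @param annotation a [fragment_annotation][as_fragment_annotation]
#'   covering every fragment in `rules` (may be omitted if the rules
#'   already carry domains).
#' @param pair_results optional pair table from [all_pairs_test()].
#' @return a list of class `"rule_breakdown"` with the four type counts,
#'   `total`, and `n_also_correlated`/`fraction_also_correlated` (NA
#'   without `pair_results`).
#' @export
rule_type_breakdown <- function(rules, annotation = NULL, pair_results = NULL) {
  if (!is.null(annotation)) {
    od <- fragment_domains(rules$origin, annotation)
    td <- fragment_domains(rules$target, annotation)
  } else {
    if (is.null(rules$origin_domain))
      stop("rules carry no domains; supply an annotation", call. = FALSE)
    od <- rules$origin_domain
    td <- rules$target_domain
  }
  cnt <- function(o, t) sum(od == o & td == t)
  out <- list(
    bacterium_to_bacterium = cnt("bacterial", "bacterial"),
    bacterium_to_archaeum = cnt("bacterial", "archaeal"),
    archaeum_to_archaeum = cnt("archaeal", "archaeal"),
    archaeum_to_bacterium = cnt("archaeal", "bacterial"),
    total = nrow(rules),
    n_also_correlated = NA_integer_,
    fraction_also_correlated = NA_real_
  )
  if (!is.null(pair_results)) {
    ov <- rule_cooccurrence_intersection(rules, pair_results)
    out$n_also_correlated <- ov$n_intersect
    out$fraction_also_correlated <- ov$fraction
  }
  class(out) <- "rule_breakdown"
  out
}

#' @export
print.rule_breakdown <- function(x, ...) {
  pc <- function(n) if (x$total > 0) sprintf(" (%.1f%%)", 100 * n / x$total) else ""
  cat("Association rules:      ", x$total, "\n", sep = "")
  if (!is.na(x$n_also_correlated))
    cat("  also sign. correlated:", x$n_also_correlated,
        sprintf(" (%.1f%%)", 100 * x$fraction_also_correlated), "\n")
  cat("Bacterium->Bacterium:   ", x$bacterium_to_bacterium, pc(x$bacterium_to_bacterium), "\n", sep = "")
  cat("Bacterium->Archaeum:    ", x$bacterium_to_archaeum, pc(x$bacterium_to_archaeum), "\n", sep = "")
  cat("Archaeum->Archaeum:     ", x$archaeum_to_archaeum, pc(x$archaeum_to_archaeum), "\n", sep = "")
  cat("Archaeum->Bacterium:    ", x$archaeum_to_bacterium, pc(x$archaeum_to_bacterium), "\n", sep = "")
  invisible(x)
}

#' Overlap between association rules and significant co-occurrence pairs
#'
#' Counts rules whose unordered fragment pair is also a significant
#' co-occurrence pair. Rules add information precisely to the extent this
#' overlap is small.
#'
#' @param rules a [rule_set][association_rules].
#' @param pair_results pair table from [all_pairs_test()], or a
#'   [cooccur_fit][cooccurrence].
#' @return list with `n_rules`, `n_intersect`, `fraction`, and the
#'   overlapping subset of `rules`.
#' @export
rule_cooccurrence_intersection <- function(rules, pair_results) {
  if (inherits(pair_results, "cooccur_fit")) pair_results <- pair_results$results
  sig <- pair_results[pair_results$significant, , drop = FALSE]
  key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r")
  hit <- key(rules$origin, rules$target) %in% key(sig$fragment_1, sig$fragment_2)
  list(n_rules = nrow(rules),
       n_intersect = sum(hit),
       fraction = if (nrow(rules) > 0) sum(hit) / nrow(rules) else 0,
       intersecting_rules = rules[hit, , drop = FALSE])
}

#' Write a rule set to TSV
#'
#' Columns: origin, target, support_origin, support_both, confidence,
#' support_target, ubiquitous_target, plus domains when present.
#'
#' @param rules a [rule_set][association_rules].
#' @param path output file path.
#' @export
write_rules <- function(rules, path) {
  utils::write.table(as.data.frame(rules), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
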
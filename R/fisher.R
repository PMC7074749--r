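#' Two-sided Fisher exact test p-value for a 2x2 table
#'
#' Computes the probability of observing the given co-occurrence table, or
#' a more extreme one, by chance under fixed margins. The two-sided p-value
#' follows the standard convention: the sum of hypergeometric probabilities
#' of all tables sharing the observed margins whose probability does not
#' exceed that of the observed table (with a `1 + 1e-7` relative tolerance
#' guarding against floating-point ties, as in [stats::fisher.test()]).
#' Tables with a zero row or column margin admit a single configuration and
#' get p = 1.
#'
#' @param tab a 2x2 table as a length-4 vector `c(a, b, c, d)` (both
#'   present, only first, only second, neither) or a 2x2 matrix in the same
#'   reading order.
#' @return a p-value in \[0, 1\].
#' @examples
#' fisher_two_sided(c(3, 1, 1, 3))  # 34/70
#' @export
fisher_two_sided <- function(tab) {
  tab <- as.vector(tab)
  if (length(tab) != 4 || any(tab < 0) || any(tab != round(tab)))
    stop("expected a 2x2 table of non-negative counts", call. = FALSE)
  a <- tab[1]; b <- tab[2]; cc <- tab[3]; d <- tab[4]
  n1 <- a + b          # occupancy of first fragment
  n2 <- a + cc         # occupancy of second fragment
  S <- a + b + cc + d  # number of samples
  pt <- fisher_p_table(n1, n2, S)
  pt$p[a - pt$lo + 1L]
}

# p-values for every feasible overlap a given margins (n1, n2) out of S;
# memoised because all-pairs scans revisit the same margin pairs constantly
# (and fixed-margin null replicates conserve row sums, so the cache is
# reused wholesale across replicates).
.fisher_cache <- new.env(parent = emptyenv())

fisher_p_table <- function(n1, n2, S) {
  key <- paste(min(n1, n2), max(n1, n2), S)
  hit <- .fisher_cache[[key]]
  if (!is.null(hit)) return(hit)
  lo <- max(0L, n1 + n2 - S)
  hi <- min(n1, n2)
  k <- lo:hi
  dens <- stats::dhyper(k, n2, S - n2, n1)
  p <- vapply(seq_along(k),
              function(i) sum(dens[dens <= dens[i] * (1 + 1e-7)]),
              numeric(1))
  out <- list(lo = lo, p = pmin(p, 1))
  .fisher_cache[[key]] <- out
  out
}

# vectorised two-sided Fisher p over pairs with overlap a and occupancies
# nA, nB out of S samples
fisher_p_vec <- function(a, nA, nB, S) {
  key <- paste(pmin(nA, nB), pmax(nA, nB))
  p <- numeric(length(a))
  for (grp in split(seq_along(a), key)) {
    pt <- fisher_p_table(nA[grp[1]], nB[grp[1]], S)
    p[grp] <- pt$p[a[grp] - pt$lo + 1L]
  }
  p
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up adjustment: order the m p-values ascending, multiply
#' the i-th by m/i, enforce monotonicity from the largest rank down, cap at
#' 1, and return values in the input order. A thin validating wrapper
#' around [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}
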
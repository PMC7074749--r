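#' Presence-absence matrices
#'
#' A presence-absence matrix records, for every fragment (row) and every
#' sample (column), whether the fragment was detected (1) or not (0).
#' Fragments are operational taxonomic units -- e.g. terminal restriction
#' fragments from a community fingerprint, or OTUs/ASVs from amplicon
#' sequencing. It is the single substrate of every analysis stage in this
#' package: co-occurrence testing, rule mining and the null models all
#' operate on it directly.
#'
#' `as_pa_matrix()` validates and coerces a numeric matrix: any strictly
#' positive cell becomes 1 (so abundance tables are usable as-is), zero
#' stays 0. Row names are fragment ids, column names sample ids; both must
#' be unique and non-empty. Orientation is fixed as rows = fragments,
#' columns = samples, so that row sums are per-fragment occupancy.
#'
#' @param x a numeric matrix with row names (fragment ids) and column names
#'   (sample ids); cells must be non-negative.
#' @return an integer 0/1 matrix of class `"pa_matrix"`.
#' @examples
#' m <- matrix(c(1, 0, 3, 0, 1, 1), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("F1", "F2"), c("s1", "s2", "s3")))
#' pa <- as_pa_matrix(m)
#' occupancy(pa)
#' @seealso [read_pa_matrix()], [contingency_table()]
#' @export
as_pa_matrix <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (!is.numeric(x)) {
    bad <- which(is.na(suppressWarnings(as.numeric(x))) & !is.na(x))
    stop("non-numeric cell(s) in presence-absence matrix, e.g. at position ",
         if (length(bad)) bad[1] else "?", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("presence-absence matrix needs fragment row names and sample column names",
         call. = FALSE)
  dup_f <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_f))
    stop("duplicated fragment id(s): ", paste(dup_f, collapse = ", "), call. = FALSE)
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s))
    stop("duplicated sample id(s): ", paste(dup_s, collapse = ", "), call. = FALSE)
  if (anyNA(x))
    stop("missing values are not allowed in a presence-absence matrix", call. = FALSE)
  if (any(x < 0)) {
    idx <- which(x < 0, arr.ind = TRUE)[1, ]
    stop("negative cell at fragment '", rownames(x)[idx[1]], "', sample '",
         colnames(x)[idx[2]], "'", call. = FALSE)
  }
  out <- matrix(as.integer(x > 0), nrow = nrow(x), dimnames = dimnames(x))
  class(out) <- c("pa_matrix", "matrix", "array")
  out
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat("Presence-absence matrix: ", nrow(x), " fragments x ", ncol(x),
      " samples (fill ", round(mean(x), 3), ")\n", sep = "")
  invisible(x)
}

#' Per-fragment occupancy and per-sample richness
#'
#' Occupancy is the number of samples in which a fragment was detected
#' (row sum); richness is the number of fragments detected in a sample
#' (column sum).
#'
#' @param m a [pa_matrix][as_pa_matrix].
#' @return named integer vector.
#' @export
occupancy <- function(m) {
  stopifnot(inherits(m, "pa_matrix"))
  rowSums(unclass(m))
}

#' @rdname occupancy
#' @export
richness <- function(m) {
  stopifnot(inherits(m, "pa_matrix"))
  colSums(unclass(m))
}

#' Read / write a presence-absence matrix
#'
#' The on-disk format is a delimited table whose header row holds the
#' sample ids and whose first column holds the fragment ids; cells are
#' numbers, with any strictly positive value read as presence.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"csv"`.
#' @return `read_pa_matrix()` returns a [pa_matrix][as_pa_matrix];
#'   `write_pa_matrix()` returns `path` invisibly. Writing then reading
#'   reproduces the matrix exactly (ids, order, values).
#' @export
read_pa_matrix <- function(path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", stringsAsFactors = FALSE)
  frag <- df[[1]]
  cells <- df[, -1, drop = FALSE]
  num <- suppressWarnings(vapply(cells, as.numeric, numeric(nrow(cells))))
  if (nrow(cells) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, colnames(cells)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("cannot parse cell at fragment '", frag[bad[1, 1]], "', sample '",
         colnames(cells)[bad[1, 2]], "' in ", path, call. = FALSE)
  rownames(num) <- frag
  as_pa_matrix(num)
}

#' @rdname read_pa_matrix
#' @param m a [pa_matrix][as_pa_matrix] to write.
#' @export
write_pa_matrix <- function(m, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(m, "pa_matrix"))
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(fragment_id = rownames(m), unclass(m), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' 2x2 contingency table for a fragment pair
#'
#' Counts, over all samples: `a` both fragments present, `b` only the
#' first, `c` only the second, `d` neither. `a + b + c + d` equals the
#' number of samples. Swapping the two fragments exchanges `b` and `c`.
#'
#' @param m a [pa_matrix][as_pa_matrix].
#' @param i,j distinct fragment ids present in `m`.
#' @return named integer vector `c(a, b, c, d)`.
#' @export
contingency_table <- function(m, i, j) {
  stopifnot(inherits(m, "pa_matrix"))
  if (identical(i, j)) stop("fragment pair must be two distinct fragments", call. = FALSE)
  for (id in c(i, j)) if (!id %in% rownames(m))
    stop("unknown fragment id: ", id, call. = FALSE)
  x <- m[i, ]
  y <- m[j, ]
  a <- sum(x == 1 & y == 1)
  b <- sum(x == 1 & y == 0)
  cc <- sum(x == 0 & y == 1)
  d <- sum(x == 0 & y == 0)
  c(a = a, b = b, c = cc, d = d)
}
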
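#' Fragment annotations and sample metadata
#'
#' Fragment annotations carry the domain label (bacterial or archaeal) used
#' for all domain breakdowns, the restriction enzyme when the data are
#' T-RFLP fingerprints, and optional species candidates. Ambiguous species
#' assignments hold several names separated by a slash. Sample metadata
#' place each sample along the sampling transect: the push core it came
#' from (e.g. C1..C8 along a groundwater flow path), its depth section, the
#' spatial scale (bulk soil vs single soil particle), and, for particle
#' samples only, the particle index.
#'
#' @param df a data frame with columns `fragment_id`, `domain`
#'   (`"bacterial"`/`"archaeal"`), and optionally `enzyme`, `species`.
#' @return validated data frame of class `"fragment_annotation"`.
#' @export
as_fragment_annotation <- function(df) {
  stopifnot(is.data.frame(df))
  need <- c("fragment_id", "domain")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation lacks column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  df$fragment_id <- as.character(df$fragment_id)
  dup <- unique(df$fragment_id[duplicated(df$fragment_id)])
  if (length(dup)) stop("duplicated fragment id(s) in annotation: ",
                        paste(dup, collapse = ", "), call. = FALSE)
  df$domain <- as.character(df$domain)
  bad <- setdiff(unique(df$domain), c("bacterial", "archaeal"))
  if (length(bad)) stop("domain must be 'bacterial' or 'archaeal', got: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (!"species" %in% names(df)) df$species <- ""
  if (!"enzyme" %in% names(df)) df$enzyme <- NA_character_
  class(df) <- c("fragment_annotation", "data.frame")
  df
}

#' @rdname as_fragment_annotation
#' @param path file path of a TSV with the annotation columns.
#' @export
read_fragment_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  as_fragment_annotation(df)
}

#' @rdname as_fragment_annotation
#' @param ann a `fragment_annotation`.
#' @export
write_fragment_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Look up domain labels for a set of fragments
#'
#' @param fragments character vector of fragment ids.
#' @param ann a [fragment_annotation][as_fragment_annotation].
#' @return character vector of `"bacterial"`/`"archaeal"`, same order as
#'   `fragments`. Errors listing the offending fragments if any lack an
#'   annotation.
#' @export
fragment_domains <- function(fragments, ann) {
  idx <- match(fragments, ann$fragment_id)
  if (anyNA(idx))
    stop("fragments without domain annotation: ",
         paste(fragments[is.na(idx)], collapse = ", "), call. = FALSE)
  ann$domain[idx]
}

#' @rdname as_fragment_annotation
#' @param meta a data frame with columns `sample_id`, `core`,
#'   `depth_section`, `scale` (`"bulk"`/`"particle"`), `particle_index`
#'   (integer, present iff scale is `"particle"`).
#' @export
as_sample_metadata <- function(meta) {
  stopifnot(is.data.frame(meta))
  need <- c("sample_id", "core", "scale")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata lacks column(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  meta$sample_id <- as.character(meta$sample_id)
  dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
  if (length(dup)) stop("duplicated sample id(s) in metadata: ",
                        paste(dup, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(as.character(meta$scale)), c("bulk", "particle"))
  if (length(bad)) stop("scale must be 'bulk' or 'particle', got: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  if (!"depth_section" %in% names(meta)) meta$depth_section <- NA_integer_
  if (!"particle_index" %in% names(meta)) meta$particle_index <- NA_integer_
  has_idx <- !is.na(meta$particle_index)
  if (any(has_idx != (meta$scale == "particle")))
    stop("particle_index must be present exactly for particle-scale samples",
         call. = FALSE)
  class(meta) <- c("sample_metadata", "data.frame")
  meta
}

#' @rdname as_fragment_annotation
#' @export
read_sample_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"", comment.char = "")
  as_sample_metadata(df)
}

#' @rdname as_fragment_annotation
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(as.data.frame(meta), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
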
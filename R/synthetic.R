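#' Configure a synthetic community with planted structure
#'
#' Describes a presence-absence matrix generator that emulates spatially
#' structured fingerprinting data: samples fall into labelled groups
#' (push cores along a transect), blocks of fragments form location-bound
#' modules (present with probability `p_in` in their groups' samples and
#' `p_out` elsewhere), selected ordered fragment pairs are planted as
#' subset dependencies (the origin's sample set is constructed inside the
#' target's, the signature of a confidence-1 association rule), selected
#' unordered pairs are planted with disjoint sample sets (mutual
#' exclusions), and all remaining fragments are unstructured background
#' with a per-domain occupancy probability. Independent cell-wise noise is
#' applied after planting, and the ground truth is recomputed on the final
#' matrix, because single flips destroy confidence-1 rules.
#'
#' @param n_fragments,n_samples matrix dimensions.
#' @param sample_groups character vector of length `n_samples`: group
#'   (core) label per sample.
#' @param fraction_archaeal probability that an unconstrained fragment is
#'   archaeal.
#' @param module_specs list of module blocks, each a list with `size`,
#'   `groups` (labels from `sample_groups`), and optionally `p_in`
#'   (default 0.9), `p_out` (default 0.05), `domain` (forces all members'
#'   domain).
#' @param rule_specs list of planted dependencies, each a length-2 integer
#'   vector `c(origin, target)` of fragment indices; an origin may appear
#'   in at most one rule. Targets get a uniform random sample set of size
#'   `round(rule_target_occupancy * n_samples)` (unless already planted);
#'   each origin gets a random subset of its target's set of relative size
#'   `rule_origin_relative` (at least 1 sample).
#' @param exclusion_specs list of length-2 integer vectors: fragment pairs
#'   planted with disjoint sample sets of size about
#'   `exclusion_occupancy * n_samples` each.
#' @param background_occupancy presence probability for unstructured
#'   fragments: a scalar, or a named vector `c(bacterial = , archaeal = )`.
#' @param rule_target_occupancy,rule_origin_relative,exclusion_occupancy
#'   planting proportions, see above.
#' @param origin_domain,target_domain optional domain forced on rule
#'   origins / targets (e.g. archaeal origins and bacterial targets).
#' @param noise_rate probability of flipping any cell after planting.
#' @param scale `"bulk"` or `"particle"`; recorded in the sample metadata.
#' @param depth_section,particle_index optional per-sample metadata
#'   vectors.
#' @param seed RNG seed; identical seed and config give identical output.
#' @return a validated list of class `"synthetic_config"`.
#' @seealso [synthetic_community()], [bulk_like_config()],
#'   [particle_like_config()]
#' @export
synthetic_config <- function(n_fragments, n_samples,
                             sample_groups = rep("C1", n_samples),
                             fraction_archaeal = 0.25,
                             module_specs = list(),
                             rule_specs = list(),
                             exclusion_specs = list(),
                             background_occupancy = 0.15,
                             rule_target_occupancy = 0.5,
                             rule_origin_relative = 0.35,
                             exclusion_occupancy = 1 / 3,
                             origin_domain = NULL,
                             target_domain = NULL,
                             noise_rate = 0.02,
                             scale = c("bulk", "particle"),
                             depth_section = NULL,
                             particle_index = NULL,
                             seed = 1) {
  scale <- match.arg(scale)
  stopifnot(n_fragments >= 2, n_samples >= 2,
            length(sample_groups) == n_samples,
            noise_rate >= 0, noise_rate <= 1,
            fraction_archaeal >= 0, fraction_archaeal <= 1,
            all(background_occupancy >= 0 & background_occupancy <= 1),
            rule_target_occupancy > 0, rule_target_occupancy <= 1,
            rule_origin_relative > 0, rule_origin_relative <= 1,
            exclusion_occupancy > 0, exclusion_occupancy <= 0.5)
  module_specs <- lapply(module_specs, function(sp) {
    sp$p_in <- if (is.null(sp$p_in)) 0.9 else sp$p_in
    sp$p_out <- if (is.null(sp$p_out)) 0.05 else sp$p_out
    if (is.null(sp$size) || is.null(sp$groups))
      stop("each module spec needs 'size' and 'groups'", call. = FALSE)
    if (!all(sp$groups %in% sample_groups))
      stop("module spec references unknown sample group(s): ",
           paste(setdiff(sp$groups, sample_groups), collapse = ", "), call. = FALSE)
    if (sp$p_in <= sp$p_out)
      stop("module spec needs p_in > p_out", call. = FALSE)
    sp
  })
  mod_n <- sum(vapply(module_specs, function(sp) sp$size, numeric(1)))
  rule_idx <- unlist(rule_specs)
  excl_idx <- unlist(exclusion_specs)
  structured <- c(rule_idx, excl_idx)
  if (length(structured) && (any(structured < 1) || any(structured > n_fragments)))
    stop("rule/exclusion fragment index out of range", call. = FALSE)
  if (length(structured) && any(structured <= mod_n))
    stop("rule/exclusion fragments may not lie inside module blocks", call. = FALSE)
  if (anyDuplicated(excl_idx) || length(intersect(rule_idx, excl_idx)))
    stop("structured fragment indices overlap", call. = FALSE)
  origins <- vapply(rule_specs, `[`, numeric(1), 1)
  targets <- vapply(rule_specs, `[`, numeric(1), 2)
  if (anyDuplicated(origins) || length(intersect(origins, targets)))
    stop("each fragment may be a rule origin at most once, and never both origin and target",
         call. = FALSE)
  if (mod_n > n_fragments)
    stop("module block sizes exceed the number of fragments", call. = FALSE)
  cfg <- list(n_fragments = n_fragments, n_samples = n_samples,
              sample_groups = as.character(sample_groups),
              fraction_archaeal = fraction_archaeal,
              module_specs = module_specs, rule_specs = rule_specs,
              exclusion_specs = exclusion_specs,
              background_occupancy = background_occupancy,
              rule_target_occupancy = rule_target_occupancy,
              rule_origin_relative = rule_origin_relative,
              exclusion_occupancy = exclusion_occupancy,
              origin_domain = origin_domain, target_domain = target_domain,
              noise_rate = noise_rate, scale = scale,
              depth_section = depth_section, particle_index = particle_index,
              seed = seed)
  class(cfg) <- "synthetic_config"
  cfg
}

# xor-flip each cell with probability rate; at rate = 1 this is the exact
# complement, so applying it twice is the identity
apply_noise <- function(M, rate) {
  if (rate == 0) return(M)
  flips <- matrix(stats::runif(length(M)) < rate, nrow(M))
  out <- abs(M - flips)
  storage.mode(out) <- "integer"
  out
}

#' Generate a synthetic community with full ground truth
#'
#' Realizes a [synthetic_config()]: plants module blocks, subset-dependency
#' pairs and exclusion pairs, fills the background, applies cell-wise
#' noise, and returns the matrix together with a fragment annotation,
#' sample metadata, and the ground truth. `surviving_rules` is recomputed
#' on the final (noisy) matrix by a direct subset check, so at
#' `noise_rate = 0` it equals the planted rules exactly.
#'
#' @param config a [synthetic_config()].
#' @return a list with components `matrix` ([pa_matrix][as_pa_matrix]),
#'   `annotation` ([fragment_annotation][as_fragment_annotation]),
#'   `metadata` ([sample_metadata][as_sample_metadata]), `truth` (list:
#'   `module_membership` named integer vector with NA for unstructured
#'   fragments, `planted_rules`, `planted_exclusions`, `surviving_rules`
#'   data frames), and `config`.
#' @export
synthetic_community <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  Fn <- cfg$n_fragments
  S <- cfg$n_samples
  with_seed(cfg$seed, {
    domain <- ifelse(stats::runif(Fn) < cfg$fraction_archaeal,
                     "archaeal", "bacterial")
    M <- matrix(0L, Fn, S)
    module_id <- rep(NA_integer_, Fn)
    nxt <- 1L
    for (b in seq_along(cfg$module_specs)) {
      sp <- cfg$module_specs[[b]]
      idx <- nxt:(nxt + sp$size - 1L)
      nxt <- nxt + sp$size
      module_id[idx] <- b
      prob <- ifelse(cfg$sample_groups %in% sp$groups, sp$p_in, sp$p_out)
      for (i in idx) M[i, ] <- stats::rbinom(S, 1L, prob)
      if (!is.null(sp$domain)) domain[idx] <- sp$domain
    }
    origins <- vapply(cfg$rule_specs, `[`, numeric(1), 1)
    targets <- vapply(cfg$rule_specs, `[`, numeric(1), 2)
    for (t in unique(targets)) {
      if (all(M[t, ] == 0L)) {
        sz <- max(1L, round(cfg$rule_target_occupancy * S))
        M[t, sample.int(S, sz)] <- 1L
      }
    }
    for (r in seq_along(cfg$rule_specs)) {
      o <- origins[r]; t <- targets[r]
      tset <- which(M[t, ] == 1L)
      if (length(tset) == 0)
        stop("infeasible config: rule target ", t, " has zero occupancy",
             call. = FALSE)
      osz <- max(1L, round(cfg$rule_origin_relative * length(tset)))
      oset <- if (length(tset) == 1L) tset else sample(tset, osz)
      M[o, ] <- 0L
      M[o, oset] <- 1L
    }
    if (length(origins)) {
      if (!is.null(cfg$origin_domain)) domain[origins] <- cfg$origin_domain
      if (!is.null(cfg$target_domain)) domain[unique(targets)] <- cfg$target_domain
    }
    ex1 <- vapply(cfg$exclusion_specs, `[`, numeric(1), 1)
    ex2 <- vapply(cfg$exclusion_specs, `[`, numeric(1), 2)
    for (e in seq_along(cfg$exclusion_specs)) {
      sz <- max(1L, round(cfg$exclusion_occupancy * S))
      sx <- sample.int(S, sz)
      rest <- setdiff(seq_len(S), sx)
      sy <- if (length(rest) == 1L) rest else sample(rest, min(sz, length(rest)))
      M[ex1[e], ] <- 0L; M[ex1[e], sx] <- 1L
      M[ex2[e], ] <- 0L; M[ex2[e], sy] <- 1L
    }
    structured <- c(which(!is.na(module_id)), origins, targets, ex1, ex2)
    background <- setdiff(seq_len(Fn), structured)
    bo <- cfg$background_occupancy
    p_bg <- if (length(bo) == 1L) rep(bo, Fn) else unname(bo[domain])
    for (i in background) M[i, ] <- stats::rbinom(S, 1L, p_bg[i])
    M <- apply_noise(M, cfg$noise_rate)

    ids <- paste0(ifelse(domain == "archaeal", "Arch_", "Bact_"), seq_len(Fn))
    rownames(M) <- ids
    colnames(M) <- sprintf("S%03d", seq_len(S))
    pa <- as_pa_matrix(M)

    planted_rules <- data.frame(origin = ids[origins], target = ids[targets],
                                stringsAsFactors = FALSE)
    planted_exclusions <- data.frame(fragment_1 = ids[ex1], fragment_2 = ids[ex2],
                                     stringsAsFactors = FALSE)
    truth <- list(
      module_membership = stats::setNames(module_id, ids),
      planted_rules = planted_rules,
      planted_exclusions = planted_exclusions,
      surviving_rules = recompute_surviving_rules(pa, planted_rules))

    ann <- as_fragment_annotation(data.frame(
      fragment_id = ids, domain = domain, enzyme = NA_character_,
      species = "", stringsAsFactors = FALSE))
    grp_seq <- stats::ave(seq_len(S), cfg$sample_groups, FUN = seq_along)
    meta <- as_sample_metadata(data.frame(
      sample_id = colnames(M),
      core = cfg$sample_groups,
      depth_section = if (is.null(cfg$depth_section)) grp_seq else cfg$depth_section,
      scale = cfg$scale,
      particle_index = if (is.null(cfg$particle_index)) {
        if (cfg$scale == "particle") grp_seq else NA_integer_
      } else cfg$particle_index,
      stringsAsFactors = FALSE))
    list(matrix = pa, annotation = ann, metadata = meta, truth = truth,
         config = cfg)
  })
}

#' Recompute which planted rules survive in a (noisy) matrix
#'
#' A planted dependency origin -> target survives iff the origin still
#' occurs in at least one sample and no sample contains the origin without
#' the target -- the exact condition under which the rule miner will emit
#' it with confidence 1.
#'
#' @param m a [pa_matrix][as_pa_matrix].
#' @param planted data frame with columns `origin`, `target` (fragment
#'   ids in `m`).
#' @return the surviving subset of `planted`.
#' @export
recompute_surviving_rules <- function(m, planted) {
  stopifnot(inherits(m, "pa_matrix"))
  if (nrow(planted) == 0) return(planted)
  keep <- vapply(seq_len(nrow(planted)), function(r) {
    o <- m[planted$origin[r], ]
    t <- m[planted$target[r], ]
    sum(o) >= 1 && !any(o == 1 & t == 0)
  }, logical(1))
  out <- planted[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Study-shaped synthetic presets
#'
#' Two ready-made [synthetic_config()]s mirroring the shape of a
#' contaminated-aquifer fingerprinting study. `bulk_like_config()`: 280
#' fragments x 72 bulk samples over five cores (C1, C2, C3, C5, C8) along
#' the flow path; five location-bound modules of 20 fragments each
#' (p_in 0.9, p_out 0.05; bacterial-dominated at the plume source and in
#' pristine conditions, archaeal under methanogenic conditions); 8 planted
#' dependency hubs with 5 origins each; 6 planted exclusion pairs; 27%
#' archaeal fragments and background occupancy 0.15.
#' `particle_like_config()`: 620 fragments x 104 single-particle samples
#' (13 core sections x 8 particles); four weaker modules; 10 bacterial
#' dependency hubs fed by 8 archaeal origins each (the keystone pattern);
#' 48% archaeal fragments with sparser archaeal background occupancy
#' (0.06 vs 0.20 for bacteria); 4 exclusion pairs. Both default to 2%
#' cell-flip noise.
#'
#' @param seed RNG seed.
#' @param noise_rate cell-flip probability (default 0.02).
#' @return a [synthetic_config()].
#' @export
bulk_like_config <- function(seed = 1, noise_rate = 0.02) {
  groups <- rep(c("C1", "C2", "C3", "C5", "C8"), times = c(15, 15, 14, 14, 14))
  mods <- Map(function(core, dom) list(size = 20, groups = core, p_in = 0.9,
                                       p_out = 0.05, domain = dom),
              c("C1", "C2", "C3", "C5", "C8"),
              c("bacterial", "bacterial", "archaeal", "archaeal", "bacterial"))
  targets <- 101:108
  origins <- 109:148
  rules <- lapply(seq_along(origins),
                  function(i) c(origins[i], targets[(i - 1) %/% 5 + 1]))
  excl <- lapply(seq_len(6), function(e) c(149 + 2 * (e - 1), 150 + 2 * (e - 1)))
  synthetic_config(
    n_fragments = 280, n_samples = 72, sample_groups = groups,
    fraction_archaeal = 0.27, module_specs = unname(mods),
    rule_specs = rules, exclusion_specs = excl,
    background_occupancy = 0.15, noise_rate = noise_rate,
    scale = "bulk", seed = seed)
}

#' @rdname bulk_like_config
#' @export
particle_like_config <- function(seed = 1, noise_rate = 0.02) {
  sections_per_core <- c(C1 = 2, C2 = 2, C3 = 3, C5 = 4, C8 = 2)
  core <- rep(rep(names(sections_per_core), times = sections_per_core), each = 8)
  section <- rep(seq_len(13), each = 8)
  particle <- rep(seq_len(8), times = 13)
  mods <- Map(function(cr, dom) list(size = 20, groups = cr, p_in = 0.85,
                                     p_out = 0.1, domain = dom),
              c("C1", "C2", "C3", "C5"),
              c("bacterial", "bacterial", "archaeal", "bacterial"))
  targets <- 81:90
  origins <- 91:170
  rules <- lapply(seq_along(origins),
                  function(i) c(origins[i], targets[(i - 1) %/% 8 + 1]))
  excl <- lapply(seq_len(4), function(e) c(171 + 2 * (e - 1), 172 + 2 * (e - 1)))
  synthetic_config(
    n_fragments = 620, n_samples = 104, sample_groups = core,
    fraction_archaeal = 0.48, module_specs = unname(mods),
    rule_specs = rules, exclusion_specs = excl,
    background_occupancy = c(bacterial = 0.20, archaeal = 0.06),
    rule_origin_relative = 0.3,
    origin_domain = "archaeal", target_domain = "bacterial",
    noise_rate = noise_rate, scale = "particle",
    depth_section = section, particle_index = particle, seed = seed)
}

#' Write a synthetic community to disk
#'
#' Writes the matrix, annotation and metadata in their TSV formats and the
#' ground truth as JSON, so a simulated data set can be fed back through
#' the file-based pipeline.
#'
#' @param sim result of [synthetic_community()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_synthetic_community <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "ground_truth.json"))
  write_pa_matrix(sim$matrix, paths["matrix"])
  write_fragment_annotation(sim$annotation, paths["annotation"])
  write_sample_metadata(sim$metadata, paths["metadata"])
  truth <- sim$truth
  truth$module_membership <- list(fragment = names(truth$module_membership),
                                  module = unname(truth$module_membership))
  jsonlite::write_json(truth, paths["truth"], dataframe = "columns",
                       na = "null", auto_unbox = FALSE)
  invisible(paths)
}
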
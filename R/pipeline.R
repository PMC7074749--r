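#' Configure the end-to-end analysis pipeline
#'
#' Bundles the inputs and tuning parameters of the full analysis chain:
#' co-occurrence testing (alpha on BH-adjusted p-values), empirical FDR
#' replicates, sign-classification replicates and level,
#' rule-mining minimum support, Erdos-Renyi baseline replicates, hub list
#' length, and the master seed from which all stage seeds are derived by
#' fixed offsets.
#'
#' @param matrix a [pa_matrix][as_pa_matrix] or path to one (TSV).
#' @param annotation optional
#'   [fragment_annotation][as_fragment_annotation] or path.
#' @param metadata optional [sample_metadata][as_sample_metadata] or path.
#' @param alpha significance threshold (default 0.05).
#' @param fdr_reps fixed-margin randomizations for the empirical FDR
#'   (default 100; 0 skips).
#' @param sign_reps,sign_level occupancy-null draws and threshold for sign
#'   classification (1000, 0.95).
#' @param min_support minimum rule origin occupancy (default 1).
#' @param er_reps Erdos-Renyi baseline draws per topology panel (default
#'   100; 0 skips).
#' @param top_k hub list length (default 25).
#' @param seed master RNG seed.
#' @param out_dir output directory for the report bundle (NULL = no files
#'   written).
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(matrix, annotation = NULL, metadata = NULL,
                            alpha = 0.05, fdr_reps = 100, sign_reps = 1000,
                            sign_level = 0.95, min_support = 1, er_reps = 100,
                            top_k = 25, seed = 1, out_dir = NULL) {
  stopifnot(alpha > 0, alpha < 1, sign_level > 0, sign_level < 1,
            sign_reps >= 1, min_support >= 1, top_k >= 1,
            fdr_reps >= 0, er_reps >= 0)
  structure(list(matrix = matrix, annotation = annotation, metadata = metadata,
                 alpha = alpha, fdr_reps = fdr_reps, sign_reps = sign_reps,
                 sign_level = sign_level, min_support = min_support,
                 er_reps = er_reps, top_k = top_k, seed = seed,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the complete chain on a presence-absence matrix: all-pairs
#' Fisher testing with BH correction and sign classification; empirical
#' FDR by fixed-margin randomization; confidence-1 rule mining;
#' co-occurrence and rule network construction; topology panels with
#' Erdos-Renyi baselines; Newman modularity on the positive edges; module
#' presence profiles along the cores (when sample metadata are given); the
#' hub-role report; rule/co-occurrence intersection; and rule
#' neighborhoods with co-occurrence overlay for the top exclusive-target
#' hubs. With `out_dir` set, all tables, networks (GraphML + edge lists)
#' and a JSON summary are written, plus a run log recording the
#' configuration and stage counts. The run is deterministic under the
#' master seed.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list of class `"fragnet_report"` with components
#'   `cooccurrence` ([cooccur_fit][cooccurrence]), `rules`, `breakdown`,
#'   `cooccurrence_network`, `rule_network`, `cooccurrence_topology`,
#'   `rule_topology`, `modules`, `profile` (or NULL), `hubs`,
#'   `intersection`, `neighborhoods`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  m <- if (is.character(cfg$matrix)) read_pa_matrix(cfg$matrix) else cfg$matrix
  ann <- if (is.character(cfg$annotation)) read_fragment_annotation(cfg$annotation)
         else cfg$annotation
  meta <- if (is.character(cfg$metadata)) read_sample_metadata(cfg$metadata)
          else cfg$metadata
  problems <- character()
  if (!inherits(m, "pa_matrix")) problems <- c(problems, "matrix is not a pa_matrix")
  else if (nrow(m) < 2) problems <- c(problems, "matrix has fewer than 2 fragments")
  if (!is.null(ann) && inherits(m, "pa_matrix")) {
    missing_ann <- setdiff(rownames(m), ann$fragment_id)
    if (length(missing_ann))
      problems <- c(problems, paste("fragments without annotation:",
                                    paste(utils::head(missing_ann, 5), collapse = ", ")))
  }
  if (!is.null(meta) && inherits(m, "pa_matrix")) {
    missing_meta <- setdiff(colnames(m), meta$sample_id)
    if (length(missing_meta))
      problems <- c(problems, paste("samples without metadata:",
                                    paste(utils::head(missing_meta, 5), collapse = ", ")))
  }
  if (length(problems))
    stop("pipeline input validation failed:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)

  log_lines <- c(sprintf("fragnet pipeline | seed %s | alpha %g | %d fragments x %d samples",
                         cfg$seed, cfg$alpha, nrow(m), ncol(m)),
                 sprintf("R %s, fragnet %s, igraph %s", getRversion(),
                         as.character(utils::packageVersion("fragnet")),
                         as.character(utils::packageVersion("igraph"))))

  fit <- cooccurrence(m, annotation = ann, alpha = cfg$alpha,
                      sign_reps = cfg$sign_reps, sign_level = cfg$sign_level,
                      fdr_reps = cfg$fdr_reps, seed = seed_offset(cfg$seed, 10))
  log_lines <- c(log_lines,
                 sprintf("cooccurrence: %d pairs tested, %d significant (%d pos / %d neg / %d uncl)",
                         nrow(fit$results), fit$summary$n_correlated,
                         fit$summary$n_positive, fit$summary$n_negative,
                         fit$summary$n_unclassified))

  rules <- association_rules(m, annotation = ann, min_support = cfg$min_support)
  breakdown <- if (!is.null(ann))
    rule_type_breakdown(rules, ann, fit$results) else NULL
  log_lines <- c(log_lines, sprintf("rules: %d confidence-1 rules mined", nrow(rules)))

  cnet <- build_cooccurrence_network(fit$results, ann)
  rnet <- build_rule_network(rules, ann)
  ctopo <- if (igraph::vcount(cnet) >= 3)
    network_topology(cnet, all_fragments_count = nrow(m), er_reps = cfg$er_reps,
                     seed = seed_offset(cfg$seed, 20)) else NULL
  rtopo <- if (igraph::vcount(rnet) >= 3)
    network_topology(rnet, all_fragments_count = nrow(m), er_reps = cfg$er_reps,
                     seed = seed_offset(cfg$seed, 21)) else NULL
  log_lines <- c(log_lines,
                 sprintf("networks: cooccurrence %d nodes / %d edges; rules %d nodes / %d edges",
                         igraph::vcount(cnet), igraph::ecount(cnet),
                         igraph::vcount(rnet), igraph::ecount(rnet)))

  modules <- tryCatch(modularity_partition(cnet), error = function(e) NULL)
  if (!is.null(modules))
    log_lines <- c(log_lines,
                   sprintf("modularity: Q = %.3f, %d modules (%d with > 3 fragments)",
                           modules$q, modules$n_modules, modules$n_modules_gt3))

  profile <- if (!is.null(meta) && !is.null(modules))
    module_core_profile(m, meta, modules) else NULL

  hubs <- if (igraph::vcount(rnet) > 0) hub_roles(rnet, k = cfg$top_k) else NULL
  intersection <- rule_cooccurrence_intersection(rules, fit$results)
  log_lines <- c(log_lines,
                 sprintf("intersection: %d of %d rules also significantly correlated (%.1f%%)",
                         intersection$n_intersect, intersection$n_rules,
                         100 * intersection$fraction))

  neighborhoods <- list()
  if (!is.null(hubs) && nrow(hubs$top_targets) > 0 && igraph::vcount(cnet) > 0) {
    for (h in utils::head(hubs$top_targets$fragment, 3))
      neighborhoods[[h]] <- hub_neighborhood(rnet, cnet, h)
  }

  report <- structure(
    list(cooccurrence = fit, rules = rules, breakdown = breakdown,
         cooccurrence_network = cnet, rule_network = rnet,
         cooccurrence_topology = ctopo, rule_topology = rtopo,
         modules = modules, profile = profile, hubs = hubs,
         intersection = intersection, neighborhoods = neighborhoods,
         config = cfg, log = log_lines),
    class = "fragnet_report")

  if (!is.null(cfg$out_dir)) write_report_bundle(report, cfg$out_dir)
  invisible(report)
}

#' @export
print.fragnet_report <- function(x, ...) {
  cat(x$log, sep = "\n")
  invisible(x)
}

# serialize every table of a pipeline report into out_dir
write_report_bundle <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_pair_results(report$cooccurrence$results, p("pair_results.tsv"))
  write_rules(report$rules, p("rules.tsv"))
  if (igraph::vcount(report$cooccurrence_network) > 0) {
    write_graphml(report$cooccurrence_network, p("cooccurrence_network.graphml"))
    write_edge_list(report$cooccurrence_network, p("cooccurrence_edges.tsv"))
  }
  if (igraph::vcount(report$rule_network) > 0) {
    write_graphml(report$rule_network, p("rule_network.graphml"))
    write_edge_list(report$rule_network, p("rule_edges.tsv"))
  }
  if (!is.null(report$modules)) {
    mm <- report$modules$membership
    utils::write.table(data.frame(fragment = names(mm), module = unname(mm)),
                       p("modules.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(report$profile))
    write_module_profile(report$profile, p("module_profile.tsv"))
  if (!is.null(report$hubs)) {
    utils::write.table(report$hubs$nodes, p("hub_roles.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(report$hubs$top_targets, p("top_targets.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(report$hubs$top_origins, p("top_origins.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  summ <- list(
    cooccurrence = unclass(report$cooccurrence$summary),
    rule_breakdown = if (!is.null(report$breakdown)) unclass(report$breakdown) else NULL,
    cooccurrence_topology = if (!is.null(report$cooccurrence_topology))
      unclass(report$cooccurrence_topology) else NULL,
    rule_topology = if (!is.null(report$rule_topology))
      unclass(report$rule_topology) else NULL,
    modularity = if (!is.null(report$modules))
      report$modules[c("q", "n_modules", "n_modules_gt3")] else NULL,
    intersection = report$intersection[c("n_rules", "n_intersect", "fraction")])
  jsonlite::write_json(summ, p("summary.json"), auto_unbox = TRUE, digits = NA,
                       na = "null")
  writeLines(report$log, p("run_log.txt"))
  invisible(out_dir)
}
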
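#' Build a pipeline configuration
#'
#' A single structured configuration drives the end-to-end analysis:
#' either file inputs (`table`, `metadata`, optional `taxonomy`) or a
#' synthetic preset, stage toggles, every stage parameter, the seed for
#' stochastic stages, and the output directory. The configuration
#' round-trips losslessly through YAML ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param table,metadata,taxonomy input file paths (ignored when
#'   `preset` is given).
#' @param preset synthetic preset name (see [synthetic_presets()]).
#' @param out_dir output directory.
#' @param stages character subset of
#'   `c("diversity", "profiles", "ordination", "clam", "network")`.
#' @param seed integer seed; mandatory because ordination (permutations)
#'   is stochastic.
#' @param rank taxonomic rank for profile aggregation (NULL = none).
#' @param top_k taxa kept in the heatmap structure.
#' @param group_factor metadata column tested by PERMANOVA.
#' @param n_perm PERMANOVA permutations.
#' @param habitat_factor metadata column for the CLAM contrast.
#' @param clam_threshold,clam_alpha,clam_coverage_limit CLAM parameters
#'   (see [clam_classify()]).
#' @param min_mean_relabund,rho_min,p_max network filter and screen
#'   parameters.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(table = NULL, metadata = NULL, taxonomy = NULL,
                            preset = NULL, out_dir = "permanet_out",
                            stages = c("diversity", "profiles", "ordination",
                                       "clam", "network"),
                            seed = 1, rank = NULL, top_k = 50,
                            group_factor = "oiled", n_perm = 999,
                            habitat_factor = "oiled",
                            clam_threshold = 2/3, clam_alpha = 0.05 / 20,
                            clam_coverage_limit = 30,
                            min_mean_relabund = 1e-4,
                            rho_min = 0.6, p_max = 0.01) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(preset) && is.null(table))
    stop("either input files or a synthetic preset is required", call. = FALSE)
  if (is.null(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(clam_threshold > 0.5, clam_threshold < 1,
            clam_alpha > 0, clam_alpha < 0.5,
            min_mean_relabund >= 0, rho_min >= -1, rho_min <= 1,
            p_max > 0, p_max <= 1, n_perm >= 1)
  cfg <- list(table = table, metadata = metadata, taxonomy = taxonomy,
              preset = preset, out_dir = out_dir, stages = stages,
              seed = as.integer(seed), rank = rank, top_k = top_k,
              group_factor = group_factor, n_perm = n_perm,
              habitat_factor = habitat_factor,
              clam_threshold = clam_threshold, clam_alpha = clam_alpha,
              clam_coverage_limit = clam_coverage_limit,
              min_mean_relabund = min_mean_relabund,
              rho_min = rho_min, p_max = p_max)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns the validated config.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Cross-validate the pipeline inputs
#'
#' Checks sample-ID agreement between table and metadata, factor levels,
#' and taxonomy coverage. Issues are returned as a data.frame with a
#' `severity` column: `"error"` entries abort [run_pipeline()]; extra
#' metadata rows or taxa missing from the taxonomy are warnings only.
#'
#' @param table an [abundance_table()].
#' @param metadata a [sample_metadata()].
#' @param taxonomy optional [taxonomy_map()].
#' @return data.frame with `severity` and `message` (zero rows when fully
#'   consistent).
#' @export
validate_inputs <- function(table, metadata, taxonomy = NULL) {
  issues <- list()
  add <- function(sev, msg)
    issues[[length(issues) + 1]] <<- data.frame(severity = sev, message = msg,
                                                stringsAsFactors = FALSE)
  missing_meta <- setdiff(colnames(table), metadata$sample_id)
  if (length(missing_meta))
    add("error", paste("samples missing from metadata:",
                       paste(missing_meta, collapse = ", ")))
  extra <- setdiff(metadata$sample_id, colnames(table))
  if (length(extra))
    add("warning", paste("metadata rows without table samples:",
                         paste(extra, collapse = ", ")))
  zero <- colnames(table)[colSums(count_matrix(as_abundance_table(table))) == 0]
  if (length(zero))
    add("error", paste("zero-total samples:", paste(zero, collapse = ", ")))
  if (!is.null(taxonomy)) {
    unknown <- setdiff(rownames(table), taxonomy$taxon_id)
    if (length(unknown))
      add("warning", paste(length(unknown),
                           "taxa missing from taxonomy (unclassified bucket)"))
  }
  if (length(issues)) do.call(rbind, issues)
  else data.frame(severity = character(0), message = character(0))
}

#' Run the full community-analysis pipeline
#'
#' Loads (or simulates) the inputs, validates them, then executes the
#' enabled stages in order - diversity, profiles, ordination, CLAM,
#' network - writing one TSV/CSV/Newick/GraphML artifact set per stage
#' plus a run manifest (package version, every parameter actually used,
#' seed, input checksums, stage list). Re-running an identical
#' configuration on identical inputs reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  checksums <- list()
  if (!is.null(config$preset)) {
    presets <- synthetic_presets()
    if (!config$preset %in% names(presets))
      stop("unknown preset '", config$preset, "'; available: ",
           paste(names(presets), collapse = ", "), call. = FALSE)
    sim <- simulate_community(presets[[config$preset]])
    table <- sim$table; metadata <- sim$metadata; taxonomy <- NULL
  } else {
    for (p in c(config$table, config$metadata, config$taxonomy))
      if (!file.exists(p))
        stop("[input] file not found: ", p, call. = FALSE)
    table <- read_abundance_table(config$table)
    metadata <- read_sample_metadata(config$metadata)
    taxonomy <- if (!is.null(config$taxonomy)) read_taxonomy(config$taxonomy)
    checksums <- as.list(tools::md5sum(
      unlist(c(config$table, config$metadata, config$taxonomy))))
  }

  issues <- validate_inputs(table, metadata, taxonomy)
  utils::write.table(issues, file.path(out, "validation.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (any(issues$severity == "error"))
    stop("[validate] ", paste(issues$message[issues$severity == "error"],
                              collapse = "; "), call. = FALSE)

  results <- list()
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }

  if ("diversity" %in% config$stages) results$diversity <- stage("diversity", {
    rep <- diversity_report(table)
    utils::write.table(rep$indices, file.path(out, "diversity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rep$curves, file.path(out, "rarefaction.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rep
  })

  if ("profiles" %in% config$stages) results$profiles <- stage("profiles", {
    prof_table <- table
    if (!is.null(taxonomy) && !is.null(config$rank))
      prof_table <- aggregate_by_rank(table, taxonomy, config$rank)
    rel <- relative_abundance(prof_table, "percent")
    utils::write.table(cbind(taxon_id = rownames(rel),
                             as.data.frame(round(unclass(rel), 6))),
                       file.path(out, "relative_abundance_pct.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    top <- top_k_taxa(rel, min(config$top_k, nrow(rel)))
    writeLines(top, file.path(out, "top_taxa.txt"))
    hs <- NULL
    if (ncol(rel) >= 2) {
      hs <- heatmap_structure(rel, k = min(config$top_k, nrow(rel)))
      write_dendrogram(hs$sample_tree, file.path(out, "sample_dendrogram.nwk"))
      if (!is.null(hs$taxon_tree))
        write_dendrogram(hs$taxon_tree, file.path(out, "taxon_dendrogram.nwk"))
    }
    list(top = top, heatmap = hs)
  })

  if ("ordination" %in% config$stages) results$ordination <- stage("ordination", {
    d <- bray_curtis(table)
    utils::write.table(as.matrix(d), file.path(out, "bray_curtis.tsv"),
                       sep = "\t", quote = FALSE)
    pc <- pcoa(d)
    utils::write.table(pc$coordinates, file.path(out, "pcoa_coords.tsv"),
                       sep = "\t", quote = FALSE)
    meta <- align_metadata(table, metadata)
    pm <- permanova(d, meta[[config$group_factor]], n_perm = config$n_perm,
                    seed = derive_seed(config$seed, "permanova"))
    pm_df <- data.frame(factor = config$group_factor, pseudo_f = pm$f,
                        r_squared = pm$r_squared, p_value = pm$p_value,
                        n_perm = pm$n_perm)
    utils::write.table(pm_df, file.path(out, "permanova.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(pcoa = pc, permanova = pm)
  })

  if ("clam" %in% config$stages) results$clam <- stage("clam", {
    ci <- pool_by_habitat(table, metadata, config$habitat_factor)
    res <- clam_classify(ci, threshold = config$clam_threshold,
                         alpha = config$clam_alpha,
                         coverage_limit = config$clam_coverage_limit)
    utils::write.table(as.data.frame(res), file.path(out, "clam.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    smry <- clam_summary(res)
    utils::write.table(rbind(cbind(level = "taxa", smry$taxa),
                             cbind(level = "reads", smry$reads)),
                       file.path(out, "clam_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(clam_plot_coords(res),
                       file.path(out, "clam_plot_coords.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    list(result = res, summary = smry)
  })

  if ("network" %in% config$stages) results$network <- stage("network", {
    kept <- filter_rare(table, config$min_mean_relabund)
    screen <- spearman_screen(kept, config$rho_min, config$p_max)
    net <- project_affiliation(kept, screen)
    write_network(net, file.path(out, "network_edges.tsv"), "edge_list_tsv")
    write_network(net, file.path(out, "network.graphml"), "graphml")
    utils::write.table(node_summaries(net),
                       file.path(out, "node_summaries.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.csv(chord_matrix(net), file.path(out, "chord_matrix.csv"),
                     quote = FALSE)
    net
  })

  manifest <- list(
    package = "permanet",
    version = as.character(utils::packageVersion("permanet")),
    stages = c("load", "validate", intersect(
      c("diversity", "profiles", "ordination", "clam", "network"),
      config$stages)),
    seed = config$seed,
    parameters = unclass(config)[setdiff(names(config),
                                         c("table", "metadata", "taxonomy"))],
    input_checksums = checksums)
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))
  invisible(c(results, list(manifest = manifest)))
}
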
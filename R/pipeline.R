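# Pipeline orchestration: curate -> network -> metrics -> measure ->
# integrate -> clusters, plus a simulate stage for synthetic inputs. The
# run configuration is one YAML file with sections mirroring the package's
# parameter objects; every stage writes deterministic TSV/JSON artifacts so
# reruns with identical configuration and seeds are byte-identical.

#' Default run configuration
#'
#' Returns the configuration skeleton with the pipeline's standard
#' parameter values: no compartment/process filters, hub exclusion off
#' unless lists are supplied, degree threshold 50, metric ensembles of 10
#' replicates, measurement coverage threshold 0.5, cluster search with sets
#' of 25 at depth 2 and overlap thresholds 0.25/0.50/0.75.
#'
#' @param output_dir Directory for stage artifacts.
#' @param seed Base seed for all stochastic stages.
#' @return Nested list usable as `config` in [run_pipeline()].
#' @export
default_config <- function(output_dir = "metnets_out", seed = 1L) {
  list(
    paths = list(model = NULL, measurements = NULL,
                 output_dir = output_dir),
    curation = list(boundary_compartment = NULL,
                    extracellular_compartment = NULL,
                    name_patterns = c("biomass",
                                      "protein (assembly|degradation)")),
    network = list(compartmentalize = FALSE, compartment_filter = NULL,
                   process_filter = NULL,
                   hubs_category1 = character(),
                   hubs_category2 = character(),
                   degree_threshold = 50L,
                   keep_largest_component = TRUE),
    metrics = list(mode = "metabolite", replicates = 10L),
    measurement = list(coverage_threshold = 0.5, var_equal = TRUE),
    clusters = list(n_modules = 25L, depth = 2L,
                    overlap_thresholds = c(0.25, 0.50, 0.75)),
    simulate = list(toy = "toy4", effects = list()),
    seed = as.integer(seed))
}

#' Read a run configuration from YAML
#'
#' Missing keys fall back to [default_config()] values.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_cfg <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]])) {
        merge_cfg(base[[k]], over[[k]])
      } else over[[k]]
    }
    base
  }
  merge_cfg(default_config(), user)
}

config_network_spec <- function(cfg) {
  network_spec(
    compartmentalize = isTRUE(cfg$network$compartmentalize),
    compartment_filter = cfg$network$compartment_filter,
    process_filter = cfg$network$process_filter,
    excluded_metabolites = c(cfg$network$hubs_category1,
                             cfg$network$hubs_category2),
    degree_threshold = cfg$network$degree_threshold,
    keep_largest_component = isTRUE(cfg$network$keep_largest_component))
}

stage_path <- function(cfg, ...) file.path(cfg$paths$output_dir, ...)

#' Run pipeline stages
#'
#' Executes the requested stages in their canonical order
#' (`simulate`, `curate`, `network`, `metrics`, `measure`, `integrate`,
#' `clusters`), each reading the previous stages' artifacts from the
#' configured output directory. A log records the configuration hash so
#' reruns can be verified identical.
#'
#' @param config Configuration list (see [default_config()] /
#'   [read_config()]).
#' @param stages Character vector; subset of the stage names above. An
#'   empty vector is a no-op.
#' @return Invisibly, a named list of artifact paths written.
#' @export
run_pipeline <- function(config, stages = character()) {
  canonical <- c("simulate", "curate", "network", "metrics", "measure",
                 "integrate", "clusters")
  unknown <- setdiff(stages, canonical)
  if (length(unknown)) {
    stop("unknown stage(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  stages <- canonical[canonical %in% stages]
  if (length(stages) == 0L) return(invisible(list()))
  dir.create(config$paths$output_dir, recursive = TRUE,
             showWarnings = FALSE)
  artifacts <- list()
  log_lines <- character()
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  cfg_tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, cfg_tmp)
  note("config_hash: ", unname(tools::md5sum(cfg_tmp)))
  unlink(cfg_tmp)

  need <- function(path, producer) {
    if (!file.exists(path)) {
      stop("missing prerequisite artifact '", path,
           "'; run the '", producer, "' stage first", call. = FALSE)
    }
    path
  }
  model_path <- function() {
    curated <- stage_path(config, "model_curated.json")
    if (file.exists(curated)) curated
    else need(config$paths$model %||% stage_path(config, "model.json"),
              "curate")
  }
  measurements_path <- function() {
    config$paths$measurements %||% stage_path(config, "measurements.tsv")
  }

  for (stage in stages) {
    note("stage: ", stage)
    switch(stage,
      simulate = {
        model <- toy_model(config$simulate$toy %||% "toy4")
        eff <- config$simulate$effects %||% list()
        es <- effect_spec(
          affected = unlist(eff$affected %||% numeric()),
          n_per_group = eff$n_per_group %||% 10L,
          paired = isTRUE(eff$paired),
          sigma = eff$sigma %||% 0.25,
          seed = config$seed)
        study <- generate_measurements(model, es)
        artifacts$model <- stage_path(config, "model.json")
        artifacts$measurements <- stage_path(config, "measurements.tsv")
        write_model(model, artifacts$model)
        write_measurements(study, artifacts$measurements)
        config$paths$model <- artifacts$model
        config$paths$measurements <- artifacts$measurements
      },
      curate = {
        model <- read_model(need(config$paths$model %||%
                                   stage_path(config, "model.json"),
                                 "simulate"))
        fc <- filter_config(
          boundary_compartment = config$curation$boundary_compartment,
          extracellular_compartment =
            config$curation$extracellular_compartment,
          name_patterns = config$curation$name_patterns)
        model <- suppressWarnings(filter_simulation_artifacts(model, fc))
        model <- classify_model_behaviors(model)
        model <- assign_transport_processes(model)
        artifacts$model_curated <- stage_path(config, "model_curated.json")
        artifacts$curation_summary <-
          stage_path(config, "curation_summary.tsv")
        write_model(model, artifacts$model_curated)
        write_curation_summary(summarize_curation(model),
                               artifacts$curation_summary)
      },
      network = {
        model <- read_model(model_path())
        net <- build_network(model, config_network_spec(config))
        artifacts$network <- stage_path(config, "network.json")
        artifacts$network_tables <- stage_path(config, "network")
        export_network(net, artifacts$network, "node_link_text")
        export_network(net, artifacts$network_tables, "cytoscape_tables")
      },
      metrics = {
        model <- read_model(model_path())
        net <- build_network(model, config_network_spec(config))
        rep <- metrics_report(net, mode = config$metrics$mode,
                              replicates = config$metrics$replicates,
                              seed = config$seed)
        artifacts$metrics <- stage_path(config, "metrics.tsv")
        artifacts$ranks <- stage_path(config, "ranks.tsv")
        write_report(rep, artifacts$metrics)
        utils::write.table(rep$ranks, artifacts$ranks, sep = "\t",
                           quote = FALSE, row.names = FALSE)
      },
      measure = {
        study <- read_measurements(need(measurements_path(), "simulate"))
        study <- suppressMessages(filter_coverage(
          study, config$measurement$coverage_threshold))
        model <- read_model(model_path())
        key <- suppressWarnings(match_analytes(study, model))
        study <- resolve_redundancy(study, key)
        study <- normalize_total_signal(study)
        comp <- suppressMessages(compare_groups(
          study, var_equal = isTRUE(config$measurement$var_equal)))
        comp$metabolite <- unname(key[comp$analyte])
        artifacts$comparisons <- stage_path(config, "comparisons.tsv")
        artifacts$volcano <- stage_path(config, "volcano.tsv")
        write_comparisons(comp, artifacts$comparisons)
        utils::write.table(volcano_data(comp), artifacts$volcano,
                           sep = "\t", quote = FALSE, row.names = FALSE)
      },
      integrate = {
        model <- read_model(model_path())
        net <- build_network(model, config_network_spec(config))
        comp <- utils::read.delim(need(stage_path(config,
                                                  "comparisons.tsv"),
                                       "measure"))
        comp <- data.frame(analyte = comp$analyte,
                           metabolite = as.character(comp$metabolite),
                           log2_fold_change = comp$log2fc,
                           p_value = comp$p_value,
                           stringsAsFactors = FALSE)
        net <- suppressMessages(suppressWarnings(
          annotate_network(net, comp)))
        artifacts$annotated <- stage_path(config, "network_annotated.json")
        export_network(net, artifacts$annotated, "node_link_text")
      },
      clusters = {
        model <- read_model(model_path())
        net <- build_network(model, config_network_spec(config))
        comp <- utils::read.delim(need(stage_path(config,
                                                  "comparisons.tsv"),
                                       "measure"))
        comp <- data.frame(analyte = comp$analyte,
                           metabolite = as.character(comp$metabolite),
                           log2_fold_change = comp$log2fc,
                           p_value = comp$p_value,
                           stringsAsFactors = FALSE)
        net <- suppressMessages(suppressWarnings(
          annotate_network(net, comp)))
        ann <- net$annotations
        if (is.null(ann)) {
          stop("no measurements matched network nodes; nothing to cluster",
               call. = FALSE)
        }
        z <- node_z_scores(data.frame(metabolite = ann$id,
                                      p_value = ann$p_value,
                                      stringsAsFactors = FALSE))
        found <- search_modules(
          net, z, n_modules = config$clusters$n_modules,
          depth = config$clusters$depth,
          overlap_thresholds = config$clusters$overlap_thresholds,
          seed = config$seed)
        kept <- filter_clusters(found, net)
        artifacts$clusters <- stage_path(config, "clusters")
        export_clusters(if (length(kept)) kept else found, net,
                        artifacts$clusters)
        note("clusters_found: ", length(found),
             "; clusters_kept: ", length(kept))
      })
  }
  writeLines(log_lines, stage_path(config, "run_log.txt"))
  invisible(artifacts)
}
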
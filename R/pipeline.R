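# End-to-end orchestration: simulate or load a cohort, build the backbone,
# call positivity and seeds, run the iterative search, optionally bootstrap,
# and write every stage table plus a provenance manifest. Identical config and
# seeds give byte-identical pathway and stability tables.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

.pipeline_defaults <- function(config) {
  d <- list(
    simulate = list(model = "random_geometric", nodes_per_hemisphere = 8,
                    template_seed = 1L, n_subjects = 62, rng_seed = 7L,
                    beta1 = 0.5, alpha1 = 0.5, chain_length = 6,
                    null = FALSE),
    input = NULL,
    ddis = list(),
    bootstrap = list(enabled = FALSE, n_boot = 100, rng_seed = 17L,
                     min_frequency = 0.30, resample_backbone = FALSE),
    sweep = list(from = 0.04, to = 0.11, step = 0.01))
  for (nm in names(config)) {
    if (is.list(config[[nm]]) && is.list(d[[nm]]))
      d[[nm]][names(config[[nm]])] <- config[[nm]]
    else d[[nm]] <- config[[nm]]
  }
  d
}

#' Run the whole pipeline from a configuration
#'
#' Configuration is a named list or the path to a YAML file with blocks
#' `simulate` (or `input: dir` pointing at the four cohort tables), `ddis`
#' (fields of [ddis_config()]), `bootstrap` (`enabled`, `n_boot`, `rng_seed`,
#' `min_frequency`, `resample_backbone`) and `sweep` (`from`, `to`, `step`).
#' The configuration is validated before any computation; any stage error
#' aborts with a stage-tagged message.
#'
#' Outputs written to `out_dir`: `pathways.tsv`, `tested_connections.tsv`,
#' `prevalence.tsv`, `backbone_edges.tsv`, `sweep.tsv`, `summary.tsv`,
#' `stability.tsv` (when the bootstrap is enabled) and `manifest.json`
#' (config snapshot, package version, RNG seeds, per-stage row counts and
#' output checksums — enough to re-run bit-identically given the same
#' inputs).
#'
#' @param config named list or YAML file path.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `cohort`, `backbone`, `prevalence`,
#'   `seeds`, `pattern`, `stability` (or `NULL`), and `paths`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("[stage config] config must be a list or a YAML path")
  cfg <- .pipeline_defaults(config)
  dcfg <- .stage("config", do.call(ddis_config, cfg$ddis))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- .stage("cohort", {
    if (!is.null(cfg$input)) {
      dir <- if (is.list(cfg$input)) cfg$input$dir else cfg$input
      load_cohort(file.path(dir, "subjects.tsv"), file.path(dir, "nodes.tsv"),
                  file.path(dir, "edges.tsv"),
                  file.path(dir, "parcellation.tsv"))
    } else {
      sc <- cfg$simulate
      tpl <- make_template_graph(sc$nodes_per_hemisphere, sc$model,
                                 rng_seed = sc$template_seed)
      chains <- .default_chains(tpl, sc$chain_length)
      gt <- ground_truth(tpl, chains = chains,
                         beta1 = if (isTRUE(sc$null)) 0 else sc$beta1,
                         alpha1 = if (isTRUE(sc$null)) 0 else sc$alpha1,
                         metric = dcfg$metric)
      simulate_cohort(gt, sc$n_subjects, sc$rng_seed)
    }
  })
  .stage("validate", {
    viol <- validate_cohort(cohort)
    if (length(viol) > 0)
      stop("cohort validation failed:\n  ", paste(viol, collapse = "\n  "))
  })

  backbone <- .stage("backbone",
    build_backbone(cohort, dcfg$backbone_fraction, dcfg$size_correction))
  sweep_tab <- .stage("sweep", {
    fr <- seq(cfg$sweep$from, cfg$sweep$to, by = cfg$sweep$step)
    backbone_sweep(backbone$group_mean, fr)
  })
  prev <- .stage("prevalence", {
    pos <- call_positivity(cohort$node_signal[[dcfg$signal]],
                           dcfg$positivity_cutoff, dcfg$positivity_comparator)
    compute_prevalence(pos, dcfg$signal, dcfg$positivity_cutoff)
  })
  seeds <- .stage("seeds",
    select_seeds(prev, cohort$parcellation, dcfg$seed_prevalence,
                 dcfg$seed_list))
  pattern <- .stage("search", run_ddis(cohort, backbone, seeds, dcfg))

  paths <- list(pathways = file.path(out_dir, "pathways.tsv"),
                tested = file.path(out_dir, "tested_connections.tsv"),
                prevalence = file.path(out_dir, "prevalence.tsv"),
                backbone = file.path(out_dir, "backbone_edges.tsv"),
                sweep = file.path(out_dir, "sweep.tsv"),
                summary = file.path(out_dir, "summary.tsv"))
  .stage("write", {
    write_pathway_table(pattern, paths$pathways)
    .write_tsv(pattern$tested, paths$tested)
    write_prevalence_table(prev, cohort$parcellation, seeds, paths$prevalence)
    write_backbone_table(backbone, cohort$parcellation, paths$backbone)
    .write_tsv(sweep_tab, paths$sweep)
    .write_tsv(summarize_pattern(pattern), paths$summary)
  })

  stability <- NULL
  if (isTRUE(cfg$bootstrap$enabled)) {
    stability <- .stage("bootstrap",
      bootstrap_ddis(cohort, dcfg, n_boot = cfg$bootstrap$n_boot,
                     rng_seed = cfg$bootstrap$rng_seed,
                     resample_backbone = isTRUE(cfg$bootstrap$resample_backbone)))
    paths$stability <- file.path(out_dir, "stability.tsv")
    .stage("write", write_stability_table(
      filter_stability(stability, cfg$bootstrap$min_frequency),
      paths$stability))
  }

  .stage("manifest", {
    files <- unlist(paths)
    manifest <- list(
      package_version = as.character(utils::packageVersion("ddis")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = cfg,
      n_subjects = n_subjects(cohort), n_rois = n_rois(cohort),
      n_backbone_edges = nrow(backbone$edges),
      n_seeds = length(seeds$roi_ids),
      n_pathways = nrow(pattern$pathways),
      n_tested_connections = nrow(pattern$tested),
      output_md5 = as.list(tools::md5sum(files)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  })
  invisible(list(cohort = cohort, backbone = backbone, prevalence = prev,
                 seeds = seeds, pattern = pattern, stability = stability,
                 paths = paths))
}
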
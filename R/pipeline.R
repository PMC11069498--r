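pipeline_defaults <- function() {
  list(seed = 0L, output_dir = NULL,
       min_prevalence = 0.01, rarefaction_depth = NULL,
       alpha = 0.1, n_permutations = 1000L,
       index_name = "rural_index", min_overlap = 150L, bin_width = 10L,
       coupling_permutations = 100L,
       reference_table = NULL, reference_metadata = NULL,
       target_table = NULL, target_metadata = NULL,
       contaminant_scores = NULL,
       coefficients_a = NULL, coefficients_b = NULL,
       omics_x = NULL, omics_y = NULL,
       simulate = NULL)
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration, fills in defaults, and aggregates all
#' problems (unknown keys, missing input files) into a single error.
#' A config either names input files (`reference_table`,
#' `reference_metadata`, `target_table`, `target_metadata`, optional
#' `contaminant_scores`, `coefficients_a`/`coefficients_b`,
#' `omics_x`/`omics_y`) or carries a `simulate:` block of [sim_config()]
#' fields in place of the cohort paths.
#'
#' @param path Path to a YAML config file, or a named list.
#' @return The resolved `pipeline_config` list.
#' @export
validate_config <- function(path) {
  raw <- if (is.character(path)) {
    if (!file.exists(path)) abort(sprintf("no such config file: %s", path))
    yaml::read_yaml(path)
  } else if (is.list(path)) path else abort("`path` must be a file path or a list")
  defaults <- pipeline_defaults()
  problems <- character()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown)) {
    problems <- c(problems, sprintf("unknown config key(s): %s",
                                    paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, raw[intersect(names(raw), names(defaults))])
  path_keys <- c("reference_table", "reference_metadata", "target_table",
                 "target_metadata", "contaminant_scores",
                 "coefficients_a", "coefficients_b", "omics_x", "omics_y")
  for (k in path_keys) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]])) {
      problems <- c(problems, sprintf("%s: no such file: %s", k, cfg[[k]]))
    }
  }
  if (is.null(cfg$simulate) &&
      (is.null(cfg$reference_table) || is.null(cfg$target_table))) {
    problems <- c(problems,
                  "either a `simulate:` block or reference/target table paths are required")
  }
  if (!is.null(cfg$simulate)) {
    ok_sim <- names(formals(sim_config))
    bad <- setdiff(names(cfg$simulate), ok_sim)
    if (length(bad)) problems <- c(problems, sprintf(
      "unknown simulate key(s): %s", paste(bad, collapse = ", ")))
  }
  if (length(problems)) abort(paste(c("invalid configuration:", problems),
                                    collapse = "\n  - "))
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes (optionally) the synthetic cohort simulation, then the index
#' workflow ([run_index_pipeline()]), plus coefficient concordance and
#' paired-omics coupling when their inputs are configured. All stage seeds
#' are fanned out from the single global seed with [derive_seed()], so
#' reruns with the same config are byte-identical. When `output_dir` is
#' set, per-stage TSV/JSON artifacts and a run summary (with seed and a
#' config hash) are written.
#'
#' @param config A `pipeline_config` from [validate_config()] (or a path /
#'   list, validated on the fly).
#' @return A `ruralindex_run` list of stage results.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  seed <- as.integer(config$seed)
  out <- list(config = config, seed = seed)

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% derive_seed(seed, "simulate")
    scfg <- do.call(sim_config, sim_args)
    ref <- simulate_reference_cohort(scfg)
    tgt <- simulate_target_cohort(scfg, ref$truth)
    contaminants <- simulate_contaminant_scores(
      ref$truth, seed = derive_seed(seed, "contaminants"))
    out$truth <- ref$truth
  } else {
    ref <- list(table = read_feature_table(config$reference_table),
                metadata = read_sample_metadata(config$reference_metadata))
    tgt <- list(table = read_feature_table(config$target_table),
                metadata = read_sample_metadata(config$target_metadata))
    contaminants <- if (!is.null(config$contaminant_scores))
      read_contaminant_scores(config$contaminant_scores) else NULL
  }

  out$report <- run_index_pipeline(
    ref$table, ref$metadata, tgt$table, tgt$metadata,
    contaminant_scores = contaminants,
    min_prevalence = config$min_prevalence,
    rarefaction_depth = config$rarefaction_depth,
    da = da_config(n_permutations = config$n_permutations,
                   alpha = config$alpha,
                   seed = derive_seed(seed, "diffabund")),
    index_name = config$index_name,
    min_overlap = config$min_overlap,
    seed = seed)

  if (!is.null(config$coefficients_a) && !is.null(config$coefficients_b)) {
    out$concordance <- concordance(
      readr::read_tsv(config$coefficients_a, col_types = readr::cols()),
      readr::read_tsv(config$coefficients_b, col_types = readr::cols()))
  }
  if (!is.null(config$omics_x) && !is.null(config$omics_y)) {
    x <- ft_matrix(read_feature_table(config$omics_x, kind = "abundance"))
    y <- ft_matrix(read_feature_table(config$omics_y, kind = "abundance"))
    out$coupling <- coupling_significance(
      x, y, n_permutations = config$coupling_permutations,
      seed = derive_seed(seed, "coupling"))
  }

  if (!is.null(config$output_dir)) write_run_artifacts(out, config$output_dir)
  structure(out, class = "ruralindex_run")
}

write_run_artifacts <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rep <- run$report
  readr::write_tsv(tidy(rep$differential_abundance),
                   file.path(dir, "differential_abundance.tsv"))
  write_index_definition(rep$index, file.path(dir, "index_definition.json"))
  readr::write_tsv(rep$scores, file.path(dir, "index_scores.tsv"))
  readr::write_tsv(rep$comparisons, file.path(dir, "group_comparisons.tsv"))
  if (!is.null(run$concordance)) {
    readr::write_tsv(glance(run$concordance), file.path(dir, "concordance.tsv"))
  }
  if (!is.null(run$coupling)) {
    jsonlite::write_json(
      list(rho_observed = run$coupling$rho_observed, p = run$coupling$p,
           null_rhos = run$coupling$null_rhos),
      file.path(dir, "coupling.json"), auto_unbox = TRUE, digits = NA)
  }
  summary <- list(seed = run$seed,
                  config_hash = rlang::hash(unclass(run$config)),
                  log = rep$log,
                  n_significant = sum(rep$differential_abundance$results$significant),
                  comparisons = rep$comparisons)
  jsonlite::write_json(summary, file.path(dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}

#' @export
print.ruralindex_run <- function(x, ...) {
  cat(sprintf("ruralindex pipeline run (seed %d)\n", x$seed))
  print(x$report)
  if (!is.null(x$concordance)) print(x$concordance)
  if (!is.null(x$coupling)) print(x$coupling)
  invisible(x)
}
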
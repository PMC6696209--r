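#' Pipeline configuration
#'
#' Bundles every tunable of the selection pipeline.  The single `seed`
#' fans out to fixed per-stage sub-seeds (`seed + 101` for cohort
#' generation, `+ 202` for multiple imputation, `+ 303` for the forest)
#' so each stochastic stage is independently reproducible.
#'
#' @param synth a `synth_config` used to generate the cohort, or `NULL`
#'   when `input` tables are supplied.
#' @param input optional list with elements `table`
#'   (`measure_table`), `catalogue`, and optionally `retest_table` and
#'   `clinical`, for running on user data instead of a synthetic
#'   cohort.
#' @param smd_threshold sensitivity threshold on |SMD| (default 0.5).
#' @param corr_threshold redundancy threshold on |rho| (default 0.70).
#' @param missing_task_threshold task-removal missingness fraction
#'   (default 0.20).
#' @param m_imputations completed datasets for multiple imputation
#'   (default 25).
#' @param smd_variant SMD denominator (see [smd()]).
#' @param folds cross-validation folds (default 10).
#' @param n_trees forest size (default 500).
#' @param alpha significance level for clinical associations
#'   (default 0.01).
#' @param seed master integer seed (mandatory).
#' @return List of class `run_config`.
#' @export
run_config <- function(synth = default_study_config(), input = NULL,
                       smd_threshold = 0.5, corr_threshold = 0.70,
                       missing_task_threshold = 0.20, m_imputations = 25,
                       smd_variant = "paper", folds = 10, n_trees = 500,
                       alpha = 0.01, seed = 1L) {
  stopifnot(smd_threshold > 0, corr_threshold > 0, corr_threshold < 1,
            missing_task_threshold > 0, missing_task_threshold < 1,
            m_imputations >= 1, folds >= 2, alpha > 0, alpha < 1,
            is.numeric(seed))
  if (is.null(synth) && is.null(input))
    stop("either a synth config or input tables must be given")
  structure(list(synth = synth, input = input,
                 smd_threshold = smd_threshold,
                 corr_threshold = corr_threshold,
                 missing_task_threshold = missing_task_threshold,
                 m_imputations = m_imputations, smd_variant = smd_variant,
                 folds = folds, n_trees = n_trees, alpha = alpha,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full measure-selection pipeline
#'
#' Executes, in order: cohort acquisition (synthetic or user tables),
#' removal of tasks with excessive missingness, worst-case single-value
#' imputation (fall / no-APA cells), chained-equation multiple
#' imputation (skip / unusable / noisy cells), SMD sensitivity
#' filtering pooled over the imputed datasets, Spearman redundancy
#' pruning, random-forest 10-fold cross-validation on the pruned
#' survivors and on all analysed measures, test-retest reliability of
#' the survivors (when a retest table exists), and clinical-scale
#' associations (when a clinical table exists).
#'
#' @param config a `run_config`.
#' @param out_dir optional directory: per-stage CSV/JSON reports and
#'   the manifest are written there.
#' @return List of class `selection_run` with `manifest` (stage-by-stage
#'   measure counts, config echo, output hashes), `effects`,
#'   `selected`, `corr`, `audit`, `forest_selected`, `forest_all`,
#'   `reliability`, `associations`, and the intermediate `cohort` /
#'   `ensemble`.
#' @export
run_selection_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  stage_counts <- c()

  ## stage 1: data
  if (!is.null(config$input)) {
    table <- config$input$table
    cat <- config$input$catalogue
    retest <- config$input$retest_table
    clinical <- config$input$clinical
    cohort <- NULL
  } else {
    synth <- config$synth
    synth$seed <- seed + 101L
    cohort <- generate_cohort(synth)
    table <- cohort$table
    cat <- synth$catalogue
    retest <- cohort$retest_table
    clinical <- cohort$clinical
  }
  stage_counts["initial"] <- nrow(cat)

  ## stage 2: task removal
  dropped <- drop_high_missing_tasks(table, cat,
                                     config$missing_task_threshold)
  table <- dropped$table; cat <- dropped$catalogue
  stage_counts["after_task_removal"] <- nrow(cat)

  ## stage 3: imputation (worst-case, then multiple); the unimputed
  ## table is kept for reliability, which uses observed pairs only
  observed_table <- table
  table <- impute_worst_case(table, cat)
  ensemble <- impute_multiple(table, m = config$m_imputations,
                              seed = seed + 202L)

  ## stage 4: SMD filter (pooled over the ensemble)
  effects <- effect_size_table(ensemble, variant = config$smd_variant)
  selected <- filter_by_smd(effects, config$smd_threshold)
  stage_counts["after_smd_filter"] <- nrow(selected)

  ## stage 5: redundancy pruning
  if (nrow(selected) >= 2) {
    corr <- spearman_matrix(ensemble, selected$measure_id)
    audit <- prune_redundant(selected, corr, cat, config$corr_threshold)
  } else {
    corr <- NULL
    audit <- structure(list(survivors = selected$measure_id,
                            removed = data.frame(), threshold =
                              config$corr_threshold),
                       class = "pruning_audit")
  }
  stage_counts["after_pruning"] <- length(audit$survivors)

  ## stage 6: forest validation on one completed dataset (the first;
  ## classification metrics are insensitive to the imputation draw)
  complete1 <- ensemble$datasets[[1]]
  forest_selected <- forest_all <- NULL
  if (length(audit$survivors) >= 2) {
    forest_selected <- cross_validate_forest(
      complete1, audit$survivors, folds = config$folds,
      seed = seed + 303L, n_trees = config$n_trees)
    forest_all <- cross_validate_forest(
      complete1, measure_ids(complete1), folds = config$folds,
      seed = seed + 303L, n_trees = config$n_trees)
  }

  ## stage 7: reliability of the survivors
  reliability <- NULL
  if (!is.null(retest) && length(audit$survivors)) {
    ids <- intersect(audit$survivors, measure_ids(retest))
    reliability <- reliability_table(observed_table, retest, ids)
  }

  ## stage 8: clinical associations of the survivors
  associations <- NULL
  if (!is.null(clinical) && length(audit$survivors)) {
    associations <- associate_clinical(complete1, clinical,
                                       audit$survivors,
                                       alpha = config$alpha)
  }

  manifest <- list(
    stage_counts = stage_counts,
    removed_tasks = dropped$removed_tasks$task,
    no_measures_retained = nrow(selected) == 0,
    config = list(smd_threshold = config$smd_threshold,
                  corr_threshold = config$corr_threshold,
                  missing_task_threshold = config$missing_task_threshold,
                  m_imputations = config$m_imputations,
                  smd_variant = config$smd_variant, folds = config$folds,
                  n_trees = config$n_trees, alpha = config$alpha,
                  seed = seed),
    version = as.character(utils::packageVersion("balanceselect")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  run <- structure(list(manifest = manifest, effects = effects,
                        selected = selected, corr = corr, audit = audit,
                        forest_selected = forest_selected,
                        forest_all = forest_all,
                        reliability = reliability,
                        associations = associations,
                        cohort = cohort, ensemble = ensemble,
                        catalogue = cat),
                   class = "selection_run")
  if (!is.null(out_dir)) write_run_reports(run, out_dir)
  run
}

#' Write per-stage reports and the run manifest
#'
#' @param run a `selection_run`.
#' @param out_dir output directory (created if needed).
#' @return The manifest (with file hashes added), invisibly.
#' @export
write_run_reports <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths[name] <<- p
  }
  wr(run$effects, "effect_sizes.csv")
  wr(as.data.frame(run$selected), "smd_selected.csv")
  if (!is.null(run$corr)) wr(as.data.frame(run$corr$rho),
                             "correlation_matrix.csv")
  wr(run$audit$removed, "pruning_removed.csv")
  wr(data.frame(measure_id = run$audit$survivors), "survivors.csv")
  if (!is.null(run$reliability)) wr(run$reliability, "reliability.csv")
  if (!is.null(run$associations))
    wr(as.data.frame(run$associations), "clinical_associations.csv")
  if (!is.null(run$forest_selected)) {
    fr <- run$forest_selected
    jsonlite::write_json(
      list(accuracy_mean = fr$accuracy_mean, accuracy_sd = fr$accuracy_sd,
           precision_mean = fr$precision_mean,
           precision_sd = fr$precision_sd, oob_error = fr$oob_error,
           importances = as.list(fr$importances)),
      file.path(out_dir, "forest_report.json"), auto_unbox = TRUE,
      digits = NA)
    paths["forest_report.json"] <- file.path(out_dir, "forest_report.json")
  }
  manifest <- run$manifest
  manifest$file_hashes <- as.list(tools::md5sum(unname(paths)))
  names(manifest$file_hashes) <- names(paths)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' @export
print.selection_run <- function(x, ...) {
  sc <- x$manifest$stage_counts
  cat("<selection_run> measures: ",
      paste(sc, collapse = " -> "), "\n", sep = "")
  if (!is.null(x$forest_selected)) {
    cat(sprintf("  CV accuracy (survivors): %.1f +/- %.1f %%; (all): %.1f +/- %.1f %%\n",
                x$forest_selected$accuracy_mean,
                x$forest_selected$accuracy_sd,
                x$forest_all$accuracy_mean, x$forest_all$accuracy_sd))
  }
  invisible(x)
}
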
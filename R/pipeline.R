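#' Pipeline run configuration
#'
#' One object drives a full simulate - adjudicate - featurize - train -
#' stratify run. Can be loaded from YAML with [read_run_config()].
#'
#' @param seed Global seed propagated to every stochastic stage.
#' @param generator A [generator_params()] object.
#' @param thresholds A [kdigo_thresholds()] object.
#' @param selection A [selection_spec()].
#' @param learner A `pkip_learner`.
#' @param bins A [risk_bins()] object.
#' @param folds Cross-validation folds.
#' @param window First-window aggregation width in hours.
#' @param screen_alpha Univariate Cox screening level.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 7L,
                       generator = generator_params(seed = seed),
                       thresholds = kdigo_thresholds(),
                       selection = selection_spec("lasso", seed = seed),
                       learner = learner_logistic(),
                       bins = risk_bins(),
                       folds = 5L,
                       window = 2,
                       screen_alpha = 0.1) {
  structure(list(seed = as.integer(seed), generator = generator,
                 thresholds = thresholds, selection = selection,
                 learner = learner, bins = bins, folds = as.integer(folds),
                 window = window, screen_alpha = screen_alpha),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognised top-level keys: `seed`, `generator`, `thresholds`,
#' `selection`, `bins` (cut points), `folds`, `window`, `screen_alpha`,
#' `learner` (`"logistic"` or `"gbt"`); each maps onto the matching
#' constructor's arguments. Missing keys fall back to package defaults.
#'
#' @param path Path to the YAML file.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- as.integer(y$seed %||% 7L)
  gen_args <- y$generator %||% list()
  if (is.null(gen_args$seed)) {
    gen_args$seed <- seed
  }
  sel_args <- y$selection %||% list()
  if (is.null(sel_args$seed)) {
    sel_args$seed <- seed
  }
  run_config(
    seed = seed,
    generator = do.call(generator_params, gen_args),
    thresholds = do.call(kdigo_thresholds, y$thresholds %||% list()),
    selection = do.call(selection_spec, sel_args),
    learner = switch(y$learner %||% "logistic",
                     logistic = learner_logistic(),
                     gbt = learner_gbt()),
    bins = if (is.null(y$bins)) risk_bins() else risk_bins(unlist(y$bins)),
    folds = as.integer(y$folds %||% 5L),
    window = y$window %||% 2,
    screen_alpha = y$screen_alpha %||% 0.1
  )
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)),
          class = "pkipr_pipeline_error", parent = e)
  })
}

#' Run the full analysis pipeline
#'
#' Simulates a cohort, applies the inclusion filters, adjudicates AKI,
#' builds and preprocesses the first-window feature matrix, screens
#' variables by univariate Cox regression, selects features, trains the
#' cross-validated classifier, optimises the threshold, and stratifies
#' patients into five risk groups with the survival and trend analyses.
#' Every intermediate is persisted under `out_dir` together with a manifest
#' of seeds, sizes and md5 hashes; identical configurations reproduce
#' identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with all stage results (`cohort`, `filters`,
#'   `labels`, `features`, `screen`, `selected`, `cv`, `stratification`,
#'   `manifest`).
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("pkip_")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  th <- config$thresholds
  cohort <- pipeline_stage("simulate", simulate_cohort(config$generator))
  write_cohort(cohort, file.path(out_dir, "cohort"))
  filters <- pipeline_stage("filter", apply_cohort_filters(cohort, th))
  keep_ids <- filters$patient_id[filters$included]
  included <- list(
    static = filter(cohort$static, .data$patient_id %in% keep_ids),
    timeseries = filter(cohort$timeseries, .data$patient_id %in% keep_ids),
    truth = filter(cohort$truth, .data$patient_id %in% keep_ids)
  )
  class(included) <- "pkip_cohort"
  labels <- pipeline_stage("adjudicate", adjudicate_cohort(included, th))
  utils::write.csv(left_join(filters, labels, by = "patient_id"),
                   file.path(out_dir, "labels.csv"), row.names = FALSE)
  feats_raw <- pipeline_stage(
    "featurize", aggregate_first_window(included, config$window))
  feats <- pipeline_stage("preprocess", {
    robust_scale(impute_features(feats_raw, seed = config$seed))
  })
  utils::write.csv(feats, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  outcome_tbl <- pipeline_stage("outcomes", {
    tibble(patient_id = labels$patient_id,
           aki = as.integer(labels$has_aki),
           aki_time = ifelse(labels$has_aki, labels$onset_h,
                             pmin(included$static$end_time,
                                  th$obs_horizon)),
           death = as.integer(included$static$death),
           death_time = pmin(included$static$end_time, th$obs_horizon))
  })
  screen <- pipeline_stage("screen", {
    univariate_cox_screen(
      bind_cols(select(feats, -all_of("patient_id")),
                time = outcome_tbl$aki_time, event = outcome_tbl$aki),
      alpha = config$screen_alpha)
  })
  utils::write.csv(screen, file.path(out_dir, "screen.csv"),
                   row.names = FALSE)
  candidates <- screen$variable[screen$selected]
  selected <- pipeline_stage("select", {
    if (length(candidates) == 0L) {
      abort("no variable passed the screen")
    }
    select_features(feats, outcome_tbl$aki, config$selection,
                    variables = candidates)
  })
  cv <- pipeline_stage("model", {
    if (length(selected) == 0L) {
      abort("feature selection returned an empty set")
    }
    train_cv(feats, outcome_tbl$aki,
             strata = included$static$pesticide_category,
             learner = config$learner, folds = config$folds,
             seed = config$seed, variables = selected)
  })
  utils::write.csv(cv$oof, file.path(out_dir, "oof.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(learner = cv$learner, best_params = cv$best_params,
         auroc = cv$auroc, auroc_ci = cv$auroc_ci, auprc = cv$auprc,
         auprc_ci = cv$auprc_ci, brier = cv$brier,
         threshold = cv$threshold, selected = selected),
    file.path(out_dir, "cv_result.json"), auto_unbox = TRUE, digits = NA)
  strat <- pipeline_stage("stratify", {
    risk_stratification(
      bind_cols(outcome_tbl, prob = cv$oof$prob), bins = config$bins)
  })
  utils::write.csv(strat$by_group, file.path(out_dir, "risk_groups.csv"),
                   row.names = FALSE)
  utils::write.csv(bind_rows(aki = strat$aki$hr, death = strat$death$hr,
                             .id = "outcome"),
                   file.path(out_dir, "hazard_ratios.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(trend_aki = strat$trend_aki, trend_death = strat$trend_death,
         logrank_aki = strat$aki$logrank,
         logrank_death = strat$death$logrank),
    file.path(out_dir, "tests.json"), dataframe = "rows", digits = NA)
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("pkipr")),
    seed = config$seed,
    n_patients = config$generator$n_patients,
    n_included = length(keep_ids),
    files = as.list(setNames(unname(tools::md5sum(files)),
                             sub(paste0(out_dir, "/"), "", files,
                                 fixed = TRUE)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(cohort = cohort, filters = filters, labels = labels,
                 features = feats, outcomes = outcome_tbl, screen = screen,
                 selected = selected, cv = cv, stratification = strat,
                 manifest = manifest, out_dir = out_dir))
}
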
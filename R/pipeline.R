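# End-to-end orchestration: (optionally simulate) -> rest-activity metrics
# -> sleep parameters -> feature assembly -> univariate battery -> the
# three regularised Cox models with out-of-fold evaluation. One global seed
# expands deterministically into per-stage seeds so stages are individually
# reproducible.

.stage_seed <- function(seed, stage) {
  # deterministic small-integer expansion, stays well below 2^31
  (seed * 1009L + stage * 9173L) %% 2147480000L
}

#' Load a cohort's input files from a directory
#'
#' Expects the layout written by [write_cohort()]: `epochs/<id>.csv`,
#' `schedule.csv`, `diary.csv`, `clinical.csv`.
#'
#' @param dir input directory
#' @param schema feature schema used to validate the clinical table
#' @return list with ids, participants (series + schedule), diary, clinical
#' @export
load_cohort_dir <- function(dir, schema = default_feature_schema()) {
  clinical <- read_clinical_csv(file.path(dir, "clinical.csv"), schema)
  diary_path <- file.path(dir, "diary.csv")
  if (!file.exists(diary_path)) {
    rw_abort(paste("missing diary file:", diary_path), "rw_io")
  }
  diary <- read_diary_csv(diary_path)
  ids <- clinical$participant_id
  participants <- lapply(ids, function(id) {
    list(series = read_epoch_csv(file.path(dir, "epochs", paste0(id, ".csv")), id),
         schedule = read_schedule_csv(file.path(dir, "schedule.csv"), id))
  })
  names(participants) <- ids
  list(ids = ids, participants = participants, diary = diary, clinical = clinical)
}

#' Rest-activity metrics for every participant of a cohort
#' @param cohort list as from [generate_cohort()] or [load_cohort_dir()]
#' @param valid_frac validity threshold passed through
#' @return data.frame, one row per participant
#' @export
cohort_metrics <- function(cohort, valid_frac = 0.9) {
  do.call(rbind, lapply(cohort$ids, function(id) {
    p <- cohort$participants[[id]]
    d <- cohort$diary[cohort$diary$participant_id == id, , drop = FALSE]
    rest_activity_metrics(p$series, p$schedule, d, valid_frac)
  }))
}

#' Per-night sleep parameters for every participant of a cohort
#' @param cohort list as from [generate_cohort()] or [load_cohort_dir()]
#' @param sensitivity,onset_run scoring settings
#' @return data.frame of sleep-night rows (both sources)
#' @export
cohort_sleep_nights <- function(cohort, sensitivity = 40, onset_run = 10) {
  do.call(rbind, lapply(cohort$ids, function(id) {
    p <- cohort$participants[[id]]
    d <- cohort$diary[cohort$diary$participant_id == id, , drop = FALSE]
    sleep_nights(p$series, p$schedule, d, sensitivity, onset_run)
  }))
}

#' Run the full analysis pipeline
#'
#' Stages, in order: rest-activity metrics; sleep parameters (actigraphy and
#' diary); feature assembly against the schema; the univariate split
#' battery; and the three penalised Cox models (ridge alpha 0.01, elastic
#' net alpha 0.5, lasso alpha 0.99) with out-of-fold hazards, selection
#' consistency, Kaplan-Meier median-split log-rank and hazard-survival
#' Pearson correlation. The report is a pure function of (inputs, settings,
#' seed).
#'
#' @param cohort in-memory cohort (from [generate_cohort()] /
#'   [load_cohort_dir()]); alternatively pass `input_dir`
#' @param input_dir directory to load the cohort from (ignored when `cohort`
#'   is given)
#' @param schema feature schema (default [default_feature_schema()])
#' @param alphas named vector of elastic-net mixing parameters
#' @param folds cross-validation folds
#' @param seed global seed; per-stage seeds are derived from it
#' @param out_dir optional directory for result tables and the report JSON
#' @param sensitivity,onset_run sleep-scoring settings
#' @param battery univariate split battery (see [normative_sleep_battery()])
#' @return list of class `rw_report`: feature_table, metrics, nights,
#'   univariate, models (per alpha: fit, hazards, evaluation)
#' @export
run_pipeline <- function(cohort = NULL, input_dir = NULL,
                         schema = default_feature_schema(),
                         alphas = c(ridge = 0.01, elastic_net = 0.5, lasso = 0.99),
                         folds = 10, seed = 1, out_dir = NULL,
                         sensitivity = 40, onset_run = 10,
                         battery = normative_sleep_battery()) {
  if (is.null(cohort)) {
    if (is.null(input_dir)) rw_abort("need a cohort or an input_dir", "rw_io")
    cohort <- load_cohort_dir(input_dir, schema)
  }
  metrics <- cohort_metrics(cohort)
  nights <- cohort_sleep_nights(cohort, sensitivity, onset_run)
  ft <- assemble_features(cohort$clinical, metrics, nights, cohort$diary, schema)
  univariate <- run_split_battery(ft, battery)

  models <- lapply(seq_along(alphas), function(i) {
    a <- alphas[[i]]
    cvh <- out_of_fold_hazards(ft, a, folds = folds,
                               seed = .stage_seed(seed, 10L + i))
    eval_km <- tryCatch(km_median_split_eval(cvh$hazard, ft$time, ft$event),
                        restwatch_error = function(e) NULL)
    eval_r <- tryCatch(hazard_survival_correlation(cvh$hazard, ft$time),
                       restwatch_error = function(e) NULL)
    list(alpha = a, hazards = cvh, fit = cvh$final_fit,
         n_nonzero = length(cvh$final_fit$nonzero_set),
         consistent = cvh$consistent,
         median_hazard = stats::median(cvh$hazard),
         logrank = eval_km, pearson = eval_r)
  })
  names(models) <- names(alphas)

  report <- structure(list(feature_table = ft, metrics = metrics,
                           nights = nights, univariate = univariate,
                           models = models, seed = seed),
                      class = "rw_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Summarise a pipeline report as plain values (JSON-ready)
#' @param report an `rw_report`
#' @return nested list of scalar summaries
#' @export
report_summary <- function(report) {
  list(
    n_participants = length(report$feature_table$ids),
    n_predictors = ncol(report$feature_table$x),
    n_events = sum(report$feature_table$event),
    n_imputed_cells = sum(report$feature_table$mask),
    seed = report$seed,
    univariate = report$univariate,
    models = lapply(report$models, function(m) {
      list(alpha = m$alpha,
           n_nonzero = m$n_nonzero,
           n_consistent = length(m$consistent),
           consistent = m$consistent,
           median_hazard = m$median_hazard,
           logrank_statistic = if (is.null(m$logrank)) NA else m$logrank$statistic,
           logrank_p = if (is.null(m$logrank)) NA else m$logrank$p,
           pearson_r = if (is.null(m$pearson)) NA else m$pearson$r,
           pearson_p = if (is.null(m$pearson)) NA else m$pearson$p)
    }))
}

#' Write a pipeline report's tables and JSON summary
#'
#' Emits per-participant metrics, sleep nights, the flat feature CSV with
#' imputation log, the univariate battery table, per-model coefficient and
#' hazard CSVs, KM curve coordinates, and `report.json`.
#'
#' @param report an `rw_report`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  utils::write.csv(report$nights, file.path(dir, "sleep_nights.csv"), row.names = FALSE)
  write_feature_csv(report$feature_table, file.path(dir, "features.csv"),
                    file.path(dir, "imputation_log.csv"))
  utils::write.csv(report$univariate, file.path(dir, "univariate.csv"), row.names = FALSE)
  for (nm in names(report$models)) {
    m <- report$models[[nm]]
    coefs <- data.frame(variable = names(m$fit$coefficients),
                        coefficient = unname(m$fit$coefficients),
                        coefficient_std = unname(m$fit$coefficients_std),
                        selection_count = unname(m$hazards$selection_count))
    utils::write.csv(coefs, file.path(dir, paste0("coefficients_", nm, ".csv")),
                     row.names = FALSE)
    hz <- data.frame(participant_id = names(m$hazards$hazard),
                     oof_hazard = unname(m$hazards$hazard),
                     final_hazard = unname(m$hazards$final_hazard),
                     fold = m$hazards$foldid)
    utils::write.csv(hz, file.path(dir, paste0("hazards_", nm, ".csv")),
                     row.names = FALSE)
    if (!is.null(m$logrank)) {
      fit <- m$logrank$fit
      km <- data.frame(group = rep(names(fit$strata), fit$strata),
                       time = fit$time, surv = fit$surv)
      utils::write.csv(km, file.path(dir, paste0("km_", nm, ".csv")),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(report_summary(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @exportS3Method base::print
print.rw_report <- function(x, ...) {
  cat(sprintf("<rw_report> n=%d, p=%d, %d events\n",
              length(x$feature_table$ids), ncol(x$feature_table$x),
              sum(x$feature_table$event)))
  for (nm in names(x$models)) {
    m <- x$models[[nm]]
    cat(sprintf("  %-12s alpha=%.2f nonzero=%2d consistent=%2d logrank p=%s pearson r=%s\n",
                nm, m$alpha, m$n_nonzero, length(m$consistent),
                if (is.null(m$logrank)) "NA" else format.pval(m$logrank$p, digits = 3),
                if (is.null(m$pearson)) "NA" else sprintf("%.2f", m$pearson$r)))
  }
  invisible(x)
}
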
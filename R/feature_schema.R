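# Feature schema: the declaration of every predictor's name, kind, source
# and encoding parameters. The default schema carries the study design's 66
# predictors: demographics, performance status, palliative prognostic items,
# symptom burden, a routine blood panel, PSQI components, and the actigraphy
# and sleep-diary parameters computed upstream.

.kinds <- c("binary", "categorical_ordinal", "numeric_continuous", "clock_time")
.sources <- c("clinical", "psqi", "actigraphy", "sleep_diary", "derived")

#' Construct a feature schema
#'
#' @param name character vector of unique feature names
#' @param kind one of binary, categorical_ordinal, numeric_continuous,
#'   clock_time per feature
#' @param source where the raw value comes from: clinical, psqi, actigraphy,
#'   sleep_diary or derived
#' @param levels list of level vectors (ordered, low to high) for binary and
#'   ordinal features; NULL entries elsewhere
#' @param twin name of the subjective/objective counterpart used for
#'   twin-first imputation, or NA
#' @return data.frame of class `feature_schema`
#' @export
feature_schema <- function(name, kind, source, levels = NULL, twin = NA_character_) {
  p <- length(name)
  if (anyDuplicated(name)) rw_abort("feature names must be unique", "rw_schema_mismatch")
  if (!all(kind %in% .kinds)) rw_abort("unknown feature kind", "rw_schema_mismatch")
  if (!all(source %in% .sources)) rw_abort("unknown feature source", "rw_schema_mismatch")
  if (is.null(levels)) levels <- vector("list", p)
  levels <- unname(levels)
  needs_levels <- kind %in% c("binary", "categorical_ordinal")
  if (any(needs_levels & vapply(levels, is.null, TRUE))) {
    rw_abort("binary/ordinal features must declare ordered levels", "rw_schema_mismatch")
  }
  df <- data.frame(name = name, kind = kind, source = source,
                   twin = rep_len(twin, p), stringsAsFactors = FALSE)
  df$levels <- levels
  class(df) <- c("feature_schema", "data.frame")
  df
}

#' Read a feature schema from a YAML file
#'
#' The YAML maps each feature name to `kind`, `source`, optional `levels`
#' (ordered list) and optional `twin`.
#'
#' @param path YAML file path
#' @return a `feature_schema`
#' @export
schema_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  feature_schema(
    name = names(y),
    kind = vapply(y, function(e) e$kind, ""),
    source = vapply(y, function(e) e$source, ""),
    levels = lapply(y, function(e) if (is.null(e$levels)) NULL else as.character(e$levels)),
    twin = vapply(y, function(e) if (is.null(e$twin)) NA_character_ else e$twin, ""))
}

#' Write a feature schema to YAML
#' @param schema a `feature_schema`
#' @param path output path
#' @return `path`, invisibly
#' @export
schema_to_yaml <- function(schema, path) {
  y <- lapply(seq_len(nrow(schema)), function(i) {
    e <- list(kind = schema$kind[i], source = schema$source[i])
    if (!is.null(schema$levels[[i]])) e$levels <- as.list(schema$levels[[i]])
    if (!is.na(schema$twin[i])) e$twin <- schema$twin[i]
    e
  })
  names(y) <- schema$name
  yaml::write_yaml(y, path)
  invisible(path)
}

#' The default 66-predictor feature schema
#'
#' Covers the predictors a palliative-prognostication dataset of this design
#' carries: demographics and opioid use; clinician- and patient-assessed
#' ECOG performance status at day 0 and day 8; modified Glasgow Prognostic
#' Score; PiPS-B clinician survival estimate and global health status;
#' symptom-burden (MSAS-SF) totals; a 13-analyte blood panel; seven PSQI
#' component scores, three PSQI disturbance items and the two PSQI habitual
#' clock times; and the twelve actigraphy and eleven sleep-diary parameters
#' produced by the rest-activity and sleep modules. Objective/subjective
#' pairs (actigraphy vs diary sleep parameters) are declared as imputation
#' twins.
#'
#' @return a `feature_schema` with 66 rows
#' @export
default_feature_schema <- function() {
  rows <- list()
  add <- function(name, kind, source, levels = NULL, twin = NA_character_) {
    rows[[length(rows) + 1]] <<- list(name = name, kind = kind, source = source,
                                      levels = levels, twin = twin)
  }
  ord05 <- as.character(0:4)
  ord03 <- as.character(0:3)
  freq_levels <- c("not_past_month", "less_than_weekly", "once_twice_weekly",
                   "three_plus_weekly")

  add("sex_male", "binary", "clinical", c("no", "yes"))
  add("opioid_use", "binary", "clinical", c("no", "yes"))
  for (nm in c("ecog_clin_day0", "ecog_pt_day0", "ecog_clin_day8", "ecog_pt_day8"))
    add(nm, "categorical_ordinal", "clinical", ord05)
  add("mgps", "categorical_ordinal", "clinical", as.character(0:2))
  add("pips_survival_estimate", "categorical_ordinal", "clinical",
      c("days", "weeks", "months_plus"))
  add("pips_global_health", "categorical_ordinal", "clinical", as.character(1:7))
  for (nm in c("age", "pulse", "comorbidity_count", "msas_tmsas",
               "msas_global_distress", "msas_physical", "msas_psych",
               "msas_num_symptoms",
               "months_since_diagnosis", "haemoglobin", "wbc", "neutrophils",
               "lymphocytes", "platelets", "sodium", "potassium", "urea",
               "creatinine", "albumin", "alt", "alp", "crp"))
    add(nm, "numeric_continuous", "clinical")
  for (nm in c("psqi_sleep_quality", "psqi_sleep_latency", "psqi_sleep_duration",
               "psqi_sleep_efficiency", "psqi_sleep_disturbance",
               "psqi_sleep_medication", "psqi_daytime_dysfunction"))
    add(nm, "categorical_ordinal", "psqi", ord03)
  for (nm in c("psqi_dist_wake_night", "psqi_dist_pain", "psqi_dist_breathe"))
    add(nm, "categorical_ordinal", "psqi", freq_levels)
  add("psqi_usual_bt", "clock_time", "psqi")
  add("psqi_usual_gut", "clock_time", "psqi")

  for (nm in c("i_less_o", "r24", "mda", "wake_activity"))
    add(nm, "numeric_continuous", "actigraphy")
  add("act_bt", "clock_time", "actigraphy", twin = "diary_bt")
  add("act_gut", "clock_time", "actigraphy", twin = "diary_gut")
  for (nm in c("act_tib", "act_sol", "act_tst", "act_se", "act_waso", "act_na"))
    add(nm, "numeric_continuous", "actigraphy",
        twin = sub("^act_", "diary_", nm))
  add("diary_bt", "clock_time", "sleep_diary", twin = "act_bt")
  add("diary_gut", "clock_time", "sleep_diary", twin = "act_gut")
  for (nm in c("diary_tib", "diary_sol", "diary_tst", "diary_se", "diary_waso",
               "diary_na"))
    add(nm, "numeric_continuous", "sleep_diary", twin = sub("^diary_", "act_", nm))
  add("diary_twak", "numeric_continuous", "sleep_diary")
  add("diary_time_tried_sleep", "clock_time", "sleep_diary")
  add("diary_final_awakening", "clock_time", "sleep_diary")

  feature_schema(
    name = vapply(rows, `[[`, "", "name"),
    kind = vapply(rows, `[[`, "", "kind"),
    source = vapply(rows, `[[`, "", "source"),
    levels = lapply(rows, `[[`, "levels"),
    twin = vapply(rows, `[[`, "", "twin"))
}
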
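# Assembly of the participants x predictors model matrix: schema-driven
# encoding (dummy 0/1 for binaries, rank-preserving integer labels for
# ordinals, noon-shifted decimal hours for clock times), twin-first then
# cohort-mean imputation, and the join to the right-censored survival
# outcome.

#' Encode raw feature values to the numeric model scale
#'
#' Binary features map to 0/1 by their declared level order; ordinals map to
#' 0-based integer ranks respecting the declared ordering (label encoding);
#' clock times map to decimal hours on the noon-shifted 12-36 axis (07:30 ->
#' 31.5); continuous values pass through. Missing values stay NA.
#'
#' @param raw data.frame of raw values, one row per participant, columns a
#'   superset of `schema$name` (clock times as HH:MM strings)
#' @param schema a `feature_schema`
#' @return numeric matrix n x p with columns in schema order
#' @export
encode_features <- function(raw, schema) {
  n <- nrow(raw)
  x <- matrix(NA_real_, n, nrow(schema), dimnames = list(raw$participant_id, schema$name))
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    if (!nm %in% names(raw)) next
    v <- raw[[nm]]
    x[, i] <- switch(schema$kind[i],
      binary = ,
      categorical_ordinal = {
        v <- as.character(v)
        r <- match(v, schema$levels[[i]]) - 1
        if (any(!is.na(v) & is.na(r))) {
          rw_abort(sprintf("unknown level '%s' for feature '%s'",
                           v[which(!is.na(v) & is.na(r))[1]], nm), "rw_unknown_level")
        }
        r
      },
      clock_time = clock_to_axis(parse_hm(as.character(v))) / 60,
      numeric_continuous = as.numeric(v))
  }
  x
}

#' Impute missing feature values
#'
#' Two-stage policy: a feature with a declared subjective/objective twin is
#' first filled from the participant's own twin value (already on the same
#' encoded scale); remaining gaps are filled with the cohort mean of the
#' feature, rounded to the nearest valid rank for ordinals. A feature whose
#' pre-imputation missing fraction exceeds `missing_cap` is an error.
#'
#' @param x encoded numeric matrix from [encode_features()] (NAs = missing)
#' @param schema the `feature_schema` used to encode
#' @param missing_cap maximum tolerated per-feature missing fraction
#'   (default 0.25)
#' @return list with `x` (complete matrix), `mask` (logical matrix of
#'   pre-imputation missingness) and `log` (data.frame: participant_id,
#'   feature, method, value)
#' @export
impute_features <- function(x, schema, missing_cap = 0.25) {
  mask <- is.na(x)
  frac <- colMeans(mask)
  if (any(frac > missing_cap)) {
    rw_abort(sprintf("feature '%s' exceeds the %.0f%% missingness cap",
                     colnames(x)[which.max(frac)], 100 * missing_cap),
             "rw_too_much_missingness")
  }
  log <- list()
  ids <- rownames(x)
  for (i in seq_len(ncol(x))) {
    miss <- which(mask[, i])
    if (length(miss) == 0) next
    nm <- colnames(x)[i]
    si <- match(nm, schema$name)
    if (is.na(si)) rw_abort(sprintf("column '%s' not in schema", nm), "rw_schema_mismatch")
    tw <- schema$twin[si]
    if (!is.na(tw) && tw %in% colnames(x)) {
      fill <- !is.na(x[miss, tw])
      if (any(fill)) {
        rows <- miss[fill]
        x[rows, i] <- x[rows, tw]
        log[[length(log) + 1]] <- data.frame(
          participant_id = ids[rows], feature = nm, method = "twin",
          value = x[rows, i], stringsAsFactors = FALSE)
        miss <- miss[!fill]
      }
    }
    if (length(miss) > 0) {
      mu <- mean(x[, i], na.rm = TRUE)
      if (is.nan(mu)) rw_abort(sprintf("feature '%s' entirely missing", nm),
                               "rw_too_much_missingness")
      if (schema$kind[si] %in% c("binary", "categorical_ordinal")) {
        ranks <- seq_along(schema$levels[[si]]) - 1
        mu <- ranks[which.min(abs(ranks - mu))]
      }
      x[miss, i] <- mu
      log[[length(log) + 1]] <- data.frame(
        participant_id = ids[miss], feature = nm, method = "cohort_mean",
        value = rep(mu, length(miss)), stringsAsFactors = FALSE)
    }
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(participant_id = character(), feature = character(),
               method = character(), value = numeric(), stringsAsFactors = FALSE)
  list(x = x, mask = mask, log = log)
}

# circular mean of an HH:MM column, formatted back to HH:MM (NA-safe)
.mean_clock_col <- function(v) {
  m <- circular_mean_clock(parse_hm(v))
  if (is.na(m)) NA_character_ else format_hm(axis_to_clock(m))
}

# per-participant raw actigraphy/diary feature values from upstream outputs
.participant_raw_row <- function(id, metrics, nights, diary) {
  out <- list()
  m <- metrics[metrics$participant_id == id, , drop = FALSE]
  if (nrow(m) == 1) {
    out$i_less_o <- m$i_less_o_pct
    out$r24 <- m$r24
    out$mda <- m$mda
    out$wake_activity <- m$wake_activity
  }
  for (src in c("actigraphy", "diary")) {
    pre <- if (src == "actigraphy") "act_" else "diary_"
    nn <- nights[nights$participant_id == id & nights$source == src, , drop = FALSE]
    if (nrow(nn) >= 1) {
      agg <- tryCatch(aggregate_participant(nn, min_nights = 1),
                      restwatch_error = function(e) NULL)
      if (!is.null(agg)) {
        out[[paste0(pre, "bt")]] <- agg$bt
        out[[paste0(pre, "gut")]] <- agg$gut
        out[[paste0(pre, "tib")]] <- agg$tib_min
        out[[paste0(pre, "sol")]] <- agg$sol_min
        out[[paste0(pre, "tst")]] <- agg$tst_min
        out[[paste0(pre, "se")]] <- agg$se_pct
        out[[paste0(pre, "waso")]] <- agg$waso_min
        out[[paste0(pre, "na")]] <- agg$na
        if (src == "diary") out$diary_twak <- agg$twak_min
      }
    }
  }
  if (!is.null(diary)) {
    dd <- diary[diary$participant_id == id, , drop = FALSE]
    if (nrow(dd) >= 1) {
      out$diary_time_tried_sleep <- .mean_clock_col(dd$time_tried_sleep)
      out$diary_final_awakening <- .mean_clock_col(dd$final_awakening)
    }
  }
  out
}

#' Assemble the feature table
#'
#' Joins the clinical table with the per-participant rest-activity metrics
#' and sleep-night parameters, encodes everything against the schema,
#' applies twin-first then cohort-mean imputation, and attaches the survival
#' outcome. Deterministic given identical inputs.
#'
#' @param clinical `rw_clinical` data.frame (from [read_clinical_csv()] or the
#'   generator): raw predictor columns plus participant_id, survival_days,
#'   event
#' @param metrics per-participant rest-activity metrics
#'   (from [rest_activity_metrics()]); may be NULL if the schema needs none
#' @param nights per-night sleep parameter rows (from [sleep_nights()]);
#'   may be NULL
#' @param diary raw diary table (for the diary-only clock features); may be
#'   NULL
#' @param schema a `feature_schema` (default [default_feature_schema()])
#' @param missing_cap passed to [impute_features()]
#' @return object of class `feature_table`: list with ids, x (n x p complete
#'   matrix), time, event, mask, schema, imputation_log
#' @export
assemble_features <- function(clinical, metrics = NULL, nights = NULL,
                              diary = NULL, schema = default_feature_schema(),
                              missing_cap = 0.25) {
  ids <- clinical$participant_id
  if (length(ids) == 0) rw_abort("clinical table has no participants", "rw_schema_mismatch")
  raw <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  clin_cols <- intersect(schema$name[schema$source %in% c("clinical", "psqi", "derived")],
                         names(clinical))
  for (cc in clin_cols) raw[[cc]] <- clinical[[cc]]
  derived <- lapply(ids, .participant_raw_row, metrics = metrics,
                    nights = nights, diary = diary)
  derived_cols <- unique(unlist(lapply(derived, names)))
  for (cc in intersect(derived_cols, schema$name)) {
    chr <- schema$kind[match(cc, schema$name)] == "clock_time"
    raw[[cc]] <- vapply(derived, function(d) {
      v <- d[[cc]]
      if (is.null(v) || length(v) == 0 || is.na(v)) {
        if (chr) NA_character_ else NA_real_
      } else if (chr) as.character(v) else as.numeric(v)
    }, if (chr) NA_character_ else NA_real_)
  }
  x <- encode_features(raw, schema)
  imp <- impute_features(x, schema, missing_cap)
  structure(list(ids = ids, x = imp$x,
                 time = as.numeric(clinical$survival_days),
                 event = as.integer(clinical$event),
                 mask = imp$mask, schema = schema, imputation_log = imp$log),
            class = "feature_table")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @exportS3Method base::print
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d participants x %d predictors, %d events, %d imputed cells\n",
              nrow(x$x), ncol(x$x), sum(x$event), sum(x$mask)))
  invisible(x)
}

#' Write a feature table to a flat CSV (id, outcome, encoded predictors)
#' @param ft a `feature_table`
#' @param path output CSV path
#' @param log_path optional sidecar path for the imputation log
#' @return `path`, invisibly
#' @export
write_feature_csv <- function(ft, path, log_path = NULL) {
  df <- data.frame(participant_id = ft$ids, survival_days = ft$time,
                   event = ft$event, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(ft$x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(log_path)) utils::write.csv(ft$imputation_log, log_path, row.names = FALSE)
  invisible(path)
}

#' Read a flat feature CSV back into a `feature_table`
#' @param path CSV written by [write_feature_csv()]
#' @param schema the schema the table was encoded with
#' @return a `feature_table` (mask all-FALSE: the file is post-imputation)
#' @export
read_feature_csv <- function(path, schema = default_feature_schema()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(schema$name, names(df))
  if (length(miss) > 0) {
    rw_abort(paste("feature CSV lacks columns:", paste(miss, collapse = ", ")),
             "rw_schema_mismatch")
  }
  x <- as.matrix(df[, schema$name])
  rownames(x) <- df$participant_id
  structure(list(ids = df$participant_id, x = x, time = df$survival_days,
                 event = as.integer(df$event),
                 mask = matrix(FALSE, nrow(x), ncol(x), dimnames = dimnames(x)),
                 schema = schema,
                 imputation_log = data.frame()),
            class = "feature_table")
}
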
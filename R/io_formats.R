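# CSV dialects for the three study inputs (minute-epoch actigraphy, sleep
# diary, clinical table) plus the in-bed schedule, with strict validation.
# Readers never impute: missing values surface as NA and stay NA until
# feature assembly. All timestamps are naive local time (stored as UTC so no
# DST arithmetic ever applies).

.parse_ts <- function(x) {
  x <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M"))
  out
}

#' Construct a minute-epoch activity series
#'
#' An `epoch_series` holds one participant's wrist activity counts at a fixed
#' 60-second epoch. Timestamps are implied: epoch i occurs at
#' `start_time + (i-1) * 60` seconds, gap-free. Missing epochs (device off
#' wrist, download gap) are explicit `NA` counts — zero is a valid activity
#' count and is never used as a missing marker.
#'
#' @param participant_id single string
#' @param start_time POSIXct (or parseable string) of the first epoch
#' @param counts numeric vector of non-negative integer counts; NA = missing
#' @param epoch_seconds epoch length in seconds; only 60 is supported
#' @return an object of class `epoch_series`
#' @export
epoch_series <- function(participant_id, start_time, counts, epoch_seconds = 60L) {
  if (length(counts) < 1) rw_abort("counts must have length >= 1", "rw_empty_series")
  if (epoch_seconds != 60L) {
    rw_abort("only 60-second epochs are supported", "rw_malformed_epoch")
  }
  counts <- as.numeric(counts)
  obs <- counts[!is.na(counts)]
  if (any(obs < 0) || any(obs != floor(obs))) {
    rw_abort("activity counts must be non-negative integers", "rw_malformed_epoch")
  }
  if (is.character(start_time)) start_time <- .parse_ts(start_time)
  structure(list(participant_id = as.character(participant_id),
                 start_time = start_time,
                 counts = counts,
                 epoch_seconds = 60L),
            class = "epoch_series")
}

#' Epoch timestamps of a series
#' @param series an `epoch_series`
#' @return POSIXct vector, one per epoch
#' @export
epoch_times <- function(series) {
  series$start_time + (seq_along(series$counts) - 1L) * series$epoch_seconds
}

#' @exportS3Method base::print
print.epoch_series <- function(x, ...) {
  n <- length(x$counts)
  cat(sprintf("<epoch_series> %s: %d one-minute epochs from %s (%.1f days, %d missing)\n",
              x$participant_id, n, format(x$start_time, "%Y-%m-%d %H:%M"),
              n / 1440, sum(is.na(x$counts))))
  invisible(x)
}

#' Read a minute-epoch actigraphy CSV
#'
#' Expected dialect: columns `timestamp` (ISO-8601, local time) and `count`
#' (non-negative integer; empty or NA marks a missing epoch), optional third
#' column `off_wrist` (0/1). Device-export preamble lines can be skipped with
#' `header_skip`. Rows must be evenly spaced at 60 s; a gap is an error unless
#' `gap_fill = TRUE`, in which case explicit missing epochs are inserted.
#'
#' @param path CSV file path
#' @param participant_id id to attach to the series
#' @param gap_fill insert NA epochs into gaps that are whole multiples of 60 s
#' @param header_skip number of preamble lines to skip before the header
#' @param off_wrist_policy how to treat epochs flagged off-wrist:
#'   "missing" (count becomes NA, the default) or "keep"
#' @return an `epoch_series`
#' @export
read_epoch_csv <- function(path, participant_id, gap_fill = FALSE,
                           header_skip = 0L,
                           off_wrist_policy = c("missing", "keep")) {
  off_wrist_policy <- match.arg(off_wrist_policy)
  if (!file.exists(path)) rw_abort(paste("no such file:", path), "rw_io")
  df <- utils::read.csv(path, skip = header_skip, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("timestamp", "count")
  if (!all(need %in% names(df))) {
    rw_abort("epoch CSV must have columns 'timestamp' and 'count'", "rw_malformed_epoch")
  }
  if (nrow(df) == 0) rw_abort("epoch CSV has no data rows", "rw_empty_series")
  ts <- .parse_ts(df$timestamp)
  if (anyNA(ts)) rw_abort("unparseable timestamp in epoch CSV", "rw_malformed_epoch")
  cnt <- suppressWarnings(as.numeric(ifelse(df$count %in% c("", "NA"), NA, df$count)))
  bad <- !is.na(df$count) & !(df$count %in% c("", "NA")) & is.na(cnt)
  if (any(bad)) rw_abort("non-numeric activity count in epoch CSV", "rw_malformed_epoch")
  if ("off_wrist" %in% names(df) && off_wrist_policy == "missing") {
    cnt[df$off_wrist %in% c("1", "TRUE", "true")] <- NA
  }
  d <- as.numeric(diff(ts), units = "secs")
  if (any(d <= 0)) rw_abort("timestamps not strictly increasing", "rw_malformed_epoch")
  if (any(d != 60)) {
    if (!gap_fill || any(d %% 60 != 0)) {
      rw_abort("epochs not evenly spaced at 60 s (set gap_fill=TRUE for whole-minute gaps)",
               "rw_malformed_epoch")
    }
    n_total <- as.numeric(difftime(ts[length(ts)], ts[1], units = "secs")) / 60 + 1
    full <- rep(NA_real_, n_total)
    idx <- as.numeric(difftime(ts, ts[1], units = "secs")) / 60 + 1
    full[idx] <- cnt
    cnt <- full
  }
  epoch_series(participant_id, ts[1], cnt)
}

#' Write a minute-epoch series to CSV (the dialect `read_epoch_csv` reads)
#' @param series an `epoch_series`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_epoch_csv <- function(series, path) {
  df <- data.frame(
    timestamp = format(epoch_times(series), "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    count = ifelse(is.na(series$counts), "", format(series$counts, scientific = FALSE, trim = TRUE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.diary_cols <- c("participant_id", "night_index", "bed_time", "time_tried_sleep",
                 "sol_min", "waso_min", "n_awakenings", "final_awakening",
                 "get_up_time")

#' Read a sleep diary CSV
#'
#' One row per night: `participant_id, night_index, bed_time,
#' time_tried_sleep, sol_min, waso_min, n_awakenings, final_awakening,
#' get_up_time`. Clock times are HH:MM (24-h); durations are minutes. Empty
#' cells are preserved as NA (missing), never coerced to zero.
#'
#' @param path CSV file path
#' @return data.frame of diary nights (class `rw_diary`)
#' @export
read_diary_csv <- function(path) {
  if (!file.exists(path)) rw_abort(paste("no such file:", path), "rw_io")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        na.strings = c("", "NA"))
  if (!identical(names(df), .diary_cols)) {
    rw_abort(paste("diary CSV header must be:", paste(.diary_cols, collapse = ",")),
             "rw_schema_mismatch")
  }
  for (cc in c("bed_time", "time_tried_sleep", "final_awakening", "get_up_time")) {
    parse_hm(df[[cc]])  # validates; values kept as HH:MM strings
  }
  for (cc in c("sol_min", "waso_min", "n_awakenings")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (any(!is.na(df[[cc]]) & is.na(v))) {
      rw_abort(sprintf("non-numeric value in diary column '%s'", cc), "rw_schema_mismatch")
    }
    if (any(v < 0, na.rm = TRUE)) {
      rw_abort(sprintf("negative duration in diary column '%s'", cc), "rw_schema_mismatch")
    }
    df[[cc]] <- v
  }
  df$night_index <- as.integer(df$night_index)
  if (anyNA(df$night_index)) rw_abort("night_index must be integer", "rw_schema_mismatch")
  dup <- duplicated(df[c("participant_id", "night_index")])
  if (any(dup)) rw_abort("duplicate participant/night_index in diary", "rw_schema_mismatch")
  class(df) <- c("rw_diary", "data.frame")
  df
}

#' Write a sleep diary table to CSV
#' @param diary data.frame with the diary columns
#' @param path output path
#' @return `path`, invisibly
#' @export
write_diary_csv <- function(diary, path) {
  utils::write.csv(as.data.frame(diary)[, .diary_cols], path,
                   row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Construct an in-bed schedule
#'
#' One (in-bed start, out-of-bed end) interval per night, derived from the
#' sleep diary or actigraph event markers. Intervals must be chronological,
#' non-overlapping, and each shorter than 24 h.
#'
#' @param participant_id single string
#' @param in_bed_start POSIXct (or parseable strings) of in-bed times
#' @param out_of_bed_end POSIXct of the matching out-of-bed times
#' @return object of class `bed_schedule`
#' @export
bed_schedule <- function(participant_id, in_bed_start, out_of_bed_end) {
  if (is.character(in_bed_start)) in_bed_start <- .parse_ts(in_bed_start)
  if (is.character(out_of_bed_end)) out_of_bed_end <- .parse_ts(out_of_bed_end)
  if (length(in_bed_start) != length(out_of_bed_end)) {
    rw_abort("in_bed_start and out_of_bed_end lengths differ", "rw_schema_mismatch")
  }
  dur <- as.numeric(difftime(out_of_bed_end, in_bed_start, units = "hours"))
  if (any(dur <= 0 | dur >= 24)) {
    rw_abort("each in-bed interval must have duration in (0, 24) hours", "rw_schema_mismatch")
  }
  if (length(in_bed_start) > 1) {
    if (any(diff(as.numeric(in_bed_start)) <= 0) ||
        any(as.numeric(in_bed_start[-1]) < as.numeric(out_of_bed_end[-length(out_of_bed_end)]))) {
      rw_abort("in-bed intervals must be chronological and non-overlapping", "rw_schema_mismatch")
    }
  }
  structure(list(participant_id = as.character(participant_id),
                 in_bed_start = in_bed_start,
                 out_of_bed_end = out_of_bed_end),
            class = "bed_schedule")
}

#' Number of nights in a schedule
#' @param x a `bed_schedule`
#' @param ... unused
#' @export
length.bed_schedule <- function(x) length(x$in_bed_start)

#' Read an in-bed schedule CSV (columns participant_id,in_bed_start,out_of_bed_end)
#' @param path CSV path
#' @param participant_id optional filter; default uses the file's single id
#' @return a `bed_schedule`
#' @export
read_schedule_csv <- function(path, participant_id = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("participant_id", "in_bed_start", "out_of_bed_end")
  if (!all(need %in% names(df))) {
    rw_abort("schedule CSV needs columns participant_id,in_bed_start,out_of_bed_end",
             "rw_schema_mismatch")
  }
  if (!is.null(participant_id)) df <- df[df$participant_id == participant_id, ]
  ids <- unique(df$participant_id)
  if (length(ids) != 1) rw_abort("schedule CSV must resolve to a single participant", "rw_schema_mismatch")
  bed_schedule(ids, df$in_bed_start, df$out_of_bed_end)
}

#' Write a schedule to CSV
#' @param schedule a `bed_schedule`
#' @param path output path
#' @param append append to an existing file (for multi-participant files)
#' @return `path`, invisibly
#' @export
write_schedule_csv <- function(schedule, path, append = FALSE) {
  df <- data.frame(participant_id = schedule$participant_id,
                   in_bed_start = format(schedule$in_bed_start, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                   out_of_bed_end = format(schedule$out_of_bed_end, "%Y-%m-%d %H:%M:%S", tz = "UTC"))
  if (append && file.exists(path)) {
    utils::write.table(df, path, row.names = FALSE, col.names = FALSE,
                       sep = ",", quote = FALSE, append = TRUE)
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read the clinical table CSV against a feature schema
#'
#' The schema (see [feature_schema()]) declares each predictor column's kind
#' (binary, categorical_ordinal, numeric_continuous, clock_time). The file
#' must carry `participant_id`, `survival_days`, `event`, and any subset of
#' the schema's clinical-source columns; unknown columns are rejected unless
#' listed in `ignore`.
#'
#' @param path CSV file path
#' @param schema a `feature_schema`
#' @param ignore character vector of column names to silently ignore
#' @return data.frame (class `rw_clinical`) with typed columns; ordinals and
#'   binaries are kept as their raw labels, validated against the schema
#' @export
read_clinical_csv <- function(path, schema, ignore = character()) {
  if (!file.exists(path)) rw_abort(paste("no such file:", path), "rw_io")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                        na.strings = c("", "NA"))
  need <- c("participant_id", "survival_days", "event")
  if (!all(need %in% names(df))) {
    rw_abort("clinical CSV needs participant_id, survival_days, event", "rw_schema_mismatch")
  }
  known <- c(need, schema$name, ignore)
  extra <- setdiff(names(df), known)
  if (length(extra) > 0) {
    rw_abort(paste("unknown clinical columns:", paste(extra, collapse = ", ")),
             "rw_schema_mismatch")
  }
  df <- df[, setdiff(names(df), ignore), drop = FALSE]
  df$survival_days <- as.numeric(df$survival_days)
  if (any(is.na(df$survival_days)) || any(df$survival_days < 0)) {
    rw_abort("survival_days must be non-negative numbers", "rw_schema_mismatch")
  }
  ev <- as.numeric(df$event)
  if (any(is.na(ev)) || !all(ev %in% c(0, 1))) {
    rw_abort("event flag must be 0 or 1", "rw_schema_mismatch")
  }
  df$event <- as.integer(ev)
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    if (!nm %in% names(df)) next
    kind <- schema$kind[i]
    v <- df[[nm]]
    if (kind %in% c("numeric_continuous")) {
      num <- suppressWarnings(as.numeric(v))
      if (any(!is.na(v) & is.na(num))) {
        rw_abort(sprintf("non-numeric value in continuous column '%s'", nm), "rw_schema_mismatch")
      }
      df[[nm]] <- num
    } else if (kind == "clock_time") {
      parse_hm(v)  # validation only; raw HH:MM retained
    } else {
      lev <- schema$levels[[i]]
      bad <- !is.na(v) & !(v %in% lev)
      if (any(bad)) {
        rw_abort(sprintf("unknown level '%s' for %s column '%s'",
                         v[which(bad)[1]], kind, nm), "rw_unknown_level")
      }
    }
  }
  class(df) <- c("rw_clinical", "data.frame")
  df
}
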
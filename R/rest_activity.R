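# Rest-activity rhythm metrics from minute-epoch actigraphy: the dichotomy
# index I<O (full window and the 20-h restricted variant), the 24-h lag
# autocorrelation r24, mean daily activity, and mean activity during daytime
# wakefulness, plus the analysis-set qualification rules.

# logical mask, one element per epoch, TRUE while in bed ([start, end))
.in_bed_mask <- function(series, schedule) {
  tt <- as.numeric(epoch_times(series))
  mask <- rep(FALSE, length(tt))
  for (i in seq_along(schedule$in_bed_start)) {
    mask <- mask | (tt >= as.numeric(schedule$in_bed_start[i]) &
                    tt < as.numeric(schedule$out_of_bed_end[i]))
  }
  mask
}

# epochs within `margin_min` minutes of any in-bed boundary (both sides)
.boundary_mask <- function(series, schedule, margin_min = 60) {
  tt <- as.numeric(epoch_times(series))
  m <- margin_min * 60
  mask <- rep(FALSE, length(tt))
  for (b in c(as.numeric(schedule$in_bed_start), as.numeric(schedule$out_of_bed_end))) {
    mask <- mask | (tt >= b - m & tt < b + m)
  }
  mask
}

#' Dichotomy index I<O
#'
#' Percentage of in-bed activity counts strictly inferior to the median of
#' the out-of-bed activity counts, pooled over the whole recording. Values
#' of 97.5% or below indicate a disrupted rest-activity rhythm. With
#' `restriction = "20h"` the hour on either side of every in-bed boundary
#' (going to bed and getting up) is excluded from both pools before the
#' computation, removing transition epochs.
#'
#' @param series an `epoch_series`
#' @param schedule a `bed_schedule` for the same participant
#' @param restriction "none" (24-h data) or "20h" (transition hours excluded)
#' @param strict count in-bed epochs strictly below the out-of-bed median
#'   (default). `FALSE` counts epochs `<=` the median, for sensitivity
#'   analysis of the inequality convention.
#' @return I<O as a percentage in [0, 100]
#' @export
dichotomy_index <- function(series, schedule, restriction = c("none", "20h"),
                            strict = TRUE) {
  restriction <- match.arg(restriction)
  in_bed <- .in_bed_mask(series, schedule)
  keep <- rep(TRUE, length(series$counts))
  if (restriction == "20h") keep <- !.boundary_mask(series, schedule, 60)
  cin <- series$counts[in_bed & keep]
  cout <- series$counts[!in_bed & keep]
  cin <- cin[!is.na(cin)]
  cout <- cout[!is.na(cout)]
  if (length(series$counts[in_bed]) == 0) {
    rw_abort("schedule places no epochs in bed", "rw_no_in_bed_epochs")
  }
  if (length(cin) == 0 || length(cout) == 0) {
    rw_abort("no non-missing epochs in one of the I<O pools", "rw_all_missing")
  }
  med <- stats::median(cout)
  below <- if (strict) sum(cin < med) else sum(cin <= med)
  100 * below / length(cin)
}

#' Per-night dichotomy index
#'
#' I<O computed night by night for stability analysis (e.g. day-to-day ICC):
#' for night i the in-bed pool is that night's interval and the out-of-bed
#' pool is the waking span leading up to it (from the previous out-of-bed
#' time, or the recording start, to that night's bed time).
#'
#' @inheritParams dichotomy_index
#' @return numeric vector, one I<O percentage per night (NA where a night has
#'   no usable epochs)
#' @export
dichotomy_index_by_night <- function(series, schedule, strict = TRUE) {
  tt <- as.numeric(epoch_times(series))
  n_nights <- length(schedule$in_bed_start)
  out <- rep(NA_real_, n_nights)
  for (i in seq_len(n_nights)) {
    s <- as.numeric(schedule$in_bed_start[i])
    e <- as.numeric(schedule$out_of_bed_end[i])
    day_start <- if (i == 1) tt[1] else as.numeric(schedule$out_of_bed_end[i - 1])
    cin <- series$counts[tt >= s & tt < e]
    cout <- series$counts[tt >= day_start & tt < s]
    cin <- cin[!is.na(cin)]
    cout <- cout[!is.na(cout)]
    if (length(cin) == 0 || length(cout) == 0) next
    med <- stats::median(cout)
    below <- if (strict) sum(cin < med) else sum(cin <= med)
    out[i] <- 100 * below / length(cin)
  }
  out
}

#' 24-hour autocorrelation (r24)
#'
#' Pearson product-moment correlation between the minute-epoch count series
#' and itself shifted by 1440 epochs (24 h), over pairwise non-missing
#' epochs. Measures day-to-day regularity of the activity pattern: near 1
#' for a perfectly repeating profile, near 0 for structureless activity.
#'
#' @param series an `epoch_series` spanning at least 48 h
#' @return correlation in [-1, 1]
#' @export
r24_autocorrelation <- function(series) {
  n <- length(series$counts)
  lag <- 1440L
  if (n < 2 * lag) {
    rw_abort("r24 needs at least 48 h of minute epochs", "rw_series_too_short")
  }
  x <- series$counts[1:(n - lag)]
  y <- series$counts[(lag + 1):n]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) rw_abort("too few paired non-missing epochs at lag 1440", "rw_series_too_short")
  stats::cor(x[ok], y[ok])
}

#' Mean daily activity (MDA)
#'
#' Average number of wrist movements per minute over the full recording,
#' missing epochs excluded.
#'
#' @param series an `epoch_series`
#' @return mean counts/min
#' @export
mean_daily_activity <- function(series) {
  x <- series$counts[!is.na(series$counts)]
  if (length(x) == 0) rw_abort("all epochs missing", "rw_all_missing")
  mean(x)
}

#' Mean activity during daytime wakefulness
#'
#' Mean activity count over the epochs that fall between consecutive major
#' sleep periods (after one night's out-of-bed time and before the next
#' night's bed time), pooled across all such spans.
#'
#' @param series an `epoch_series`
#' @param schedule a `bed_schedule` with at least two nights
#' @return mean counts/min over the between-sleep spans
#' @export
mean_wake_activity <- function(series, schedule) {
  n_nights <- length(schedule$in_bed_start)
  if (n_nights < 2) rw_abort("need >= 2 in-bed intervals for a wake span", "rw_no_wake_span")
  tt <- as.numeric(epoch_times(series))
  vals <- numeric(0)
  for (i in seq_len(n_nights - 1)) {
    span <- tt >= as.numeric(schedule$out_of_bed_end[i]) &
            tt < as.numeric(schedule$in_bed_start[i + 1])
    vals <- c(vals, series$counts[span])
  }
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) rw_abort("no non-missing epochs between sleep periods", "rw_no_wake_span")
  mean(vals)
}

#' Valid 24-hour periods of a recording
#'
#' Splits the recording into consecutive 24-h blocks from the first epoch and
#' marks each block valid when at least `valid_frac` of its 1440 epochs are
#' non-missing (a trailing partial block is never valid).
#'
#' @param series an `epoch_series`
#' @param valid_frac minimum non-missing fraction for a valid day (default 0.9)
#' @return logical vector, one element per complete 24-h block
#' @export
valid_days <- function(series, valid_frac = 0.9) {
  n <- length(series$counts)
  n_days <- n %/% 1440
  if (n_days == 0) return(logical(0))
  vapply(seq_len(n_days), function(d) {
    blk <- series$counts[((d - 1) * 1440 + 1):(d * 1440)]
    mean(!is.na(blk)) >= valid_frac
  }, TRUE)
}

.longest_run <- function(x) {
  if (length(x) == 0 || !any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Analysis-set qualification
#'
#' Applies the study's analysis-set rules: "per protocol" requires eight
#' consecutive valid 24-h actigraphy periods with the corresponding sleep
#' diary; "full analysis" requires at least three consecutive valid 24-h
#' periods with corresponding diary nights; anything less is excluded.
#'
#' @param series an `epoch_series`
#' @param schedule a `bed_schedule` (used for night count)
#' @param diary diary data.frame for this participant (or NULL)
#' @param valid_frac see [valid_days()]
#' @return one of "per_protocol", "full_analysis", "excluded"
#' @export
qualify_analysis_set <- function(series, schedule, diary = NULL, valid_frac = 0.9) {
  run <- .longest_run(valid_days(series, valid_frac))
  n_diary <- if (is.null(diary)) 0L else sum(!is.na(diary$bed_time) & !is.na(diary$get_up_time))
  if (run >= 8 && n_diary >= 8) return("per_protocol")
  if (run >= 3 && n_diary >= 3) return("full_analysis")
  "excluded"
}

#' TRUE for nights whose bed time falls on a weekend (Sat/Sun civil calendar)
#' @param schedule a `bed_schedule`
#' @return logical vector, one per night
#' @export
night_is_weekend <- function(schedule) {
  format(schedule$in_bed_start, "%u") %in% c("6", "7")
}

#' All rest-activity metrics for one participant
#'
#' Convenience wrapper computing I<O (full and 20-h restricted), r24, mean
#' daily activity, mean wake activity, the number of valid 24-h periods and
#' the analysis-set label. Metrics are only emitted for participants with at
#' least three consecutive valid days (the full-analysis rule); excluded
#' participants get NA metrics with the label.
#'
#' @inheritParams qualify_analysis_set
#' @return one-row data.frame
#' @export
rest_activity_metrics <- function(series, schedule, diary = NULL, valid_frac = 0.9) {
  set <- qualify_analysis_set(series, schedule, diary, valid_frac)
  nvd <- sum(valid_days(series, valid_frac))
  row <- data.frame(participant_id = series$participant_id,
                    i_less_o_pct = NA_real_, i_less_o_20h = NA_real_,
                    r24 = NA_real_, mda = NA_real_, wake_activity = NA_real_,
                    n_valid_days = nvd, analysis_set = set,
                    stringsAsFactors = FALSE)
  if (set == "excluded") return(row)
  row$i_less_o_pct <- dichotomy_index(series, schedule)
  row$i_less_o_20h <- dichotomy_index(series, schedule, restriction = "20h")
  row$r24 <- tryCatch(r24_autocorrelation(series), restwatch_error = function(e) NA_real_)
  row$mda <- mean_daily_activity(series)
  row$wake_activity <- tryCatch(mean_wake_activity(series, schedule),
                                restwatch_error = function(e) NA_real_)
  row
}
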
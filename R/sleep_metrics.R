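# Sleep/wake scoring of minute epochs (Actiware-style weighted window),
# per-night sleep parameters from the scored labels, and the diary-arithmetic
# parameters. Per-night rows share one layout whether actigraphy- or
# diary-derived (`source` column), so the two can be compared and can act as
# each other's imputation twins downstream.

#' Score epochs as sleep or wake (weighted 5-epoch window)
#'
#' Each one-minute epoch is scored with the published Actiwatch weighting
#' W = 0.04*(c[-2] + c[+2]) + 0.2*(c[-1] + c[+1]) + c[0] and labelled sleep
#' when W does not exceed the sensitivity threshold (medium = 40; low = 80,
#' high = 20 selectable). Neighbours outside the recording, and missing
#' neighbours, contribute 0.
#'
#' @param series an `epoch_series`
#' @param interval length-2 POSIXct (or parseable strings): in-bed start/end;
#'   must lie within the recording
#' @param sensitivity wake threshold on W (default 40)
#' @return character vector of "sleep"/"wake", one per epoch in
#'   `[interval[1], interval[2])`
#' @export
score_epochs <- function(series, interval, sensitivity = 40) {
  if (is.character(interval)) interval <- .parse_ts(interval)
  tt <- epoch_times(series)
  if (interval[1] < tt[1] || interval[2] > tt[length(tt)] + 60) {
    rw_abort("scoring interval extends outside the recording", "rw_interval_outside_series")
  }
  c0 <- ifelse(is.na(series$counts), 0, series$counts)
  shift <- function(x, k) {
    n <- length(x)
    if (k > 0) c(rep(0, k), x[1:(n - k)]) else c(x[(1 - k):n], rep(0, -k))
  }
  # weights are 1/25, 5/25, 25/25: scale by 25 so integer counts compare
  # exactly at the threshold (W == sensitivity scores sleep, by definition)
  w25 <- 25 * c0 + 5 * (shift(c0, 1) + shift(c0, -1)) +
    (shift(c0, 2) + shift(c0, -2))
  sel <- as.numeric(tt) >= as.numeric(interval[1]) & as.numeric(tt) < as.numeric(interval[2])
  ifelse(w25[sel] <= 25 * sensitivity, "sleep", "wake")
}

#' Per-night sleep parameters from scored labels
#'
#' Sleep onset is the start of the first run of at least `onset_run`
#' consecutive sleep-scored minutes; the final awakening is the end of the
#' last such run. Within the onset-to-final-awakening window: TST is the
#' number of sleep minutes, WASO the number of wake minutes, and NA the
#' number of contiguous wake blocks. SOL is the latency from in-bed start to
#' onset; TIB is the interval length; SE = 100 * TST / TIB.
#'
#' @param labels character vector of "sleep"/"wake" from [score_epochs()]
#' @param onset_run minimum run of sleep minutes defining onset (default 10)
#' @return list with tib_min, sol_min, tst_min, se_pct, waso_min, na
#' @export
actigraphy_night_params <- function(labels, onset_run = 10) {
  tib <- length(labels)
  r <- rle(labels == "sleep")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  qual <- which(r$values & r$lengths >= onset_run)
  if (length(qual) == 0) rw_abort("no qualifying sleep onset run", "rw_no_sleep_detected")
  onset <- starts[qual[1]]
  final_end <- ends[qual[length(qual)]]
  win <- labels[onset:final_end]
  tst <- sum(win == "sleep")
  waso <- sum(win == "wake")
  na_ep <- {
    rw <- rle(win == "wake")
    sum(rw$values)
  }
  list(tib_min = tib, sol_min = onset - 1L, tst_min = tst,
       se_pct = 100 * tst / tib, waso_min = waso, na = na_ep)
}

#' Actigraphy sleep parameters for one night
#'
#' Scores the in-bed interval and extracts the night's parameters, with bed
#' time and get-up time taken from the schedule interval.
#'
#' @param series an `epoch_series`
#' @param schedule a `bed_schedule`
#' @param night which night (index into the schedule)
#' @param sensitivity threshold passed to [score_epochs()]
#' @param onset_run passed to [actigraphy_night_params()]
#' @return one-row data.frame in the shared sleep-night layout
#' @export
actigraphy_sleep_night <- function(series, schedule, night, sensitivity = 40,
                                   onset_run = 10) {
  s <- schedule$in_bed_start[night]
  e <- schedule$out_of_bed_end[night]
  labels <- score_epochs(series, c(s, e), sensitivity)
  p <- actigraphy_night_params(labels, onset_run)
  data.frame(participant_id = series$participant_id, night_index = night,
             source = "actigraphy",
             bt = format(s, "%H:%M", tz = "UTC"), gut = format(e, "%H:%M", tz = "UTC"),
             tib_min = p$tib_min, sol_min = p$sol_min, tst_min = p$tst_min,
             se_pct = p$se_pct, waso_min = p$waso_min, na = p$na,
             twak_min = NA_real_, flagged = FALSE, stringsAsFactors = FALSE)
}

#' Diary sleep parameters for one night
#'
#' Implements the diary arithmetic: TIB = GUT - BT (midnight-wrap aware),
#' TWAK = GUT - time of final awakening, TST = TIB - (SOL + WASO + TWAK),
#' SE = 100 * TST / TIB. A night whose reported wake components exceed TIB
#' gets TST/SE set missing and `flagged = TRUE` rather than a negative TST.
#'
#' @param d one diary night: a list or one-row data.frame with fields
#'   participant_id, night_index, bed_time, time_tried_sleep, sol_min,
#'   waso_min, n_awakenings, final_awakening, get_up_time
#' @return one-row data.frame in the shared sleep-night layout
#' @export
diary_night_params <- function(d) {
  bt_ax <- clock_to_axis(parse_hm(d$bed_time))
  gut_ax <- clock_to_axis(parse_hm(d$get_up_time))
  fa_ax <- clock_to_axis(parse_hm(d$final_awakening))
  if (is.na(bt_ax) || is.na(gut_ax)) {
    rw_abort("diary night needs parseable bed and get-up times", "rw_inconsistent_times")
  }
  if (gut_ax <= bt_ax) gut_ax <- gut_ax + 1440
  if (!is.na(fa_ax) && fa_ax < bt_ax) fa_ax <- fa_ax + 1440
  tib <- gut_ax - bt_ax
  if (tib <= 0) rw_abort("get-up time must follow bed time", "rw_inconsistent_times")
  twak <- if (is.na(fa_ax)) NA_real_ else gut_ax - fa_ax
  if (!is.na(twak) && twak < 0) {
    rw_abort("final awakening after get-up time", "rw_inconsistent_times")
  }
  sol <- as.numeric(d$sol_min)
  waso <- as.numeric(d$waso_min)
  flagged <- FALSE
  tst <- se <- NA_real_
  if (!anyNA(c(sol, waso, twak))) {
    tst <- tib - (sol + waso + twak)
    if (tst < 0) {
      flagged <- TRUE
      tst <- NA_real_
    } else {
      se <- 100 * tst / tib
    }
  }
  data.frame(participant_id = as.character(d$participant_id),
             night_index = as.integer(d$night_index), source = "diary",
             bt = as.character(d$bed_time), gut = as.character(d$get_up_time),
             tib_min = tib, sol_min = sol, tst_min = tst, se_pct = se,
             waso_min = waso, na = as.numeric(d$n_awakenings), twak_min = twak,
             flagged = flagged, stringsAsFactors = FALSE)
}

#' Per-participant aggregation of sleep nights
#'
#' Arithmetic mean of each numeric parameter over the available nights
#' (missing values dropped per field); bed and get-up clock times are
#' averaged circularly so e.g. 23:30 and 00:30 average to 00:00. Requires at
#' least `min_nights` nights (the full-analysis diary rule).
#'
#' @param nights data.frame of sleep-night rows (one source)
#' @param min_nights minimum nights required (default 3)
#' @return one-row data.frame with mean parameters; clock means are reported
#'   both as HH:MM (`bt`, `gut`) and as decimal hours on the noon-shifted
#'   axis (`bt_axis_h`, `gut_axis_h`)
#' @export
aggregate_participant <- function(nights, min_nights = 3) {
  if (nrow(nights) < min_nights) {
    rw_abort(sprintf("need >= %d nights to aggregate", min_nights), "rw_too_few_nights")
  }
  num <- c("tib_min", "sol_min", "tst_min", "se_pct", "waso_min", "na", "twak_min")
  means <- vapply(num, function(cc) {
    v <- nights[[cc]]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
  bt_ax <- circular_mean_clock(parse_hm(nights$bt))
  gut_ax <- circular_mean_clock(parse_hm(nights$gut))
  out <- data.frame(participant_id = nights$participant_id[1],
                    source = nights$source[1], n_nights = nrow(nights),
                    bt = format_hm(axis_to_clock(bt_ax)),
                    gut = format_hm(axis_to_clock(gut_ax)),
                    bt_axis_h = bt_ax / 60, gut_axis_h = gut_ax / 60,
                    stringsAsFactors = FALSE)
  for (cc in num) out[[cc]] <- means[[cc]]
  out
}

#' All sleep-night rows for one participant (both sources)
#'
#' @param series an `epoch_series`
#' @param schedule a `bed_schedule`
#' @param diary diary rows for this participant (may be NULL)
#' @param sensitivity,onset_run scoring settings
#' @return data.frame of per-night rows, actigraphy then diary
#' @export
sleep_nights <- function(series, schedule, diary = NULL, sensitivity = 40,
                         onset_run = 10) {
  rows <- list()
  for (i in seq_along(schedule$in_bed_start)) {
    rows[[length(rows) + 1]] <- tryCatch(
      actigraphy_sleep_night(series, schedule, i, sensitivity, onset_run),
      restwatch_error = function(e) NULL)
  }
  if (!is.null(diary)) {
    for (i in seq_len(nrow(diary))) {
      rows[[length(rows) + 1]] <- tryCatch(
        diary_night_params(diary[i, ]),
        restwatch_error = function(e) NULL)
    }
  }
  do.call(rbind, rows)
}
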
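# Clock-time helpers.
#
# Bedtimes straddle midnight, so naive HH:MM arithmetic is discontinuous at
# 00:00. All internal clock arithmetic therefore lives on a shifted axis in
# minutes: times from 12:00 onwards keep their value, times before noon get
# +24 h, giving a continuous [720, 2160) range (12:00 -> 36:00 in hours). A
# typical night (bed 23:00, rise 07:30) maps to 1380 -> 1890 and orders
# correctly.

#' Parse an HH:MM clock string to minutes since midnight
#'
#' @param x character vector of "HH:MM" times (24-h format)
#' @return numeric vector of minutes in [0, 1440); NA elements stay NA
#' @export
parse_hm <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x) & grepl("^\\s*([01]?[0-9]|2[0-3]):[0-5][0-9]\\s*$", x)
  if (any(!ok & !is.na(x))) {
    rw_abort(sprintf("unparseable clock time: '%s'", x[which(!ok & !is.na(x))[1]]),
             "rw_unparseable_time")
  }
  parts <- strsplit(trimws(x[ok]), ":", fixed = TRUE)
  out[ok] <- vapply(parts, function(p) as.numeric(p[1]) * 60 + as.numeric(p[2]), 0)
  out
}

#' Format minutes since midnight as HH:MM
#'
#' @param m numeric vector of minutes; values outside [0,1440) are wrapped
#' @return character vector
#' @export
format_hm <- function(m) {
  m <- round(m) %% 1440
  sprintf("%02d:%02d", m %/% 60, m %% 60)
}

#' Map minutes-since-midnight onto the noon-shifted axis
#'
#' Times in [12:00, 24:00) keep their value; times in [00:00, 12:00) are
#' shifted by +24 h, so the axis is continuous across midnight.
#'
#' @param m minutes since midnight in [0, 1440)
#' @return minutes on the shifted axis in [720, 2160)
#' @export
clock_to_axis <- function(m) {
  ((m - 720) %% 1440) + 720
}

#' Map shifted-axis minutes back to minutes since midnight
#' @param a axis minutes
#' @return minutes in [0, 1440)
#' @export
axis_to_clock <- function(a) {
  a %% 1440
}

#' Circular mean of clock times
#'
#' Averages clock times on the circle so that 23:30 and 00:30 average to
#' 00:00, not 12:00. The result is reported on the noon-shifted axis.
#'
#' @param m minutes since midnight (or axis minutes; both wrap identically)
#' @param na.rm drop missing values
#' @return mean time as minutes on the shifted axis, or NA if no data
#' @export
circular_mean_clock <- function(m, na.rm = TRUE) {
  if (na.rm) m <- m[!is.na(m)]
  if (length(m) == 0) return(NA_real_)
  theta <- 2 * pi * m / 1440
  ang <- atan2(mean(sin(theta)), mean(cos(theta)))
  clock_to_axis((ang * 1440 / (2 * pi)) %% 1440)
}
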
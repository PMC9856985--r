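# Univariate machinery: Kaplan-Meier estimation, log-rank tests, split
# rules (median / quartiles / normative cut-offs), Spearman correlations
# with the interpretation bands, and ICC stability of the per-day dichotomy
# index.

#' Kaplan-Meier product-limit estimate
#'
#' @param time survival/censoring times
#' @param event 0/1 event flags
#' @return list: `step`, a data.frame of (time, surv) starting at (0, 1) and
#'   non-increasing; `fit`, the underlying `survfit` object
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1) rw_abort("need at least one observation", "rw_schema_mismatch")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  step <- data.frame(time = c(0, fit$time), surv = c(1, fit$surv))
  list(step = step, fit = fit)
}

#' Survival probability past a time point from a KM estimate
#' @param km result of [km_estimate()]
#' @param t time point(s)
#' @return estimated S(t)
#' @export
km_survival_at <- function(km, t) {
  vapply(t, function(tt) {
    s <- km$step$surv[km$step$time <= tt]
    if (length(s) == 0) 1 else s[length(s)]
  }, 0)
}

#' Log-rank test comparing survival between groups
#'
#' Standard chi-square log-rank test with the hypergeometric variance and
#' g - 1 degrees of freedom; no continuity correction.
#'
#' @param time survival/censoring times
#' @param event 0/1 event flags
#' @param group group labels (2 or more non-empty groups)
#' @return list with statistic, df, p
#' @export
log_rank <- function(time, event, group) {
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2) rw_abort("need >= 2 non-empty groups", "rw_degenerate_split")
  if (sum(event) < 1) rw_abort("no events", "rw_no_events")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Form groups by a split rule and run the log-rank test
#'
#' Rules: "median" splits at the group median (values equal to the median go
#' to the low group); "quartiles" forms four groups by rank (ties broken by
#' rank order, so group sizes are as equal as possible); "cutoff" dichotomises
#' at a stated normative boundary with its printed inclusivity, e.g. TST
#' >= 390 min, SOL <= 30 min, SE >= 85%, WASO > 30 min.
#'
#' @param time survival/censoring times
#' @param event 0/1 event flags
#' @param value the grouping variable
#' @param rule "median", "quartiles" or "cutoff"
#' @param cutoff boundary value (rule = "cutoff")
#' @param op comparison defining the "meets" group: one of ">=", "<=", ">",
#'   "<" (rule = "cutoff")
#' @return list: group factor, statistic, df, p
#' @export
split_and_test <- function(time, event, value, rule = c("median", "quartiles", "cutoff"),
                           cutoff = NULL, op = c(">=", "<=", ">", "<")) {
  rule <- match.arg(rule)
  if (anyNA(value)) rw_abort("grouping values must be present", "rw_schema_mismatch")
  group <- switch(rule,
    median = {
      med <- stats::median(value)
      factor(ifelse(value <= med, "low", "high"), levels = c("low", "high"))
    },
    quartiles = {
      r <- rank(value, ties.method = "first")
      factor(paste0("Q", ceiling(4 * r / length(r))), levels = paste0("Q", 1:4))
    },
    cutoff = {
      op <- match.arg(op)
      if (is.null(cutoff)) rw_abort("cutoff rule needs a boundary value", "rw_schema_mismatch")
      meets <- do.call(op, list(value, cutoff))
      factor(ifelse(meets, "meets", "fails"), levels = c("fails", "meets"))
    })
  group <- droplevels(group)
  if (nlevels(group) < 2) rw_abort("split produced a single group", "rw_degenerate_split")
  c(list(group = group), log_rank(time, event, group))
}

#' The normative sleep-parameter split battery
#'
#' The default set of dichotomising cut-offs for the actigraphy sleep
#' parameters: TST at 6.5 h (>= 390 min), SOL at <= 30 min, SE at >= 85%,
#' WASO at > 30 min, plus median splits for TIB and NA.
#'
#' @return data.frame with variable, rule, cutoff, op
#' @export
normative_sleep_battery <- function() {
  data.frame(
    variable = c("i_less_o", "i_less_o", "r24", "r24", "act_tib", "act_tst",
                 "act_sol", "act_se", "act_waso", "act_na"),
    rule = c("median", "quartiles", "median", "quartiles", "median", "cutoff",
             "cutoff", "cutoff", "cutoff", "median"),
    cutoff = c(NA, NA, NA, NA, NA, 390, 30, 85, 30, NA),
    op = c(NA, NA, NA, NA, NA, ">=", "<=", ">=", ">", NA),
    stringsAsFactors = FALSE)
}

#' Run a battery of split-and-test analyses over a feature table
#'
#' @param ft a `feature_table`
#' @param battery data.frame as returned by [normative_sleep_battery()]
#' @return data.frame with one row per split: variable, rule, statistic, p
#'   (NA where a split was degenerate)
#' @export
run_split_battery <- function(ft, battery = normative_sleep_battery()) {
  rows <- lapply(seq_len(nrow(battery)), function(i) {
    b <- battery[i, ]
    res <- tryCatch(
      split_and_test(ft$time, ft$event, ft$x[, b$variable], rule = b$rule,
                     cutoff = if (is.na(b$cutoff)) NULL else b$cutoff,
                     op = if (is.na(b$op)) ">=" else b$op),
      restwatch_error = function(e) NULL)
    data.frame(variable = b$variable, rule = b$rule,
               statistic = if (is.null(res)) NA_real_ else res$statistic,
               p = if (is.null(res)) NA_real_ else res$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spearman correlation with interpretation band
#'
#' Tie-corrected Spearman rank correlation, with the magnitude classified
#' into the conventional bands: |r| < 0.3 negligible, < 0.5 low, < 0.7
#' moderate, < 0.9 high, and 0.9 and above very high (boundary values fall
#' in the upper band). The sign is reported separately from the band.
#'
#' @param x,y numeric vectors (n >= 3, finite)
#' @return list: r, band, sign ("positive"/"negative"/"zero"), p
#' @export
spearman_band <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y)) {
    rw_abort("need >= 3 paired values", "rw_schema_mismatch")
  }
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    rw_abort("values must be finite", "rw_schema_mismatch")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rw_abort("zero variance input", "rw_zero_variance")
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  r <- unname(ct$estimate)
  list(r = r, band = correlation_band(r),
       sign = if (r > 0) "positive" else if (r < 0) "negative" else "zero",
       p = ct$p.value)
}

#' Interpretation band for a correlation magnitude
#'
#' Pure function of |r|: [0, 0.3) negligible, [0.3, 0.5) low, [0.5, 0.7)
#' moderate, [0.7, 0.9) high, [0.9, 1] very high.
#'
#' @param r correlation in [-1, 1]
#' @return band label
#' @export
correlation_band <- function(r) {
  a <- abs(r)
  if (a > 1 + 1e-12) rw_abort("correlation outside [-1, 1]", "rw_schema_mismatch")
  if (a < 0.3) "negligible" else if (a < 0.5) "low" else
    if (a < 0.7) "moderate" else if (a < 0.9) "high" else "very high"
}

#' Intraclass correlation for day-to-day stability
#'
#' Two-way single-measure consistency ICC (ICC(3,1): days treated as fixed
#' "raters", subjects random) from the ANOVA mean squares, with the
#' F-distribution 95% confidence interval and the F test against ICC = 0.
#' ICC(2,1) (absolute agreement, days random) is available as a point
#' estimate.
#'
#' @param mat complete numeric matrix, subjects in rows, days in columns
#' @param type "ICC3" (default) or "ICC2"
#' @param conf confidence level (default 0.95)
#' @return list: icc, ci (length-2, NA for ICC2), p, ms (mean squares)
#' @export
icc_stability <- function(mat, type = c("ICC3", "ICC2"), conf = 0.95) {
  type <- match.arg(type)
  mat <- as.matrix(mat)
  if (nrow(mat) < 2 || ncol(mat) < 2) rw_abort("need >= 2 subjects and >= 2 days", "rw_schema_mismatch")
  if (anyNA(mat)) rw_abort("ICC requires a complete subject x day matrix", "rw_incomplete_matrix")
  n <- nrow(mat)
  k <- ncol(mat)
  gm <- mean(mat)
  rm_ <- rowMeans(mat)
  cm <- colMeans(mat)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm - gm)^2)
  sst <- sum((mat - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (type == "ICC3") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    f <- msr / mse
    df2 <- (n - 1) * (k - 1)
    a <- 1 - (1 - conf) / 2
    fl <- f / stats::qf(a, n - 1, df2)
    fu <- f * stats::qf(a, df2, n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    p <- stats::pf(f, n - 1, df2, lower.tail = FALSE)
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
    ci <- c(NA_real_, NA_real_)
    p <- stats::pf(msr / mse, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }
  list(icc = icc, ci = ci, p = p, ms = list(msr = msr, msc = msc, mse = mse))
}
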
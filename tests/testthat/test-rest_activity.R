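test_that("dichotomy index counts strict inequalities against the out-of-bed median", {
  # all in-bed counts below the out-of-bed median -> 100%
  f <- one_night(in_counts = c(0, 0, 0), out_counts = c(5, 10, 15))
  expect_equal(dichotomy_index(f$series, f$schedule), 100)

  # exact-median epochs do not count under the strict convention
  f <- one_night(in_counts = c(5, 10, 15), out_counts = c(0, 10, 20, 10, 40))
  expect_equal(dichotomy_index(f$series, f$schedule),
               oracle_iless_o(c(5, 10, 15), c(0, 10, 20, 10, 40)))
  expect_equal(dichotomy_index(f$series, f$schedule), 100 / 3)
  # the non-strict convention is exposed for sensitivity analysis
  expect_equal(dichotomy_index(f$series, f$schedule, strict = FALSE),
               oracle_iless_o(c(5, 10, 15), c(0, 10, 20, 10, 40), strict = FALSE))

  # disrupted-rhythm labelling threshold
  expect_true(100 / 3 <= 97.5)
})

test_that("dichotomy index equals the brute-force counter on random instances", {
  set.seed(42)
  for (i in 1:60) {
    n_nights <- sample(1:3, 1)
    per <- sample(10:40, 1)
    counts <- rnbinom(200, size = 1, mu = 40)
    s <- make_series(counts)
    in_off <- sort(sample(seq(0, 160, by = 50), n_nights))
    sch <- make_schedule(in_off, in_off + per %/% 2)
    mask <- rep(FALSE, 200)
    tt <- seq_len(200) - 1
    for (k in seq_len(n_nights)) {
      mask <- mask | (tt >= in_off[k] & tt < in_off[k] + per %/% 2)
    }
    expect_equal(dichotomy_index(s, sch),
                 oracle_iless_o(counts[mask], counts[!mask]))
  }
})

test_that("dichotomy index is invariant under strictly increasing transforms", {
  set.seed(7)
  # 241 out-of-bed epochs: an odd pool, so the median is an order statistic
  # and the strict comparison depends on ranks alone
  counts <- rnbinom(401, size = 1, mu = 30)
  s <- make_series(counts)
  sch <- make_schedule(c(30, 230), c(110, 310))
  base <- dichotomy_index(s, sch)
  for (f in list(function(x) 3 * x + 7, function(x) x^2 + x,
                 function(x) floor(exp(x / 50) * 100))) {
    s2 <- make_series(f(counts))
    expect_equal(dichotomy_index(s2, sch), base)
  }
})

test_that("restricted and full I<O agree when boundary hours change nothing", {
  # constant pools: dropping the transition hours leaves both medians intact
  s2 <- make_series(c(rep(200, 300), rep(0, 300)))
  sch2 <- make_schedule(300, 600)
  expect_equal(dichotomy_index(s2, sch2), 100)
  expect_equal(dichotomy_index(s2, sch2, restriction = "20h"), 100)

  # the restricted variant really excludes the transition epochs: plant high
  # counts only inside the hour after bed time and watch them vanish
  counts <- c(rep(200, 300), rep(500, 60), rep(0, 240))
  s3 <- make_series(counts)
  full <- dichotomy_index(s3, sch2)
  restricted <- dichotomy_index(s3, sch2, restriction = "20h")
  expect_equal(full, oracle_iless_o(counts[301:600], counts[1:300]))
  expect_equal(restricted, 100)   # spikes sat entirely in the excluded hour
  expect_gt(restricted, full)
})

test_that("dichotomy index error contracts", {
  f <- one_night(c(0, 0), c(5, 5))
  sch_empty <- make_schedule(3000, 3060)  # outside recording
  expect_error(dichotomy_index(f$series, sch_empty), class = "rw_no_in_bed_epochs")
  s <- make_series(c(5, 5, NA, NA))
  sch <- make_schedule(2, 4)
  expect_error(dichotomy_index(s, sch), class = "rw_all_missing")
})

test_that("r24 is ~1 for a pure 24-h sinusoid and ~0 for iid noise", {
  t <- seq_len(8 * 1440)
  sinus <- round(100 + 90 * sin(2 * pi * t / 1440))
  expect_gte(r24_autocorrelation(make_series(sinus)), 0.999)

  set.seed(1)
  noise <- rpois(8 * 1440, 50)
  expect_lt(abs(r24_autocorrelation(make_series(noise))), 0.05)

  expect_error(r24_autocorrelation(make_series(rep(1, 2000))),
               class = "rw_series_too_short")
})

test_that("r24 matches the two-pass correlation oracle on toy series", {
  set.seed(9)
  # 4-day series with a planted partial repeat and missing epochs
  day <- round(50 + 40 * sin(2 * pi * seq_len(1440) / 1440))
  x <- c(day, day + rpois(1440, 20), rpois(1440, 60), day)
  x[sample(length(x), 200)] <- NA
  expect_equal(r24_autocorrelation(make_series(x)), oracle_lag_cor(x),
               tolerance = 1e-12)
  # concatenating an exact copy of the first day preserves oracle equality
  y <- c(x[1:1440], x)
  expect_equal(r24_autocorrelation(make_series(y)), oracle_lag_cor(y),
               tolerance = 1e-12)
  expect_true(abs(r24_autocorrelation(make_series(x))) <= 1)
})

test_that("mean daily activity averages non-missing epochs only", {
  expect_equal(mean_daily_activity(make_series(c(0, 10, 20))), 10)
  expect_equal(mean_daily_activity(make_series(rep(7, 50))), 7)
  set.seed(3)
  x <- rpois(500, 30)
  x[sample(500, 60)] <- NA
  expect_equal(mean_daily_activity(make_series(x)), mean(x[!is.na(x)]))
  expect_error(mean_daily_activity(make_series(c(NA, NA))), class = "rw_all_missing")
})

test_that("mean wake activity pools the spans between sleep periods", {
  # two nights, one constant daytime span
  counts <- c(rep(1, 60), rep(30, 120), rep(2, 60))
  s <- make_series(counts)
  sch <- make_schedule(c(0, 180), c(60, 240))
  expect_equal(mean_wake_activity(s, sch), 30)

  counts2 <- c(rep(1, 60), 10, 20, 30, 40, rep(2, 60))
  s2 <- make_series(counts2)
  sch2 <- make_schedule(c(0, 64), c(60, 124))
  expect_equal(mean_wake_activity(s2, sch2), 25)

  # three nights: pooled mean equals the concatenation of both spans
  set.seed(11)
  counts3 <- rpois(600, 40)
  s3 <- make_series(counts3)
  sch3 <- make_schedule(c(0, 200, 400), c(100, 300, 500))
  expect_equal(mean_wake_activity(s3, sch3),
               mean(c(counts3[101:200], counts3[301:400])))

  expect_error(mean_wake_activity(s, make_schedule(0, 60)), class = "rw_no_wake_span")
})

test_that("analysis-set qualification follows the 8-day / 3-day rules", {
  d8 <- random_diaries(8, seed = 2)
  full8 <- make_series(rpois(8 * 1440, 20))
  sch <- make_schedule(seq(660, by = 1440, length.out = 8),
                       seq(1170, by = 1440, length.out = 8))
  expect_equal(qualify_analysis_set(full8, sch, d8), "per_protocol")

  # four consecutive valid days -> full analysis
  x <- rpois(8 * 1440, 20)
  x[(4 * 1440 + 1):(8 * 1440)] <- NA
  expect_equal(qualify_analysis_set(make_series(x), sch, d8), "full_analysis")

  # two valid days -> excluded
  y <- rpois(8 * 1440, 20)
  y[(2 * 1440 + 1):(8 * 1440)] <- NA
  expect_equal(qualify_analysis_set(make_series(y), sch, d8), "excluded")

  # diary gates the sets too
  expect_equal(qualify_analysis_set(full8, sch, random_diaries(3, 1)), "full_analysis")
  expect_equal(qualify_analysis_set(full8, sch, NULL), "excluded")
})

test_that("valid-day detection respects the 90% non-missing threshold", {
  x <- rpois(2 * 1440, 10)
  x[1:200] <- NA                      # day 1: 86% present -> invalid
  vd <- valid_days(make_series(x))
  expect_identical(vd, c(FALSE, TRUE))
  expect_identical(valid_days(make_series(x), valid_frac = 0.8), c(TRUE, TRUE))
})

test_that("per-night I<O and weekend flags support the stability analyses", {
  co <- cached_cohort(n = 6)
  p <- co$participants[[1]]
  by_night <- dichotomy_index_by_night(p$series, p$schedule)
  expect_length(by_night, 8)
  expect_true(all(is.finite(by_night)))
  expect_true(all(by_night >= 0 & by_night <= 100))
  # recording starts Monday 2020-01-06: nights 6 and 7 are Sat/Sun
  expect_identical(which(night_is_weekend(p$schedule)), c(6L, 7L))
})
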
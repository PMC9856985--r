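test_that("weighted-window scoring matches the per-epoch summation oracle", {
  s0 <- as.POSIXct(T0, tz = "UTC")

  # all-zero counts: W = 0 everywhere -> all sleep
  s <- make_series(rep(0, 30))
  expect_true(all(score_epochs(s, c(s0, s0 + 30 * 60)) == "sleep"))

  # single spike: centre wake, flanks per the oracle
  cnt <- c(0, 0, 500, 0, 0)
  s <- make_series(cnt)
  lab <- score_epochs(s, c(s0, s0 + 5 * 60))
  expect_identical(lab, oracle_sleep_labels(cnt))
  expect_identical(lab[3], "wake")

  # constant 41: W = 41 * 1.48 interior; wake at threshold 40, sleep at 80
  s <- make_series(rep(41, 20))
  expect_true(all(score_epochs(s, c(s0, s0 + 20 * 60), sensitivity = 40) == "wake"))
  expect_true(all(score_epochs(s, c(s0, s0 + 20 * 60), sensitivity = 80) == "sleep"))

  # random series, including missing epochs treated as zero contribution
  set.seed(5)
  for (i in 1:20) {
    cnt <- rnbinom(120, size = 0.8, mu = 35)
    cnt[sample(120, 10)] <- NA
    s <- make_series(cnt)
    expect_identical(score_epochs(s, c(s0, s0 + 120 * 60)),
                     oracle_sleep_labels(cnt))
  }

  expect_error(score_epochs(s, c(s0 - 60, s0 + 60)),
               class = "rw_interval_outside_series")
})

test_that("scoring is monotone in the sensitivity threshold", {
  set.seed(8)
  cnt <- rnbinom(200, size = 1, mu = 30)
  s <- make_series(cnt)
  s0 <- as.POSIXct(T0, tz = "UTC")
  prev <- score_epochs(s, c(s0, s0 + 200 * 60), sensitivity = 20)
  for (th in c(40, 80, 160)) {
    cur <- score_epochs(s, c(s0, s0 + 200 * 60), sensitivity = th)
    expect_true(all(!(prev == "sleep" & cur == "wake")))
    prev <- cur
  }
})

test_that("night parameters follow the onset-run and run-length rules", {
  # perfect night
  p <- actigraphy_night_params(rep("sleep", 480))
  expect_equal(p[c("sol_min", "waso_min", "na", "tst_min", "se_pct")],
               list(sol_min = 0L, waso_min = 0L, na = 0L, tst_min = 480L,
                    se_pct = 100))

  # 20 wake, 400 sleep, 30 wake, 30 sleep
  labels <- c(rep("wake", 20), rep("sleep", 400), rep("wake", 30), rep("sleep", 30))
  p <- actigraphy_night_params(labels)
  expect_equal(p$sol_min, 20L)
  expect_equal(p$waso_min, 30L)
  expect_equal(p$na, 1L)
  expect_equal(p$tst_min, 430L)
  expect_equal(p$se_pct, 100 * 430 / 480)

  expect_error(actigraphy_night_params(rep("wake", 100)),
               class = "rw_no_sleep_detected")

  # random labels vs the run-length oracle
  set.seed(13)
  for (i in 1:30) {
    labels <- sample(c("sleep", "wake"), 300, replace = TRUE, prob = c(0.8, 0.2))
    o <- oracle_night_params(labels)
    if (is.null(o)) {
      expect_error(actigraphy_night_params(labels), class = "rw_no_sleep_detected")
    } else {
      p <- actigraphy_night_params(labels)
      expect_equal(p$sol_min, o$sol)
      expect_equal(p$tst_min, o$tst)
      expect_equal(p$waso_min, o$waso)
      expect_equal(p$na, o$na)
      expect_equal(p$se_pct, o$se)
    }
  }
})

test_that("diary arithmetic reproduces the defining identities", {
  d <- list(participant_id = "P1", night_index = 1, bed_time = "23:00",
            time_tried_sleep = "23:10", sol_min = 20, waso_min = 40,
            n_awakenings = 3, final_awakening = "06:40", get_up_time = "07:00")
  n <- diary_night_params(d)
  expect_equal(n$tib_min, 480)
  expect_equal(n$twak_min, 20)
  expect_equal(n$tst_min, 400)
  expect_equal(n$se_pct, 100 * 400 / 480)

  # identity night crossing midnight
  d2 <- list(participant_id = "P1", night_index = 2, bed_time = "00:30",
             time_tried_sleep = "00:30", sol_min = 0, waso_min = 0,
             n_awakenings = 0, final_awakening = "08:30", get_up_time = "08:30")
  n2 <- diary_night_params(d2)
  expect_equal(n2$tib_min, 480)
  expect_equal(n2$twak_min, 0)
  expect_equal(n2$tst_min, 480)
  expect_equal(n2$se_pct, 100)

  # wake components exceeding TIB: clamped to missing and flagged
  d3 <- modifyList(d, list(sol_min = 300, waso_min = 300))
  n3 <- diary_night_params(d3)
  expect_true(n3$flagged)
  expect_true(is.na(n3$tst_min))

  # final awakening after get-up is inconsistent
  d4 <- modifyList(d, list(final_awakening = "07:30"))
  expect_error(diary_night_params(d4), class = "rw_inconsistent_times")
})

test_that("the diary identity holds exactly on random valid diaries", {
  dd <- random_diaries(300, seed = 21)
  for (i in seq_len(nrow(dd))) {
    n <- diary_night_params(dd[i, ])
    if (n$flagged) next
    expect_identical(n$sol_min + n$waso_min + n$twak_min + n$tst_min, n$tib_min)
    expect_true(n$se_pct >= 0 && n$se_pct <= 100)
    expect_true(n$tst_min <= n$tib_min)
  }
})

test_that("participant aggregation averages nights, clock times circularly", {
  dd <- random_diaries(2, seed = 31)
  n1 <- diary_night_params(dd[1, ]); n2 <- diary_night_params(dd[2, ])
  n1$tst_min <- 400; n2$tst_min <- 440
  n1$gut <- "23:30"; n2$gut <- "00:30"
  agg <- aggregate_participant(rbind(n1, n2), min_nights = 2)
  expect_equal(agg$tst_min, 420)
  expect_equal(agg$gut, "00:00")

  # 8 nights: plain averaging oracle on every duration field
  dd8 <- random_diaries(8, seed = 32)
  nn <- do.call(rbind, lapply(seq_len(8), function(i) diary_night_params(dd8[i, ])))
  agg8 <- aggregate_participant(nn)
  for (cc in c("tib_min", "sol_min", "waso_min", "twak_min")) {
    expect_equal(agg8[[cc]], mean(nn[[cc]], na.rm = TRUE))
  }
  expect_error(aggregate_participant(nn[1:2, ]), class = "rw_too_few_nights")
})

test_that("an all-zero count night scores as the perfect night end to end", {
  counts <- c(rep(100, 660), rep(0, 480), rep(100, 300))
  s <- make_series(counts)
  sch <- make_schedule(660, 1140)
  row <- actigraphy_sleep_night(s, sch, 1)
  expect_equal(row$sol_min, 0L)
  expect_equal(row$waso_min, 0L)
  expect_equal(row$tst_min, 480L)
  expect_equal(row$se_pct, 100)
  expect_equal(row$source, "actigraphy")
})
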
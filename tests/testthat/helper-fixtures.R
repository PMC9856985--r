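# Fixture builders. Everything is generated in code; no data files.

T0 <- "2020-01-06 12:00:00"

make_series <- function(counts, start = T0, id = "P1") {
  epoch_series(id, start, counts)
}

# schedule from epoch offsets (minutes from series start)
make_schedule <- function(in_off, out_off, start = T0, id = "P1") {
  s0 <- as.POSIXct(start, tz = "UTC")
  bed_schedule(id, s0 + in_off * 60, s0 + out_off * 60)
}

# one-night series: `out_counts` daytime epochs then `in_counts` in-bed epochs
one_night <- function(in_counts, out_counts, id = "P1") {
  n_out <- length(out_counts)
  n_in <- length(in_counts)
  list(series = make_series(c(out_counts, in_counts), id = id),
       schedule = make_schedule(n_out, n_out + n_in, id = id))
}

# small cached default cohort shared across tests (generation is seeded)
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(n = 50, seed = 101, days = 8) {
  key <- sprintf("n%d_s%d_d%d", n, seed, days)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- generate_cohort(
      cohort_spec(n_participants = n, days = days, seed = seed))
  }
  .cohort_cache[[key]]
}

# random valid diary rows (uniform clock times, wrap-aware consistency)
random_diaries <- function(n, seed) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    bt <- sample(0:1439, 1)                       # any clock minute
    tib <- sample(120:840, 1)
    sol <- sample(0:60, 1)
    waso <- sample(0:90, 1)
    twak <- sample(0:45, 1)
    if (sol + waso + twak > tib) {                # keep the night feasible
      sol <- sol %% 30; waso <- waso %% 30; twak <- twak %% 30
    }
    gut <- (bt + tib) %% 1440
    fa <- (bt + tib - twak) %% 1440
    data.frame(participant_id = "PX", night_index = i,
               bed_time = format_hm(bt),
               time_tried_sleep = format_hm((bt + 5) %% 1440),
               sol_min = sol, waso_min = waso, n_awakenings = sample(0:6, 1),
               final_awakening = format_hm(fa), get_up_time = format_hm(gut),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
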
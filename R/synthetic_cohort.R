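# Synthetic cohort generator. Emulates the study's data structure with
# known ground truth: minute-epoch wrist counts from a two-state
# (sleep/wake) process inside scheduled nights, a fragmentation parameter
# rho governing nightly wake bouts, negative-binomial counts with
# state-dependent means modulated by a 24-h sinusoid, diaries as noisy
# reports of the true night structure, clinical covariates with a sparse
# known effect on an exponential survival time, and administrative
# censoring. A per-participant latent frailty raises fragmentation, lowers
# daytime activity and raises the hazard, so the dichotomy index decreases
# and the hazard increases with frailty by construction.

#' Default sparse true coefficient vector
#'
#' Ten nonzero log-hazard coefficients on the (z-scaled) clinical features:
#' inflammatory/renal markers and reported sleep disturbance raise the
#' hazard; haemoglobin, clinician survival estimate, global health status
#' lower it.
#'
#' @return named numeric vector (nonzero entries only)
#' @export
default_true_beta <- function() {
  c(crp = 0.40, urea = 0.35, creatinine = 0.30, neutrophils = 0.30,
    psqi_dist_wake_night = 0.30, psqi_sleep_quality = 0.30, msas_tmsas = 0.25,
    haemoglobin = -0.35, pips_global_health = -0.35,
    pips_survival_estimate = -0.40)
}

#' Specify a synthetic cohort
#'
#' Defaults mirror the study design: 50 participants, eight consecutive
#' 24-h actigraphy periods at one-minute epochs with eight diary nights, 66
#' predictors, exponential survival with administrative censoring at one
#' year tuned to roughly two-thirds observed events.
#'
#' @param n_participants cohort size (>= 2)
#' @param days 24-h periods per participant (>= 3)
#' @param start_date timestamp of the first epoch (recording starts at
#'   midday after the initial review)
#' @param fragmentation length-2 range of the nightly wake-bout fraction
#'   rho; each participant's rho is placed in this range by their frailty
#' @param circadian_amplitude length-2 range of the 24-h sinusoidal
#'   modulation of daytime activity
#' @param wake_mean baseline daytime activity mean (counts/min)
#' @param sleep_mean asleep activity mean (counts/min)
#' @param bout_mean_len mean wake-bout length in minutes
#' @param dispersion negative-binomial size parameter (wrist counts are
#'   overdispersed; smaller = more dispersed)
#' @param diary_clock_sd diary clock-time reporting noise, minutes (sd)
#' @param diary_dur_cv diary duration reporting noise, coefficient of
#'   variation
#' @param beta named sparse true coefficient vector on z-scaled clinical
#'   features (see [default_true_beta()])
#' @param beta_frailty log-hazard coefficient on the latent frailty
#' @param lambda0 baseline exponential hazard per day
#' @param admin_censor_day administrative censoring day
#' @param frailty_sd sd of the latent frailty
#' @param seed integer seed; the whole bundle is a deterministic function
#'   of these settings including the seed
#' @return list of class `cohort_spec`
#' @export
cohort_spec <- function(n_participants = 50, days = 8,
                        start_date = "2020-01-06 12:00:00",
                        fragmentation = c(0.05, 0.45),
                        circadian_amplitude = c(0.2, 0.6),
                        wake_mean = 250, sleep_mean = 4, bout_mean_len = 5,
                        dispersion = 1.2,
                        diary_clock_sd = 10, diary_dur_cv = 0.15,
                        beta = default_true_beta(), beta_frailty = 0.5,
                        lambda0 = 1 / 150, admin_censor_day = 365,
                        frailty_sd = 1, seed = 1) {
  if (n_participants < 2) rw_abort("n_participants must be >= 2", "rw_schema_mismatch")
  if (days < 3) rw_abort("days must be >= 3", "rw_schema_mismatch")
  structure(list(n_participants = n_participants, days = days,
                 start_date = start_date, fragmentation = fragmentation,
                 circadian_amplitude = circadian_amplitude,
                 wake_mean = wake_mean, sleep_mean = sleep_mean,
                 bout_mean_len = bout_mean_len, dispersion = dispersion,
                 diary_clock_sd = diary_clock_sd, diary_dur_cv = diary_dur_cv,
                 beta = beta, beta_frailty = beta_frailty, lambda0 = lambda0,
                 admin_censor_day = admin_censor_day, frailty_sd = frailty_sd,
                 seed = seed),
            class = "cohort_spec")
}

#' Simulate one participant's actigraphy
#'
#' Nights are scheduled around 23:00-07:30 with per-night jitter. Within a
#' night the true state starts awake (sleep-onset latency), ends awake
#' (terminal awakening), and in between is sleep interrupted by wake bouts:
#' a bout starts at any sleeping minute with probability rho/bout_mean_len
#' and lasts a geometric number of minutes, so rho is approximately the
#' expected within-night wake fraction. Counts are negative-binomial with a
#' high daytime mean (sinusoidally modulated over 24 h), a moderate mean in
#' nightly wake bouts and a low mean asleep. Frailty shifts rho up and the
#' daytime mean down.
#'
#' @param spec a `cohort_spec`
#' @param participant_id id string
#' @param frailty latent frailty (standard-normal scale)
#' @param rho optional override of the wake-bout fraction (bypasses frailty
#'   mapping); used for controlled fragmentation sweeps
#' @return list: series (`epoch_series`), schedule (`bed_schedule`), truth
#'   (frailty, rho, per-night data.frame, full state vector)
#' @export
simulate_activity <- function(spec, participant_id, frailty = 0, rho = NULL) {
  n_ep <- spec$days * 1440L
  start <- .parse_ts(spec$start_date)
  if (is.null(rho)) {
    fr <- spec$fragmentation
    rho <- fr[1] + stats::pnorm(0.8 * frailty) * (fr[2] - fr[1])
  }
  am <- spec$circadian_amplitude
  amp <- am[1] + (1 - stats::pnorm(0.6 * frailty)) * (am[2] - am[1])
  day_mean <- spec$wake_mean * exp(-0.25 * frailty)

  # state per epoch: 1 = daytime wake, 2 = in-bed wake, 3 = sleep
  state <- rep(1L, n_ep)
  in_bed_start <- out_of_bed_end <- .POSIXct(numeric(spec$days), tz = "UTC")
  nights <- vector("list", spec$days)
  for (d in seq_len(spec$days)) {
    bed_off <- round(660 + stats::rnorm(1, 0, 20))            # ~23:00, minutes from midday
    rise_off <- round(d * 1440 - 270 + stats::rnorm(1, 0, 20)) # ~07:30 next day
    bed_ep <- (d - 1) * 1440 + bed_off + 1
    rise_ep <- min(rise_off, n_ep)
    m <- rise_ep - bed_ep + 1
    # rho = 0 is the fully consolidated sleeper: no wake minutes in bed at all
    sol <- if (rho == 0) 0L else min(m - 20, stats::rpois(1, 12 + 4 * max(0, frailty)))
    twak <- if (rho == 0) 0L else min(m - sol - 10, stats::rpois(1, 6))
    night <- rep(3L, m)
    if (sol > 0) night[seq_len(sol)] <- 2L
    if (twak > 0) night[(m - twak + 1):m] <- 2L
    interior <- which(night == 3L)
    if (length(interior) > 2) {
      p_start <- rho / spec$bout_mean_len
      starts <- interior[stats::runif(length(interior)) < p_start]
      for (s in starts) {
        len <- 1 + stats::rgeom(1, 1 / spec$bout_mean_len)
        idx <- s:min(s + len - 1, interior[length(interior)])
        night[idx] <- 2L
      }
    }
    state[bed_ep:rise_ep] <- night
    in_bed_start[d] <- start + (bed_ep - 1) * 60
    out_of_bed_end[d] <- start + rise_ep * 60
    interior_state <- night[(sol + 1):(m - twak)]
    ri <- rle(interior_state == 2L)
    nights[[d]] <- data.frame(night_index = d, bt = in_bed_start[d],
                              gut = out_of_bed_end[d], tib = m,
                              sol = sol, waso = sum(interior_state == 2L),
                              na = sum(ri$values), twak = twak,
                              tst = sum(night == 3L))
  }
  tod0 <- as.numeric(format(start, "%H", tz = "UTC")) +
    as.numeric(format(start, "%M", tz = "UTC")) / 60
  tod_h <- (tod0 + (seq_len(n_ep) - 1) / 60) %% 24
  mu <- numeric(n_ep)
  mu[state == 1L] <- pmax(1, day_mean * (1 + amp * cos(2 * pi * (tod_h[state == 1L] - 14.5) / 24)))
  mu[state == 2L] <- pmax(1, 0.9 * day_mean)
  mu[state == 3L] <- spec$sleep_mean
  counts <- stats::rnbinom(n_ep, size = spec$dispersion, mu = mu)
  series <- epoch_series(participant_id, start, counts)
  schedule <- bed_schedule(participant_id, in_bed_start, out_of_bed_end)
  list(series = series, schedule = schedule,
       truth = list(frailty = frailty, rho = rho,
                    nights = do.call(rbind, nights), state = state))
}

#' Simulate the diary as a noisy report of the true night structure
#'
#' Clock times get zero-mean Gaussian noise (sd `diary_clock_sd` minutes);
#' durations get multiplicative noise (cv `diary_dur_cv`), clamped to
#' validity. The reported wake components are rescaled when they would
#' exceed the reported time in bed, so the diary identity
#' TIB = SOL + WASO + TWAK + TST is re-established after noising.
#'
#' @param truth truth element of [simulate_activity()] output
#' @param spec a `cohort_spec`
#' @param participant_id id string
#' @return diary data.frame (one row per night, diary CSV layout)
#' @export
simulate_diary <- function(truth, spec, participant_id) {
  nt <- truth$nights
  csd <- spec$diary_clock_sd
  cv <- spec$diary_dur_cv
  rows <- lapply(seq_len(nrow(nt)), function(i) {
    bt <- nt$bt[i] + round(stats::rnorm(1, 0, csd)) * 60
    gut <- nt$gut[i] + round(stats::rnorm(1, 0, csd)) * 60
    tib <- as.numeric(difftime(gut, bt, units = "mins"))
    if (tib < 60) {
      gut <- bt + 60 * 60
      tib <- 60
    }
    noise_dur <- function(v) max(0, round(v * (1 + stats::rnorm(1, 0, cv))))
    sol <- noise_dur(nt$sol[i])
    waso <- noise_dur(nt$waso[i])
    twak <- noise_dur(nt$twak[i])
    tot <- sol + waso + twak
    if (tot > tib) {
      sc <- tib / tot
      sol <- floor(sol * sc)
      waso <- floor(waso * sc)
      twak <- floor(twak * sc)
    }
    na_rep <- max(0, nt$na[i] + round(stats::rnorm(1, 0, 1)))
    data.frame(participant_id = participant_id, night_index = nt$night_index[i],
               bed_time = format(bt, "%H:%M", tz = "UTC"),
               time_tried_sleep = format(bt + round(abs(stats::rnorm(1, 0, 5))) * 60,
                                         "%H:%M", tz = "UTC"),
               sol_min = sol, waso_min = waso, n_awakenings = na_rep,
               final_awakening = format(gut - twak * 60, "%H:%M", tz = "UTC"),
               get_up_time = format(gut, "%H:%M", tz = "UTC"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# clamp helper
.cl <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Simulate the raw clinical/questionnaire table
#'
#' Produces the clinical- and PSQI-source raw columns of the default schema
#' for each participant: realistic demographics and blood values, ordinal
#' scores, and clock-time strings. Several covariates are deliberately
#' correlated with the latent frailty (and hence with each other), so
#' downstream collinearity handling is exercised.
#'
#' @param spec a `cohort_spec`
#' @param ids participant ids
#' @param frailty latent frailty vector
#' @return data.frame of raw clinical values (no outcome columns)
#' @export
simulate_clinical <- function(spec, ids, frailty) {
  n <- length(ids)
  f <- frailty
  rn <- function(mu, sd) stats::rnorm(n, mu, sd)
  ln <- function(logmu, sd) exp(stats::rnorm(n, logmu, sd))
  ord_chr <- function(latent, lo, hi) as.character(round(.cl(latent, lo, hi)))
  freq_levels <- c("not_past_month", "less_than_weekly", "once_twice_weekly",
                   "three_plus_weekly")
  df <- data.frame(
    participant_id = ids,
    sex_male = sample(c("no", "yes"), n, replace = TRUE),
    opioid_use = ifelse(stats::runif(n) < stats::plogis(-0.2 + 0.6 * f), "yes", "no"),
    ecog_clin_day0 = ord_chr(rn(1.8, 0.7) + 0.6 * f, 0, 4),
    ecog_pt_day0 = ord_chr(rn(1.8, 0.8) + 0.5 * f, 0, 4),
    ecog_clin_day8 = ord_chr(rn(1.9, 0.7) + 0.6 * f, 0, 4),
    ecog_pt_day8 = ord_chr(rn(1.9, 0.8) + 0.5 * f, 0, 4),
    mgps = ord_chr(rn(1, 0.6) + 0.5 * f, 0, 2),
    pips_survival_estimate = c("days", "weeks", "months_plus")[
      1 + .cl(round(1.6 - 0.8 * f + rn(0, 0.5)), 0, 2)],
    pips_global_health = ord_chr(rn(4, 1) - 0.8 * f, 1, 7),
    age = round(rn(64, 10)),
    pulse = round(rn(82, 11)),
    comorbidity_count = stats::rpois(n, 2),
    msas_tmsas = .cl(rn(1.3, 0.4) + 0.3 * f, 0, 4),
    msas_global_distress = .cl(rn(1.4, 0.5) + 0.3 * f, 0, 4),
    msas_physical = .cl(rn(1.3, 0.5) + 0.25 * f, 0, 4),
    msas_psych = .cl(rn(1.2, 0.5) + 0.2 * f, 0, 4),
    msas_num_symptoms = round(.cl(rn(12, 4) + 2 * f, 0, 32)),
    months_since_diagnosis = round(ln(log(18), 0.8)),
    haemoglobin = rn(122, 13) - 6 * f,
    wbc = ln(log(8), 0.25) * exp(0.10 * f),
    neutrophils = ln(log(5.5), 0.3) * exp(0.15 * f),
    lymphocytes = ln(log(1.2), 0.3) * exp(-0.10 * f),
    platelets = rn(300, 80),
    sodium = rn(137, 3),
    potassium = rn(4.2, 0.4),
    urea = ln(log(7), 0.3) * exp(0.25 * f),
    creatinine = ln(log(85), 0.25) * exp(0.15 * f),
    albumin = rn(36, 4) - 2 * f,
    alt = ln(log(24), 0.5),
    alp = ln(log(120), 0.4) * exp(0.10 * f),
    crp = ln(log(18), 0.7) * exp(0.60 * f),
    psqi_sleep_quality = ord_chr(rn(1.2, 0.7) + 0.4 * f, 0, 3),
    psqi_sleep_latency = ord_chr(rn(1.3, 0.8) + 0.3 * f, 0, 3),
    psqi_sleep_duration = ord_chr(rn(1.2, 0.8) + 0.3 * f, 0, 3),
    psqi_sleep_efficiency = ord_chr(rn(1.1, 0.8) + 0.3 * f, 0, 3),
    psqi_sleep_disturbance = ord_chr(rn(1.5, 0.7) + 0.3 * f, 0, 3),
    psqi_sleep_medication = ord_chr(rn(0.8, 0.9), 0, 3),
    psqi_daytime_dysfunction = ord_chr(rn(1.3, 0.8) + 0.3 * f, 0, 3),
    psqi_dist_wake_night = freq_levels[1 + .cl(round(rn(1.5, 0.9) + 0.5 * f), 0, 3)],
    psqi_dist_pain = freq_levels[1 + .cl(round(rn(1.3, 0.9) + 0.4 * f), 0, 3)],
    psqi_dist_breathe = freq_levels[1 + .cl(round(rn(0.8, 0.9) + 0.3 * f), 0, 3)],
    psqi_usual_bt = format_hm(round(22 * 60 + 45 + rn(0, 40)) %% 1440),
    psqi_usual_gut = format_hm(round(7 * 60 + 30 + rn(0, 40)) %% 1440),
    stringsAsFactors = FALSE)
  df
}

#' Simulate exponential survival with administrative censoring
#'
#' Event time ~ Exponential(lambda0 * exp(x' beta)); observation is censored
#' at `admin_censor_day` with event flag 0.
#'
#' @param x numeric matrix of covariates on the model scale (columns named)
#' @param beta named coefficient vector (names must be columns of `x`)
#' @param lambda0 baseline hazard per day
#' @param admin_censor_day administrative cut-off in days
#' @return data.frame: survival_days, event, true_time, lp
#' @export
simulate_survival <- function(x, beta, lambda0, admin_censor_day) {
  miss <- setdiff(names(beta), colnames(x))
  if (length(miss) > 0) {
    rw_abort(paste("beta names not in covariates:", paste(miss, collapse = ", ")),
             "rw_schema_mismatch")
  }
  lp <- drop(x[, names(beta), drop = FALSE] %*% beta)
  tt <- stats::rexp(nrow(x), rate = lambda0 * exp(lp))
  ev <- as.integer(tt <= admin_censor_day)
  data.frame(survival_days = pmin(tt, admin_censor_day), event = ev,
             true_time = tt, lp = lp)
}

#' Generate a complete synthetic cohort
#'
#' Draws frailty, simulates actigraphy + diary + clinical covariates per
#' participant, generates survival from the z-scaled true-coefficient
#' features plus frailty, and optionally writes every input in the package's
#' CSV dialects (one epoch file per participant, a pooled schedule CSV, the
#' diary CSV, the clinical CSV with outcome, and a ground-truth sidecar that
#' the analysis path never reads).
#'
#' @param spec a `cohort_spec`
#' @param dir optional output directory (created if needed)
#' @return object of class `synthetic_cohort`: spec, ids, participants
#'   (list of series/schedule/truth), diary, clinical, truth
#' @export
generate_cohort <- function(spec = cohort_spec(), dir = NULL) {
  schema <- default_feature_schema()
  out <- with_seed(spec$seed, {
    n <- spec$n_participants
    ids <- sprintf("P%03d", seq_len(n))
    frailty <- stats::rnorm(n, 0, spec$frailty_sd)
    participants <- vector("list", n)
    diary <- vector("list", n)
    for (i in seq_len(n)) {
      participants[[i]] <- simulate_activity(spec, ids[i], frailty[i])
      diary[[i]] <- simulate_diary(participants[[i]]$truth, spec, ids[i])
    }
    names(participants) <- ids
    diary <- do.call(rbind, diary)
    clinical_raw <- simulate_clinical(spec, ids, frailty)
    enc <- encode_features(clinical_raw, schema)
    cols <- names(spec$beta)
    z <- scale(enc[, cols, drop = FALSE])
    z[, attr(z, "scaled:scale") == 0] <- 0
    zf <- cbind(z, frailty = as.numeric(scale(frailty)))
    surv <- simulate_survival(zf, c(spec$beta, frailty = spec$beta_frailty),
                              spec$lambda0, spec$admin_censor_day)
    clinical <- clinical_raw
    clinical$survival_days <- surv$survival_days
    clinical$event <- surv$event
    list(ids = ids, participants = participants, diary = diary,
         clinical = clinical,
         truth = list(frailty = frailty, lp = surv$lp,
                      true_time = surv$true_time, beta = spec$beta,
                      beta_frailty = spec$beta_frailty))
  })
  out$spec <- spec
  class(out) <- "synthetic_cohort"
  if (!is.null(dir)) write_cohort(out, dir)
  out
}

#' Write a synthetic cohort's input files
#'
#' @param cohort a `synthetic_cohort`
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "epochs"), recursive = TRUE, showWarnings = FALSE)
  sched_path <- file.path(dir, "schedule.csv")
  if (file.exists(sched_path)) file.remove(sched_path)
  for (id in cohort$ids) {
    p <- cohort$participants[[id]]
    write_epoch_csv(p$series, file.path(dir, "epochs", paste0(id, ".csv")))
    write_schedule_csv(p$schedule, sched_path, append = file.exists(sched_path))
  }
  write_diary_csv(cohort$diary, file.path(dir, "diary.csv"))
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  gt <- data.frame(participant_id = cohort$ids,
                   frailty = cohort$truth$frailty, lp = cohort$truth$lp,
                   true_time = cohort$truth$true_time)
  utils::write.csv(gt, file.path(dir, "ground_truth_synthetic.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' @exportS3Method base::print
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> n=%d, %d days, %d diary nights, %.0f%% events (seed %d)\n",
              length(x$ids), x$spec$days, nrow(x$diary),
              100 * mean(x$clinical$event), x$spec$seed))
  invisible(x)
}
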
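# synthetic feature tables with independent standard-normal predictors and
# exponential survival; used throughout the model tests
sim_table <- function(n, p, beta = NULL, seed = 1, lambda0 = 0.01,
                      censor_q = NULL) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("S", seq_len(n)), paste0("V", seq_len(p))))
  if (is.null(beta)) beta <- rep(0, p)
  lp <- drop(x %*% beta)
  tt <- rexp(n, rate = lambda0 * exp(lp))
  if (is.null(censor_q)) {
    time <- tt
    event <- rep(1L, n)
  } else {
    admin <- unname(quantile(tt, censor_q))
    event <- as.integer(tt <= admin)
    time <- pmin(tt, admin)
  }
  list(ids = rownames(x), x = x, time = time, event = event, beta = beta)
}

test_that("fold assignment is seeded, stratified and order-invariant", {
  ft <- sim_table(50, 5, seed = 2, censor_q = 0.8)
  f1 <- make_folds(ft$ids, ft$event, k = 10, seed = 9)
  f2 <- make_folds(ft$ids, ft$event, k = 10, seed = 9)
  expect_identical(f1, f2)
  # every fold's training complement keeps at least one event
  for (k in 1:10) expect_gt(sum(ft$event[f1 != k]), 0)
  # permuting the rows permutes the assignment identically by id
  perm <- sample(50)
  f3 <- make_folds(ft$ids[perm], ft$event[perm], k = 10, seed = 9)
  expect_identical(f3[order(perm)], f1)
  expect_error(make_folds(ft$ids, ft$event, k = 1), class = "rw_schema_mismatch")
})

test_that("the penalty shrinks everything to zero at lambda_max, for every alpha", {
  ft <- sim_table(60, 10, beta = c(rep(0.8, 3), rep(0, 7)), seed = 3, censor_q = 0.8)
  for (a in c(0.01, 0.5, 0.99)) {
    fit <- fit_penalised_cox(ft, alpha = a, seed = 4)
    b_top <- as.numeric(coef(fit$cv$glmnet.fit, s = fit$lambda[1]))
    expect_true(all(b_top == 0))
    expect_true(fit$lambda_min %in% fit$lambda)
    expect_equal(fit$cvm[which(fit$lambda == fit$lambda_min)], min(fit$cvm))
  }
})

test_that("the lasso selects at most n variables before saturating", {
  ft <- sim_table(50, 66, beta = c(rep(0.6, 5), rep(0, 61)), seed = 5, censor_q = 0.8)
  fit <- suppressWarnings(fit_penalised_cox(ft, alpha = 0.99, seed = 6))
  expect_lte(length(fit$nonzero_set), 50)
})

test_that("with vanishing penalty the coefficients approach the Cox MLE", {
  ft <- sim_table(500, 2, beta = c(0.7, -0.4), seed = 7, lambda0 = 0.02)
  # an explicit grid reaching ~0 (the automatic path stops early once the
  # deviance saturates)
  fit <- fit_penalised_cox(ft, alpha = 0.5, seed = 8, thresh = 1e-14,
                           lambda = 10^seq(0, -6, by = -0.5))
  b_small <- as.numeric(coef(fit$cv$glmnet.fit, s = min(fit$lambda)))
  cph <- survival::coxph(survival::Surv(ft$time, ft$event) ~ ft$x, ties = "breslow")
  expect_equal(b_small, unname(coef(cph)), tolerance = 1e-3)
})

test_that("ridge-path coefficient norms grow as lambda decreases", {
  ft <- sim_table(80, 8, beta = rep(0.5, 8), seed = 9, censor_q = 0.9)
  fit <- fit_penalised_cox(ft, alpha = 0.01, seed = 10)
  l1 <- apply(as.matrix(fit$cv$glmnet.fit$beta), 2, function(b) sum(abs(b)))
  # lambda is decreasing along the path, so the L1 norm is non-decreasing
  expect_true(all(diff(l1) >= -1e-8))
})

test_that("degenerate inputs are rejected", {
  ft <- sim_table(30, 3, seed = 11, censor_q = 0.8)
  ft$x[, 2] <- 1
  expect_error(fit_penalised_cox(ft, 0.5), class = "rw_degenerate_feature")
  ft2 <- sim_table(30, 3, seed = 12)
  ft2$event[] <- 0L
  expect_error(fit_penalised_cox(ft2, 0.5), class = "rw_no_events")
  expect_error(fit_penalised_cox(sim_table(20, 2, seed = 13, censor_q = 0.8), 1.5),
               class = "rw_schema_mismatch")
})

test_that("out-of-fold hazards are blind, deterministic and order-invariant", {
  ft <- sim_table(40, 6, beta = c(1, -1, rep(0, 4)), seed = 14, censor_q = 0.85)
  h1 <- out_of_fold_hazards(ft, alpha = 0.99, folds = 5, seed = 15)
  expect_length(h1$hazard, 40)
  expect_false(anyNA(h1$hazard))
  expect_true(all(h1$hazard > 0))
  h2 <- out_of_fold_hazards(ft, alpha = 0.99, folds = 5, seed = 15)
  expect_identical(h1$hazard, h2$hazard)

  # permuting participants leaves each id's hazard unchanged
  perm <- sample(40)
  ftp <- list(ids = ft$ids[perm], x = ft$x[perm, ], time = ft$time[perm],
              event = ft$event[perm])
  h3 <- out_of_fold_hazards(ftp, alpha = 0.99, folds = 5, seed = 15)
  expect_equal(h3$hazard[ft$ids], h1$hazard)

  # blindness: a participant's fold model never saw their row; refitting the
  # training fold by hand reproduces their prediction
  f <- h1$foldid[1]
  tr <- h1$foldid != f
  sub <- list(ids = ft$ids[tr], x = ft$x[tr, ], time = ft$time[tr],
              event = ft$event[tr])
  refit <- fit_penalised_cox(sub, 0.99, folds = min(10, max(2, sum(sub$event))),
                             seed = 15 + f)
  expect_equal(unname(h1$hazard[1]),
               unname(exp(drop(ft$x[1, ] %*% refit$coefficients))))
})

test_that("a planted strong predictor is consistently selected; null data are not", {
  ft <- sim_table(120, 10, beta = c(2, rep(0, 9)), seed = 16, censor_q = 0.9)
  h <- out_of_fold_hazards(ft, alpha = 0.99, folds = 5, seed = 17)
  expect_true("V1" %in% h$consistent)
  expect_equal(unname(h$selection_count["V1"]), 5)

  # under the null, few if any variables survive every refit
  n_consistent <- vapply(1:3, function(s) {
    ftn <- sim_table(60, 10, seed = 20 + s, censor_q = 0.9)
    length(out_of_fold_hazards(ftn, alpha = 0.99, folds = 5, seed = s)$consistent)
  }, 0L)
  expect_lte(median(n_consistent), 1)
})

test_that("median-split evaluation separates by predicted hazard, ties low", {
  set.seed(30)
  time <- rexp(40, 0.01)
  event <- rep(1L, 40)
  hz <- c(rep(1, 10), rep(2, 10), rep(3, 20))
  res <- km_median_split_eval(hz, time, event)
  # median is 2.5 here: 20 low, 20 high
  expect_equal(as.vector(table(res$group)), c(20, 20))
  # exact ties at the median go to the low-hazard group
  hz2 <- c(rep(1, 10), rep(2, 15), rep(3, 15))
  res2 <- km_median_split_eval(hz2, time, event)
  expect_equal(unname(table(res2$group)["low"]), 40L - sum(hz2 > median(hz2)))
  expect_error(km_median_split_eval(rep(1, 40), time, event), class = "rw_all_tied")

  # identical survival in both groups: statistic exactly 0
  t2 <- rep(c(5, 10, 15, 20), 2)
  e2 <- rep(1L, 8)
  hz3 <- rep(c(1, 9), each = 4)
  res3 <- km_median_split_eval(hz3, t2, e2)
  expect_equal(res3$statistic, 0)
  expect_equal(res3$p, 1)
})

test_that("hazard-survival correlation matches the direct formula and sign logic", {
  set.seed(31)
  time <- sort(rexp(30, 0.01), decreasing = TRUE)
  hz <- rank(-time) + runif(30, 0, 0.01)    # near-inverse ranks
  res <- hazard_survival_correlation(hz, time)
  expect_lt(res$r, -0.9)
  expect_equal(res$r, cor(hz, time))
  expect_error(hazard_survival_correlation(rep(2, 30), time),
               class = "rw_zero_variance")

  # censored participants can be excluded
  ev <- rep(c(1L, 0L), 15)
  res2 <- hazard_survival_correlation(hz, time, ev, censored = "exclude")
  expect_equal(res2$r, cor(hz[ev == 1], time[ev == 1]))
})
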
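# Regularised Cox modelling: elastic-net penalised partial likelihood along
# a lambda path (glmnet), lambda chosen at the minimum mean cross-validated
# deviance (CVM), out-of-fold relative hazards with lambda re-selected
# inside each training set, selection-consistency counts, and the two
# evaluation statistics (median-split log-rank, hazard-survival Pearson r).

# run `code` under a local RNG stream without disturbing the caller's
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

#' Event-stratified cross-validation folds
#'
#' Assigns each participant to one of `k` folds, stratified by event status
#' so every training set contains events. The assignment is a function of
#' the participant ids and the seed, not of row order: permuting the rows
#' yields the same id-to-fold map.
#'
#' @param ids participant ids
#' @param event 0/1 event flags
#' @param k number of folds
#' @param seed integer seed
#' @return integer fold vector aligned with `ids`
#' @export
make_folds <- function(ids, event, k = 10, seed = 1) {
  if (k < 2 || k > length(ids)) rw_abort("folds must be in [2, n]", "rw_schema_mismatch")
  fold <- integer(length(ids))
  ord <- order(as.character(ids))
  with_seed(seed, {
    for (ev in c(0L, 1L)) {
      idx <- ord[event[ord] == ev]
      if (length(idx) == 0) next
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  fold
}

#' Fit a penalised Cox model with cross-validated lambda selection
#'
#' Maximises the elastic-net penalised Cox partial likelihood along a
#' decreasing lambda path (penalty alpha*L1 + (1-alpha)/2*L2 on
#' standardised coefficients), computes the mean cross-validated
#' partial-likelihood deviance (CVM) by event-stratified k-fold CV, and
#' returns the coefficients at the lambda minimising CVM. The study's three
#' settings are ridge alpha = 0.01, elastic net alpha = 0.5, lasso
#' alpha = 0.99.
#'
#' @param ft a `feature_table` (or list with x, time, event, ids)
#' @param alpha elastic-net mixing parameter in (0, 1]
#' @param folds number of CV folds (default 10)
#' @param seed seed for the fold assignment
#' @param nlambda lambda grid size (default 100)
#' @param lambda_min_ratio smallest lambda as a fraction of lambda_max
#' @param lambda optional explicit decreasing lambda grid; overrides
#'   `nlambda`/`lambda_min_ratio`
#' @param ... further arguments passed to [glmnet::cv.glmnet()] (e.g.
#'   `thresh` for a tighter convergence tolerance)
#' @return object of class `penalised_cox_fit`: alpha, lambda grid, cvm,
#'   lambda_min, coefficients (original scale), coefficients_std
#'   (standardised scale), nonzero_set, foldid
#' @export
fit_penalised_cox <- function(ft, alpha, folds = 10, seed = 1, nlambda = 100,
                              lambda_min_ratio = 1e-3, lambda = NULL, ...) {
  if (alpha <= 0 || alpha > 1) rw_abort("alpha must be in (0, 1]", "rw_schema_mismatch")
  x <- ft$x
  if (sum(ft$event) < 2) rw_abort("need at least 2 events", "rw_no_events")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    rw_abort(sprintf("zero-variance feature: %s", colnames(x)[which(sds == 0)[1]]),
             "rw_degenerate_feature")
  }
  y <- survival::Surv(ft$time, ft$event)
  foldid <- make_folds(ft$ids, ft$event, folds, seed)
  args <- list(x = x, y = y, family = "cox", alpha = alpha, foldid = foldid,
               type.measure = "deviance", standardize = TRUE, ...)
  if (is.null(lambda)) {
    args$nlambda <- nlambda
    args$lambda.min.ratio <- lambda_min_ratio
  } else {
    args$lambda <- lambda
  }
  cv <- with_seed(seed, do.call(glmnet::cv.glmnet, args))
  beta <- as.numeric(stats::coef(cv, s = "lambda.min"))
  names(beta) <- colnames(x)
  structure(list(alpha = alpha, lambda = cv$lambda, cvm = cv$cvm,
                 lambda_min = cv$lambda.min,
                 coefficients = beta,
                 coefficients_std = beta * sds,
                 nonzero_set = names(beta)[beta != 0],
                 foldid = foldid, cv = cv),
            class = "penalised_cox_fit")
}

#' @exportS3Method base::print
print.penalised_cox_fit <- function(x, ...) {
  cat(sprintf("<penalised_cox_fit> alpha=%.2f lambda_min=%.4g nonzero=%d/%d\n",
              x$alpha, x$lambda_min, length(x$nonzero_set), length(x$coefficients)))
  invisible(x)
}

#' Out-of-fold relative hazards and selection consistency
#'
#' For each of the k folds, refits the penalised Cox model on the other
#' k - 1 folds — re-selecting lambda by an inner cross-validation confined
#' to the training folds, so the held-out participants never influence
#' their own prediction — and predicts each held-out participant's relative
#' hazard exp(x'beta). A variable's selection count is the number of fold
#' refits in which its coefficient was nonzero; "consistently selected"
#' means selected in every refit. A final model fitted on all participants
#' is also returned, with its (in-sample) hazards, clearly labelled.
#'
#' @inheritParams fit_penalised_cox
#' @param inner_folds folds for the inner lambda-selection CV (default 10,
#'   capped at the training-set size)
#' @return object of class `cv_hazards`: hazard (out-of-fold, aligned with
#'   ids), foldid, selection_count, consistent (variable names),
#'   final_fit, final_hazard
#' @export
out_of_fold_hazards <- function(ft, alpha, folds = 10, seed = 1,
                                inner_folds = 10, nlambda = 100,
                                lambda_min_ratio = 1e-3) {
  x <- ft$x
  foldid <- make_folds(ft$ids, ft$event, folds, seed)
  hazard <- rep(NA_real_, nrow(x))
  sel <- matrix(FALSE, ncol(x), folds, dimnames = list(colnames(x), NULL))
  for (f in seq_len(folds)) {
    tr <- foldid != f
    sub <- list(ids = ft$ids[tr], x = x[tr, , drop = FALSE],
                time = ft$time[tr], event = ft$event[tr])
    fit <- fit_penalised_cox(sub, alpha,
                             folds = min(inner_folds, max(2, sum(sub$event))),
                             seed = seed + f, nlambda = nlambda,
                             lambda_min_ratio = lambda_min_ratio)
    sel[, f] <- fit$coefficients != 0
    lp <- drop(x[!tr, , drop = FALSE] %*% fit$coefficients)
    hazard[!tr] <- exp(lp)
  }
  final <- fit_penalised_cox(ft, alpha, folds = folds, seed = seed,
                             nlambda = nlambda, lambda_min_ratio = lambda_min_ratio)
  names(hazard) <- ft$ids
  counts <- rowSums(sel)
  structure(list(hazard = hazard, foldid = foldid,
                 selection_count = counts,
                 consistent = names(counts)[counts == folds],
                 final_fit = final,
                 final_hazard = stats::setNames(exp(drop(x %*% final$coefficients)), ft$ids)),
            class = "cv_hazards")
}

#' @exportS3Method base::print
print.cv_hazards <- function(x, ...) {
  cat(sprintf("<cv_hazards> %d participants, %d folds, %d consistently selected\n",
              length(x$hazard), max(x$foldid), length(x$consistent)))
  invisible(x)
}

#' Kaplan-Meier median-split evaluation of predicted hazards
#'
#' Splits participants at the median predicted hazard (ties go to the
#' low-hazard group), estimates a Kaplan-Meier curve per group and compares
#' them with the two-group log-rank test.
#'
#' @param hazard numeric vector of predicted relative hazards
#' @param time survival/censoring times in days
#' @param event 0/1 event flags
#' @return list: group factor ("low"/"high"), statistic, df, p, fit
#'   (a `survfit` object with both curves), median_hazard
#' @export
km_median_split_eval <- function(hazard, time, event) {
  if (length(hazard) < 4) rw_abort("need at least 4 participants", "rw_schema_mismatch")
  if (anyNA(hazard)) rw_abort("hazards must all be present", "rw_schema_mismatch")
  med <- stats::median(hazard)
  group <- factor(ifelse(hazard <= med, "low", "high"), levels = c("low", "high"))
  if (length(unique(group)) < 2) rw_abort("all hazards tied; no split possible", "rw_all_tied")
  lr <- log_rank(time, event, group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group)
  c(lr, list(group = group, fit = fit, median_hazard = med))
}

#' Pearson correlation between predicted hazard and observed survival
#'
#' Correlates each participant's predicted relative hazard with their
#' observed survival time in days. Censored participants enter at their
#' censoring time (set `censored = "exclude"` to use events only).
#'
#' @param hazard predicted relative hazards
#' @param time survival/censoring times in days
#' @param event 0/1 flags (needed only when `censored = "exclude"`)
#' @param censored "include" (default) or "exclude"
#' @return list with r and p
#' @export
hazard_survival_correlation <- function(hazard, time, event = NULL,
                                        censored = c("include", "exclude")) {
  censored <- match.arg(censored)
  if (censored == "exclude") {
    if (is.null(event)) rw_abort("event flags needed to exclude censored", "rw_schema_mismatch")
    keep <- event == 1
    hazard <- hazard[keep]
    time <- time[keep]
  }
  if (length(hazard) < 3) rw_abort("need at least 3 pairs", "rw_schema_mismatch")
  if (stats::sd(hazard) == 0 || stats::sd(time) == 0) {
    rw_abort("zero variance in hazard or survival", "rw_zero_variance")
  }
  ct <- stats::cor.test(hazard, time, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}
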
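# Independent brute-force oracles. Each recomputes a quantity from its
# definition by literal enumeration, never via the package's own code path.

# dichotomy index: literally count strict inequalities against the exact median
oracle_iless_o <- function(in_counts, out_counts, strict = TRUE) {
  med <- median(out_counts)
  hits <- if (strict) sum(in_counts < med) else sum(in_counts <= med)
  100 * hits / length(in_counts)
}

# two-pass product-moment correlation at lag `lag`, pairwise deletion
oracle_lag_cor <- function(x, lag = 1440) {
  n <- length(x)
  a <- x[1:(n - lag)]
  b <- x[(lag + 1):n]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  ma <- mean(a); mb <- mean(b)
  sum((a - ma) * (b - mb)) / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# per-epoch weighted window by direct summation over offsets; weights
# 0.04/0.2/1 are 1/25, 5/25, 25/25, so summing the 25-scaled integer terms
# keeps the tie W == threshold exact
oracle_sleep_labels <- function(counts, threshold = 40) {
  w25 <- c(1, 5, 25, 5, 1)
  n <- length(counts)
  sapply(seq_len(n), function(i) {
    W <- 0
    for (k in -2:2) {
      j <- i + k
      cj <- if (j < 1 || j > n || is.na(counts[j])) 0 else counts[j]
      W <- W + w25[k + 3] * cj
    }
    if (W <= 25 * threshold) "sleep" else "wake"
  })
}

# run-length extraction of night parameters (independent of rle())
oracle_night_params <- function(labels, onset_run = 10) {
  n <- length(labels)
  is_sleep <- labels == "sleep"
  run_start <- NA
  onset <- NA
  final_end <- NA
  i <- 1
  while (i <= n) {
    if (is_sleep[i]) {
      j <- i
      while (j <= n && is_sleep[j]) j <- j + 1
      if (j - i >= onset_run) {
        if (is.na(onset)) onset <- i
        final_end <- j - 1
      }
      i <- j
    } else i <- i + 1
  }
  if (is.na(onset)) return(NULL)
  win <- is_sleep[onset:final_end]
  n_bouts <- 0
  for (k in seq_along(win)) {
    if (!win[k] && (k == 1 || win[k - 1])) n_bouts <- n_bouts + 1
  }
  list(sol = onset - 1, tst = sum(win), waso = sum(!win), na = n_bouts,
       tib = n, se = 100 * sum(win) / n)
}

# product-limit estimator by direct product over event times
oracle_km <- function(time, event, t) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  for (tt in ut[ut <= t]) {
    at_risk <- sum(time >= tt)
    d <- sum(time == tt & event == 1)
    s <- s * (1 - d / at_risk)
  }
  s
}

# two-group log-rank by observed-minus-expected tabulation
oracle_logrank2 <- function(time, event, group) {
  g <- as.integer(factor(group))
  ut <- sort(unique(time[event == 1]))
  OE <- 0; V <- 0
  for (tt in ut) {
    n_at <- sum(time >= tt)
    n1 <- sum(time >= tt & g == 1)
    d <- sum(time == tt & event == 1)
    d1 <- sum(time == tt & event == 1 & g == 1)
    e1 <- d * n1 / n_at
    OE <- OE + (d1 - e1)
    if (n_at > 1) V <- V + d * (n1 / n_at) * (1 - n1 / n_at) * (n_at - d) / (n_at - 1)
  }
  OE^2 / V
}

# ICC(3,1) from a two-way ANOVA fit by aov()
oracle_icc3 <- function(mat) {
  df <- data.frame(y = as.vector(mat),
                   subj = factor(rep(seq_len(nrow(mat)), ncol(mat))),
                   day = factor(rep(seq_len(ncol(mat)), each = nrow(mat))))
  ms <- summary(aov(y ~ subj + day, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; mse <- ms[3]
  k <- ncol(mat)
  (msr - mse) / (msr + (k - 1) * mse)
}

# Spearman by rank transform then the Pearson formula
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}
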
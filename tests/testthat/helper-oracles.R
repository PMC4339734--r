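## Independent oracles used across the suite: deliberately naive, written
## from the definitions rather than sharing code with the implementation.

## Triple-loop evaluation of the per-band lagged product moment.
brute_autocorr <- function(A, max_lag, demean = TRUE) {
  K <- nrow(A); N <- ncol(A)
  if (demean) A <- A - rowMeans(A)
  r <- matrix(0, K, max_lag + 1)
  for (k in seq_len(K)) {
    for (t in 0:max_lag) {
      s <- 0
      for (n in seq_len(N - t)) s <- s + A[k, n] * A[k, n + t]
      r[k, t + 1] <- s / (N - t)
    }
  }
  r
}

## Exhaustive intra-class-variance minimizer over all midpoints between
## consecutive distinct sorted values.
brute_otsu <- function(x) {
  u <- sort(unique(x))
  mids <- (utils::head(u, -1) + utils::tail(u, -1)) / 2
  wiv <- vapply(mids, function(th) {
    a <- x[x <= th]; b <- x[x > th]
    (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / length(x)
  }, numeric(1))
  mids[which.min(wiv)]
}

## Rank-based pairwise-concordance AUC: P(stat_sleep < stat_wake) + ties/2,
## for a classifier that calls sleep when the statistic is below the cut.
concordance_auc <- function(stat, is_sleep) {
  s <- stat[is_sleep]; w <- stat[!is_sleep]
  cmp <- outer(s, w, function(a, b) (a < b) + 0.5 * (a == b))
  mean(cmp)
}

## Wrap a plain matrix as a spectrogram interval (hop chosen so lag indices
## equal frame indices when lag_s = hop_s * t).
as_spec <- function(A, hop_s = 0.03) {
  nightbreath:::new_spectrogram_interval(A, seq_len(nrow(A)), hop_s, 0.06,
                                         0, ncol(A) * hop_s)
}

## Short synthetic night with snappy defaults for pipeline tests.
quick_cfg <- function(seed, n_epochs = 10, ...) {
  sim_config(seed = seed, n_epochs = n_epochs, ...)
}

quick_night <- function(seed, n_epochs = 10, ...) {
  cfg <- quick_cfg(seed, n_epochs, ...)
  h <- simulate_hypnogram(cfg)
  c(synthesize_night(h, cfg), list(cfg = cfg, hypnogram = h))
}
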
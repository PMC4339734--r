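#' Epoch-by-epoch confusion counts
#'
#' Sleep is the positive class: TP = sleep predicted as sleep, TN = wake as
#' wake.
#'
#' @param pred,ref Hypnograms (or character vectors) of equal length.
#' @return List with `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(pred, ref) {
  p <- as.character(pred); r <- as.character(ref)
  if (length(p) != length(r)) stop("hypnogram lengths differ")
  list(tp = sum(p == "sleep" & r == "sleep"),
       tn = sum(p == "wake" & r == "wake"),
       fp = sum(p == "sleep" & r == "wake"),
       fn = sum(p == "wake" & r == "sleep"))
}

#' Agreement metrics from confusion counts
#'
#' Sensitivity, specificity, predictive values, accuracy, the chance
#' agreement `pe = ((tp+fn)(tp+fp) + (tn+fp)(tn+fn)) / n^2`, and Cohen's
#' kappa `(acu - pe) / (1 - pe)`. A metric whose denominator is zero (e.g.
#' specificity of a night with no reference wake) is returned as `NA`
#' rather than an error.
#'
#' @param cc Confusion counts from [confusion_counts()].
#' @return List with `sen`, `spc`, `ppv`, `npv`, `acu`, `pe`, `kappa`.
#' @export
epoch_metrics <- function(cc) {
  tp <- cc$tp; tn <- cc$tn; fp <- cc$fp; fn <- cc$fn
  n <- tp + tn + fp + fn
  if (n == 0) stop("no scored epochs")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  acu <- (tp + tn) / n
  pe <- ((tp + fn) * (tp + fp) + (tn + fp) * (tn + fn)) / n^2
  kappa <- if (pe < 1) (acu - pe) / (1 - pe) else NA_real_
  list(sen = ratio(tp, tp + fn), spc = ratio(tn, tn + fp),
       ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn),
       acu = acu, pe = pe, kappa = kappa)
}

#' Pooled and per-subject evaluation of predicted against reference
#' hypnograms
#'
#' @param pred_list,ref_list Lists of hypnograms, one element per subject.
#' @return List with `per_subject` (data frame, one row per subject; metrics
#'   undefined for a subject are NA and excluded from the means),
#'   `subject_mean`, and `pooled` (metrics over all epochs pooled).
#' @export
evaluate_subjects <- function(pred_list, ref_list) {
  stopifnot(length(pred_list) == length(ref_list), length(pred_list) >= 1)
  rows <- lapply(seq_along(pred_list), function(i) {
    as.data.frame(epoch_metrics(confusion_counts(pred_list[[i]],
                                                 ref_list[[i]])))
  })
  per_subject <- do.call(rbind, rows)
  pooled_cc <- Reduce(function(a, b) Map(`+`, a, b),
                      lapply(seq_along(pred_list), function(i) {
                        confusion_counts(pred_list[[i]], ref_list[[i]])
                      }))
  list(per_subject = per_subject,
       subject_mean = colMeans(per_subject, na.rm = TRUE),
       pooled = epoch_metrics(pooled_cc))
}

#' ROC curve and AUC over a threshold-offset sweep
#'
#' Sweeps a global additive offset applied to each subject's per-epoch
#' threshold profile — mirroring how the deployed decision rule operates —
#' and at each offset computes the pooled sleep-detection true-positive rate
#' against the false-positive rate. AUC is the trapezoidal area, oriented so
#' perfect separation gives 1. With `profiles = NULL` the sweep is over a
#' raw global threshold instead.
#'
#' @param swl_list List of `swl_curve`s (or numeric vectors).
#' @param ref_list List of reference hypnograms, matching lengths.
#' @param profiles List of `threshold_profile`s, or NULL for a raw sweep.
#' @return List with `points` (data frame `offset`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(swl_list, ref_list, profiles = NULL) {
  if (!is.list(swl_list)) swl_list <- list(swl_list)
  if (!is.list(ref_list) || inherits(ref_list, "hypnogram")) {
    ref_list <- list(ref_list)
  }
  stopifnot(length(swl_list) == length(ref_list))
  s <- unlist(lapply(seq_along(swl_list), function(i) {
    sc <- as.numeric(swl_list[[i]])
    if (is.null(profiles)) sc else sc - profiles[[i]]$per_epoch
  }))
  y <- unlist(lapply(ref_list, as.character))
  stopifnot(length(s) == length(y))
  is_sleep <- y == "sleep"
  n_pos <- sum(is_sleep); n_neg <- sum(!is_sleep)
  if (n_pos == 0 || n_neg == 0) stop("reference contains a single class")
  ## predict sleep when (score - threshold) < offset; sweep all cuts
  o <- order(s)
  ys <- is_sleep[o]
  tp <- cumsum(ys); fp <- cumsum(!ys)
  ## collapse tied score values to their last cumulative count
  sv <- s[o]
  last_of_run <- c(diff(sv) > 0, TRUE)
  tpr <- c(0, tp[last_of_run] / n_pos, 1)
  fpr <- c(0, fp[last_of_run] / n_neg, 1)
  offs <- c(-Inf, sv[last_of_run], Inf)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(offset = offs, fpr = fpr, tpr = tpr), auc = auc)
}

#' Bland-Altman agreement statistics
#'
#' Differences are audio-based minus reference (BSA - PSG); limits of
#' agreement are the mean difference +/- 1.96 standard deviations (n-1
#' denominator).
#'
#' @param bsa,psg Numeric vectors of per-subject parameter values (>= 2).
#' @return List with `mean_diff`, `sd_diff`, `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(bsa, psg) {
  stopifnot(length(bsa) == length(psg))
  if (length(bsa) < 2L) stop("need at least 2 pairs")
  d <- bsa - psg
  m <- mean(d); s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s,
       loa_low = m - 1.96 * s, loa_high = m + 1.96 * s, n = length(d))
}

#' Pearson correlation of per-subject agreement with a covariate
#'
#' @param kappa Per-subject kappa values (>= 3).
#' @param covariate Per-subject covariate (age, BMI, AHI, SNR, ...).
#' @return List with `r`, `p_value`, `n`.
#' @export
covariate_correlation <- function(kappa, covariate) {
  stopifnot(length(kappa) == length(covariate))
  if (length(kappa) < 3L) stop("need at least 3 pairs")
  if (stats::sd(covariate) == 0 || stats::sd(kappa) == 0) {
    stop("constant input: correlation undefined")
  }
  ct <- stats::cor.test(kappa, covariate, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(kappa))
}

#' Align the audio envelope to a reference intensity channel
#'
#' Both signals are resampled onto a common 15-ms grid over their time
#' ranges and the lag maximizing the normalized cross-correlation is
#' returned. A positive lag means the reference is delayed relative to the
#' audio. The result is always an integer multiple of the grid step.
#'
#' @param audio_env `energy_signal` of the audio.
#' @param ref_env Reference intensity: an `energy_signal`, or a list with
#'   `values` and either `times_s` or `dt_s` (+ optional `start_time_s`).
#' @param grid_s Alignment grid (default 0.015 s).
#' @param max_lag_s Largest |lag| searched (default 60 s).
#' @return Lag in seconds.
#' @export
align_to_reference <- function(audio_env, ref_env, grid_s = 0.015,
                               max_lag_s = 60) {
  a <- envelope_series(audio_env)
  r <- envelope_series(ref_env)
  t0 <- max(min(a$t), min(r$t))
  t1 <- min(max(a$t), max(r$t))
  if (t1 - t0 < 10) stop("overlap shorter than 10 s")
  grid <- seq(t0, t1, by = grid_s)
  av <- stats::approx(a$t, a$v, xout = grid, rule = 2)$y
  rv <- stats::approx(r$t, r$v, xout = grid, rule = 2)$y
  av <- av - mean(av); rv <- rv - mean(rv)
  max_lag <- min(length(grid) - 1L, round(max_lag_s / grid_s))
  lags <- -max_lag:max_lag
  cc <- vapply(lags, function(k) {
    if (k >= 0) {
      x <- av[seq_len(length(av) - k)]
      y <- rv[seq_len(length(rv) - k) + k]
    } else {
      x <- av[seq_len(length(av) + k) - k]
      y <- rv[seq_len(length(rv) + k)]
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(-Inf)
    stats::cor(x, y)
  }, numeric(1))
  lags[which.max(cc)] * grid_s
}

envelope_series <- function(e) {
  if (inherits(e, "energy_signal")) {
    return(list(t = frame_times(e), v = e$frame_db))
  }
  stopifnot(is.list(e), !is.null(e$values))
  if (!is.null(e$times_s)) return(list(t = e$times_s, v = e$values))
  stopifnot(!is.null(e$dt_s))
  st <- if (is.null(e$start_time_s)) 0 else e$start_time_s
  list(t = st + (seq_along(e$values) - 1L) * e$dt_s, v = e$values)
}
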
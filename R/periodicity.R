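#' Magnitude spectrogram of one analysis interval
#'
#' Short-time magnitude spectrum of a 12-s or 24-s interval: 60-ms Hann
#' frames, 30-ms hop. The rows (frequency bins) of this matrix are the
#' per-band series whose autocorrelation reveals the breathing cycle.
#'
#' @param signal A standardized [audio_signal()].
#' @param start_s Interval start, seconds from the signal start.
#' @param interval_len_s Interval length in seconds (12 or 24 in the
#'   pipeline; any positive length accepted).
#' @param frame_len_s,hop_s Framing (defaults 0.060 / 0.030 s).
#' @param max_freq_hz Optional band limit; bins above it are dropped.
#' @return A `spectrogram_interval`: list with magnitude matrix `x`
#'   (bins x frames), `freq_hz`, `hop_s`, `frame_len_s`, `start_s`,
#'   `interval_len_s`, `center_s`.
#' @export
interval_spectrogram <- function(signal, start_s, interval_len_s,
                                 frame_len_s = 0.060, hop_s = 0.030,
                                 max_freq_hz = NULL) {
  stopifnot(inherits(signal, "audio_signal"), interval_len_s > 0)
  fs <- signal$sample_rate_hz
  i0 <- round((start_s - signal$start_time_s) * fs) + 1L
  i1 <- i0 + round(interval_len_s * fs) - 1L
  if (i0 < 1L || i1 > length(signal$samples)) {
    stop("interval [", start_s, ", ", start_s + interval_len_s,
         "] s out of signal range")
  }
  sp <- stft_frames(signal$samples[i0:i1], fs, frame_len_s, hop_s,
                    complex = FALSE, max_freq_hz = max_freq_hz)
  new_spectrogram_interval(sp$x, sp$freq_hz, hop_s, frame_len_s, start_s,
                           interval_len_s)
}

new_spectrogram_interval <- function(x, freq_hz, hop_s, frame_len_s,
                                     start_s, interval_len_s) {
  structure(
    list(x = x, freq_hz = freq_hz, hop_s = hop_s, frame_len_s = frame_len_s,
         start_s = start_s, interval_len_s = interval_len_s,
         center_s = start_s + interval_len_s / 2),
    class = "spectrogram_interval"
  )
}

#' Per-frequency-band autocorrelation of an interval spectrogram
#'
#' For each frequency bin k, the lag-domain similarity of its magnitude
#' series: `R(k,t) = 1/(N-t) * sum_{n=1}^{N-t} X(k,n) X(k,n+t)`, computed for
#' lags `t = 0 ... max_lag` frames. By default each row is mean-removed
#' first, so that peak amplitudes are comparable across bands after zero-lag
#' normalization; `demean = FALSE` gives the raw product-moment form.
#'
#' @param spec A `spectrogram_interval`.
#' @param max_lag_s Maximum lag in seconds; must be below the interval
#'   length.
#' @param demean Remove each row's mean first (default TRUE).
#' @return An `autocorr_matrix`: list with matrix `r` (bins x lags, lag 0
#'   first), `lag_s` (lag spacing = frame hop), `freq_hz`.
#' @export
per_band_autocorr <- function(spec, max_lag_s, demean = TRUE) {
  stopifnot(inherits(spec, "spectrogram_interval"))
  A <- spec$x
  N <- ncol(A)
  Tmax <- round(max_lag_s / spec$hop_s)
  if (Tmax >= N) stop("max_lag_s too large for interval (", Tmax,
                      " lags >= ", N, " frames)")
  if (Tmax < 0) stop("max_lag_s must be non-negative")
  r <- if (ncol(A) >= 64L) {
    fft_autocorr_rows(A, Tmax, demean)
  } else {
    autocorr_rows(A, Tmax, demean)       # direct sum; cheaper when tiny
  }
  structure(list(r = r, lag_s = spec$hop_s, freq_hz = spec$freq_hz,
                 max_lag_frames = Tmax),
            class = "autocorr_matrix")
}

## FFT evaluation of the same lagged product moments: linear correlation via
## zero-padded transforms, packing row pairs into single complex FFTs in
## both directions (|FFT|^2 of real data is even, so its inverse transform
## is real and two spectra share one inverse). Equal to the direct sum to
## machine precision.
fft_autocorr_rows <- function(A, Tmax, demean) {
  N <- ncol(A)
  if (demean) A <- A - rowMeans(A)
  K <- nrow(A)
  p2 <- stats::nextn(N + Tmax)
  At <- rbind(t(A), matrix(0, p2 - N, K))
  Kp <- if (K %% 2L == 1L) K + 1L else K
  if (Kp > K) At <- cbind(At, 0)
  odd <- seq(1L, Kp, by = 2L)
  Z <- stats::mvfft(At[, odd, drop = FALSE] +
                      (0+1i) * At[, odd + 1L, drop = FALSE])
  Zr <- Z[c(1L, p2:2L), , drop = FALSE]
  Ssum <- Mod(Z)^2 + Mod(Zr)^2
  Sdif <- 2 * Re(Z * Zr)
  S <- matrix(0, p2, Kp)
  S[, odd] <- (Ssum + Sdif) / 4
  S[, odd + 1L] <- (Ssum - Sdif) / 4
  Wt <- stats::mvfft(S[, odd, drop = FALSE] +
                       (0+1i) * S[, odd + 1L, drop = FALSE],
                     inverse = TRUE) / p2
  sums <- matrix(0, Tmax + 1L, Kp)
  sums[, odd] <- Re(Wt[seq_len(Tmax + 1L), , drop = FALSE])
  sums[, odd + 1L] <- Im(Wt[seq_len(Tmax + 1L), , drop = FALSE])
  r <- t(sums[, seq_len(K), drop = FALSE])
  sweep(r, 2L, N - (0:Tmax), `/`)
}

## Positive local maxima of a lag series, restricted to index range
## idx_band (indices into r, 1 = zero lag). A peak strictly rises into its
## location; plateaus resolve to their first (smallest-lag) sample.
positive_peaks <- function(r, idx_band) {
  n <- length(r)
  if (n < 3L) return(integer(0))
  i <- 2:(n - 1L)
  pk <- i[r[i] > r[i - 1L] & r[i] >= r[i + 1L] & r[i] > 0]
  pk[pk %in% idx_band]
}

#' Emphasized autocorrelation of an interval
#'
#' Averages the most periodic frequency bands into a single lag function.
#' Each row of the autocorrelation matrix is normalized by its zero-lag
#' value, rows are ranked by the amplitude of their first positive peak
#' within the breathing-lag band, the top fraction (default the top 50%) is
#' averaged, and the average is renormalized so R(0) = 1.
#'
#' @param ac An `autocorr_matrix`.
#' @param top_fraction Fraction of rows kept (default 0.5).
#' @param band_s Lag band (seconds) searched for the first peak
#'   (default c(1.5, 10), i.e. 6-40 breathing cycles/min).
#' @return An `emphasized_autocorr`: list with `r` (lags, R(0) = 1 when
#'   valid), `lag_s`, `valid`, `selected` (row indices used).
#' @export
emphasize_autocorr <- function(ac, top_fraction = 0.5, band_s = c(1.5, 10)) {
  stopifnot(inherits(ac, "autocorr_matrix"),
            top_fraction > 0, top_fraction <= 1)
  R <- ac$r
  nl <- ncol(R)
  lags_s <- (0:(nl - 1L)) * ac$lag_s
  idx_band <- which(lags_s >= band_s[1] & lags_s <= band_s[2])
  r0 <- R[, 1L]
  ok <- is.finite(r0) & r0 > 0
  if (!any(ok)) {
    return(structure(list(r = rep(NA_real_, nl), lag_s = ac$lag_s,
                          valid = FALSE, selected = integer(0)),
                     class = "emphasized_autocorr"))
  }
  Rok <- R[ok, , drop = FALSE]
  r0ok <- r0[ok]
  lo <- if (length(idx_band)) min(idx_band) - 1L else 1L
  hi <- if (length(idx_band)) max(idx_band) - 1L else 0L
  first_amp <- first_peak_amp(Rok, r0ok, lo, hi)
  n_keep <- max(1L, ceiling(top_fraction * nrow(Rok)))
  sel <- order(first_amp, decreasing = TRUE)[seq_len(n_keep)]
  avg <- colMeans(Rok[sel, , drop = FALSE] / r0ok[sel])
  if (!is.finite(avg[1L]) || avg[1L] <= 0) {
    return(structure(list(r = rep(NA_real_, nl), lag_s = ac$lag_s,
                          valid = FALSE, selected = integer(0)),
                     class = "emphasized_autocorr"))
  }
  structure(list(r = avg / avg[1L], lag_s = ac$lag_s, valid = TRUE,
                 selected = which(ok)[sel]),
            class = "emphasized_autocorr")
}

#' Breathing-cycle features of an interval
#'
#' From the emphasized autocorrelation: cycle period CP = lag of the first
#' positive peak (zero lag excluded); cycle intensity CI = the peak's
#' amplitude, clamped to \[0, 1\]; cycle consistency CC = standard deviation
#' of the successive differences of all positive-peak lags in the band
#' (0 when the peaks are equally spaced — the more repetitive the interval,
#' the lower CC).
#'
#' @param eac An `emphasized_autocorr`.
#' @param band_s Lag band searched for peaks (seconds).
#' @return List with `cp_s`, `ci`, `cc`, `valid`.
#' @export
extract_cycle_features <- function(eac, band_s = c(1.5, 10)) {
  stopifnot(inherits(eac, "emphasized_autocorr"))
  invalid <- list(cp_s = NA_real_, ci = NA_real_, cc = NA_real_, valid = FALSE)
  if (!isTRUE(eac$valid)) return(invalid)
  r <- eac$r
  lags_s <- (seq_along(r) - 1L) * eac$lag_s
  idx_band <- which(lags_s >= band_s[1] & lags_s <= band_s[2])
  pk <- positive_peaks(r, idx_band)
  if (!length(pk)) return(invalid)
  ## sub-grid peak locations by 3-point parabolic interpolation: removes the
  ## lag-quantization floor and the downward bias of flat peak tops
  lag_ref <- vapply(pk, function(i) {
    num <- r[i - 1L] - r[i + 1L]
    den <- r[i - 1L] - 2 * r[i] + r[i + 1L]
    delta <- if (den != 0) 0.5 * num / den else 0
    (i - 1L + min(max(delta, -0.5), 0.5)) * eac$lag_s
  }, numeric(1))
  cp_s <- lag_ref[1L]
  ci <- min(max(r[pk[1L]], 0), 1)
  d <- diff(lag_ref)
  cc <- if (length(d) >= 2L) stats::sd(d) else 0
  list(cp_s = cp_s, ci = ci, cc = cc, valid = TRUE)
}

#' Resample a time-stamped feature series onto the 30-s epoch grid
#'
#' Linear interpolation evaluated at each epoch center (15 s, 45 s, ...);
#' ends are clamped to the nearest valid value and non-finite entries are
#' skipped before interpolating.
#'
#' @param times_s Time stamps of the feature values, seconds.
#' @param values Feature values (non-finite entries are dropped).
#' @param n_epochs Number of 30-s epochs on the output grid.
#' @param epoch_len_s Epoch length (default 30).
#' @return Numeric vector of length `n_epochs`.
#' @export
features_to_epoch_grid <- function(times_s, values, n_epochs,
                                   epoch_len_s = 30) {
  stopifnot(length(times_s) == length(values), n_epochs >= 1)
  ok <- is.finite(values) & is.finite(times_s)
  if (!any(ok)) stop("no valid feature values to interpolate")
  t <- times_s[ok]; v <- values[ok]
  centers <- (seq_len(n_epochs) - 0.5) * epoch_len_s
  if (length(v) == 1L) return(rep(v, n_epochs))
  o <- order(t)
  stats::approx(t[o], v[o], xout = centers, rule = 2, ties = "ordered")$y
}

#' Breathing-pattern features for a whole night
#'
#' Runs the interval pipeline (spectrogram, per-band autocorrelation,
#' emphasis, cycle features) over non-overlapping 12-s and 24-s intervals
#' and interpolates the six series onto the 30-s epoch grid. When a
#' precomputed whole-night short-time magnitude matrix is supplied (e.g.
#' the enhanced spectrogram from [spectral_subtract()]), intervals are
#' sliced from it instead of re-analyzing the waveform.
#'
#' @param signal Enhanced, standardized [audio_signal()].
#' @param cfg Settings: `interval_lens_s` (c(12, 24)), `band_s` (c(1.5, 10)),
#'   `max_lag_s` (10), `max_freq_hz` (3000), `top_fraction` (0.5),
#'   `epoch_len_s` (30).
#' @param stft Optional precomputed night STFT: list with `mag`
#'   (bins x frames), `freq_hz`, `frame_len_s`, `hop_s`.
#' @return Data frame with `n_epochs` rows and columns `cp12`, `ci12`,
#'   `cc12`, `cp24`, `ci24`, `cc24`.
#' @export
breathing_features <- function(signal, cfg = list(), stft = NULL) {
  d <- list(interval_lens_s = c(12, 24), band_s = c(1.5, 10), max_lag_s = 10,
            max_freq_hz = 3000, top_fraction = 0.5, epoch_len_s = 30)
  cfg <- utils::modifyList(d, cfg)
  dur <- audio_duration(signal)
  n_epochs <- floor(dur / cfg$epoch_len_s)
  stopifnot(n_epochs >= 1)
  if (is.null(stft)) {
    stft <- stft_frames(signal$samples, signal$sample_rate_hz,
                        complex = FALSE, max_freq_hz = cfg$max_freq_hz)
    stft$mag <- stft$x
  }
  hop <- stft$hop_s
  out <- data.frame(row.names = seq_len(n_epochs))
  for (ilen in cfg$interval_lens_s) {
    starts <- seq(0, dur - ilen, by = ilen)
    centers <- starts + ilen / 2
    n_frames <- floor((ilen - stft$frame_len_s) / hop) + 1L
    feats <- lapply(starts, function(s0) {
      fr0 <- round(s0 / hop) + 1L
      fr1 <- min(ncol(stft$mag), fr0 + n_frames - 1L)
      sp <- new_spectrogram_interval(stft$mag[, fr0:fr1, drop = FALSE],
                                     stft$freq_hz, hop, stft$frame_len_s,
                                     s0, ilen)
      ac <- per_band_autocorr(sp, cfg$max_lag_s)
      eac <- emphasize_autocorr(ac, cfg$top_fraction, cfg$band_s)
      extract_cycle_features(eac, cfg$band_s)
    })
    tag <- as.character(round(ilen))
    for (f in c("cp_s", "ci", "cc")) {
      v <- vapply(feats, function(x) if (isTRUE(x$valid)) x[[f]] else NA_real_,
                  numeric(1))
      col <- paste0(c(cp_s = "cp", ci = "ci", cc = "cc")[[f]], tag)
      out[[col]] <- features_to_epoch_grid(centers, v, n_epochs,
                                           cfg$epoch_len_s)
    }
  }
  out
}
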
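## Short-time analysis helpers -------------------------------------------------

hann_window <- function(L) 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / L)

## Windowed frame matrix (L x n_frames) for frames starting at 0-based sample
## offsets `starts`.
frame_matrix <- function(x, starts, L, window = NULL) {
  idx <- outer(seq_len(L), starts, `+`)
  m <- matrix(x[idx], nrow = L)
  if (!is.null(window)) m <- m * window
  m
}

## Magnitude (or complex) STFT of a vector: 60-ms Hann frames by default.
## Returns bins x frames, non-negative frequencies only.
stft_frames <- function(x, fs, frame_len_s = 0.060, hop_s = 0.030,
                        complex = FALSE, max_freq_hz = NULL) {
  L <- round(frame_len_s * fs)
  H <- round(hop_s * fs)
  n <- length(x)
  nbins <- L %/% 2L + 1L
  if (n < L) {
    return(list(x = matrix(0, nbins, 0), freq_hz = (0:(nbins - 1)) * fs / L,
                frame_len_s = frame_len_s, hop_s = hop_s))
  }
  m <- (n - L) %/% H + 1L
  starts <- (seq_len(m) - 1L) * H
  f <- stats::mvfft(frame_matrix(x, starts, L, hann_window(L)))[seq_len(nbins), , drop = FALSE]
  freq <- (0:(nbins - 1)) * fs / L
  if (!is.null(max_freq_hz)) {
    keep <- freq <= max_freq_hz
    f <- f[keep, , drop = FALSE]
    freq <- freq[keep]
  }
  list(x = if (complex) f else Mod(f), freq_hz = freq,
       frame_len_s = frame_len_s, hop_s = hop_s)
}

#' Wiener-type spectral-subtraction noise suppression
#'
#' Suppresses stationary background noise (fans, air conditioning) while
#' preserving intermittent breathing sounds. The background spectrum is
#' tracked automatically and adaptively as the per-bin low quantile of the
#' short-time power spectrum over a sliding window, and removed with a
#' floored Wiener-type gain. Analysis uses 60-ms Hann frames at 50% overlap
#' with overlap-add reconstruction, so output length and rate equal the
#' input's. Pairs of frames share one complex FFT in each direction
#' (real-signal Hermitian packing), which roughly halves the transform cost
#' over a whole night.
#'
#' Because the tracker defines "background" as whatever is spectrally
#' stationary over the window, sustained constant tones are treated as
#' noise; breathing events, which occupy well under half of each window,
#' are not.
#'
#' @param signal A standardized (16 kHz) [audio_signal()].
#' @param cfg Settings: `frame_len_s` (0.060), `noise_window_s` (30, sliding
#'   window for noise tracking), `update_s` (5, tracker update interval),
#'   `noise_quantile` (0.10), `oversubtraction` (2.5, multiplier on the
#'   estimated noise power), `gain_floor` (0.05, minimum amplitude gain).
#' @param return_stft Also return the modified short-time magnitudes
#'   (the enhanced spectrogram) up to `stft_max_freq_hz`, for reuse by the
#'   feature stage without a second analysis pass.
#' @param stft_max_freq_hz Band limit of the returned magnitudes (default
#'   3000).
#' @return Enhanced [audio_signal()] of identical length and rate; or, with
#'   `return_stft = TRUE`, a list with `audio`, `mag` (bins x frames),
#'   `freq_hz`, `frame_len_s`, `hop_s`.
#' @export
spectral_subtract <- function(signal, cfg = list(), return_stft = FALSE,
                              stft_max_freq_hz = 3000) {
  stopifnot(inherits(signal, "audio_signal"))
  d <- list(frame_len_s = 0.060, noise_window_s = 30, update_s = 5,
            noise_quantile = 0.10, oversubtraction = 2.5, gain_floor = 0.05)
  cfg <- utils::modifyList(d, cfg)
  fs <- signal$sample_rate_hz
  x <- signal$samples
  n <- length(x)
  L <- round(cfg$frame_len_s * fs)
  H <- L %/% 2L
  hop_s <- H / fs
  if (n < L) {
    warning("signal shorter than one analysis window; returned unchanged")
    if (!return_stft) return(signal)
    return(list(audio = signal, mag = matrix(0, 0, 0), freq_hz = numeric(0),
                frame_len_s = cfg$frame_len_s, hop_s = hop_s))
  }
  w <- hann_window(L)
  B <- L %/% 2L + 1L                                   # non-negative bins
  M <- (n - L) %/% H + 1L
  U <- max(1L, round(cfg$update_s / hop_s))            # frames per update
  n_hist <- max(1L, ceiling(cfg$noise_window_s / cfg$update_s))
  ## exponential-tail calibration: the q-quantile of Exp(mean lambda) is
  ## -lambda*log(1-q); divide by that factor to recover lambda
  cal <- 1 / (-log(1 - cfg$noise_quantile))
  q <- cfg$noise_quantile
  a <- cfg$oversubtraction
  gmin <- cfg$gain_floor

  keep_feat <- NULL
  mag_out <- NULL
  if (return_stft) {
    freq <- (0:(B - 1)) * fs / L
    keep_feat <- which(freq <= stft_max_freq_hz)
    mag_out <- matrix(0, length(keep_feat), M)
  }

  out <- numeric(n)
  ## noise-history ring stored frames x bins (quantile selection runs down
  ## contiguous columns), holding every fourth frame of the sliding window:
  ## 50%-overlapped neighbors are highly redundant for a quantile, and ~250
  ## retained frames still put the 10th percentile on the ~25th order
  ## statistic
  ring_stride <- 4L
  hist_ring <- matrix(0, max(1L, (U * n_hist) %/% ring_stride), B)
  ring_pos <- 0L
  ring_fill <- 0L
  lambda <- NULL
  block_frames <- 2400L
  f0 <- 1L
  while (f0 <= M) {
    f1 <- min(M, f0 + block_frames - 1L)
    nb <- f1 - f0 + 1L
    starts0 <- (f0:f1 - 1L) * H                        # 0-based sample offsets
    Z <- stats::mvfft(pack_frames(x, starts0, w))
    P <- packed_power(Z, B)                            # B x (2 * npairs)
    ## per-segment noise tracking and gain (half-spectrum), causal updates
    G <- matrix(gmin, B, ncol(P))
    for (s0 in seq(1L, nb, by = U)) {
      s1 <- min(nb, s0 + U - 1L)
      if (is.null(lambda)) {
        lambda <- row_quantiles(P[, s0:s1, drop = FALSE], q) * cal
      }
      segment_gain(P, G, s0 - 1L, s1 - 1L, lambda, a, gmin)
      st <- ring_push(hist_ring, P, s0 - 1L, s1 - 1L, ring_pos, ring_fill,
                      ring_stride)
      ring_pos <- st[1L]; ring_fill <- st[2L]
      lambda <- col_quantiles(hist_ring, ring_fill, q) * cal
    }
    if (return_stft) {
      mag_out[, f0:f1] <- (G[keep_feat, seq_len(nb), drop = FALSE] *
                             sqrt(P[keep_feat, seq_len(nb), drop = FALSE]))
    }
    Yt <- stats::mvfft(packed_gain(Z, G), inverse = TRUE) / L
    ola_add(out, Yt, starts0)
    f0 <- f1 + 1L
  }
  ## window-sum compensation: the interior sums to exactly 1 (periodic Hann,
  ## 50% overlap); blend the original back in at the edges and the
  ## frame-uncovered tail
  e1 <- seq_len(H)
  out[e1] <- out[e1] + (1 - w[e1]) * x[e1]
  lastL <- (M - 1L) * H
  e2 <- (lastL + H + 1L):(lastL + L)
  out[e2] <- out[e2] + (1 - w[(H + 1L):L]) * x[e2]
  if (lastL + L < n) {
    tail_idx <- (lastL + L + 1L):n
    out[tail_idx] <- x[tail_idx]
  }
  audio <- audio_signal(out, fs, signal$start_time_s)
  if (!return_stft) return(audio)
  list(audio = audio, mag = mag_out,
       freq_hz = ((0:(B - 1)) * fs / L)[keep_feat],
       frame_len_s = cfg$frame_len_s, hop_s = hop_s)
}
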
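#' Detect energetic acoustic events from an energy envelope
#'
#' Surrogate breathing-sound event detector: events are maximal runs of
#' frames whose energy exceeds a rolling noise floor by a margin. Runs closer
#' than `merge_gap_s` are merged and runs shorter than `min_dur_s` are
#' discarded. The noise floor is the rolling 10th percentile of the frame
#' energies over a sliding window. An externally produced event list (CSV)
#' can be used in place of this detector throughout the pipeline.
#'
#' @param env An `energy_signal` computed after noise suppression.
#' @param cfg Settings: `margin_db` (6), `merge_gap_s` (0.1), `min_dur_s`
#'   (0.2), `floor_window_s` (30), `floor_quantile` (0.1),
#'   `floor_update_s` (5).
#' @return A data frame of class `acoustic_events` with columns `start_s`,
#'   `end_s`, `peak_db`, `sls` (NA until scored); attribute
#'   `noise_floor_db` holds the median rolling floor.
#' @export
detect_events <- function(env, cfg = list()) {
  stopifnot(inherits(env, "energy_signal"))
  d <- list(margin_db = 6, merge_gap_s = 0.1, min_dur_s = 0.2,
            floor_window_s = 30, floor_quantile = 0.1, floor_update_s = 5)
  cfg <- utils::modifyList(d, cfg)
  fdb <- env$frame_db
  m <- length(fdb)
  if (m == 0L) return(empty_events(NA_real_))
  floor_per_frame <- rolling_floor(fdb, env$hop_s, cfg$floor_window_s,
                                   cfg$floor_quantile, cfg$floor_update_s)
  active <- fdb > floor_per_frame + cfg$margin_db
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  if (!length(on)) return(empty_events(stats::median(floor_per_frame)))
  ev_start <- starts[on]
  ev_end <- ends[on]
  ## merge runs separated by a short gap
  if (length(ev_start) > 1L) {
    gap_s <- (ev_start[-1L] - 1L - ev_end[-length(ev_end)]) * env$hop_s
    keep_new <- c(TRUE, gap_s >= cfg$merge_gap_s)
    grp <- cumsum(keep_new)
    ev_start <- tapply(ev_start, grp, min)
    ev_end <- tapply(ev_end, grp, max)
  }
  start_s <- env$start_time_s + (ev_start - 1L) * env$hop_s
  end_s <- env$start_time_s + (ev_end - 1L) * env$hop_s + env$frame_len_s
  dur_ok <- (end_s - start_s) >= cfg$min_dur_s
  start_s <- start_s[dur_ok]; end_s <- end_s[dur_ok]
  ev_start <- ev_start[dur_ok]; ev_end <- ev_end[dur_ok]
  if (!length(start_s)) return(empty_events(stats::median(floor_per_frame)))
  peak_db <- mapply(function(a, b) max(fdb[a:b]), ev_start, ev_end)
  ev <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   peak_db = as.numeric(peak_db), sls = NA_real_)
  class(ev) <- c("acoustic_events", "data.frame")
  attr(ev, "noise_floor_db") <- stats::median(floor_per_frame)
  ev
}

.filter_cache <- new.env(parent = emptyenv())

empty_events <- function(floor_db) {
  ev <- data.frame(start_s = numeric(0), end_s = numeric(0),
                   peak_db = numeric(0), sls = numeric(0))
  class(ev) <- c("acoustic_events", "data.frame")
  attr(ev, "noise_floor_db") <- floor_db
  ev
}

## Rolling low-quantile of the frame-energy series: evaluated on a coarse
## update grid over a centered sliding window, then linearly interpolated to
## every frame.
rolling_floor <- function(fdb, hop_s, window_s, q, update_s) {
  m <- length(fdb)
  half <- max(1L, round(window_s / hop_s / 2))
  step <- max(1L, round(update_s / hop_s))
  at <- unique(c(seq(1L, m, by = step), m))
  vals <- vapply(at, function(i) {
    stats::quantile(fdb[max(1L, i - half):min(m, i + half)], q, names = FALSE)
  }, numeric(1))
  if (length(at) == 1L) return(rep(vals, m))
  stats::approx(at, vals, xout = seq_len(m), rule = 2)$y
}

#' Snore-likelihood score (SLS) for one acoustic event
#'
#' Surrogate scorer: a weighted sum of (i) the harmonicity of the event's
#' low-frequency content, measured as the maximum normalized autocorrelation
#' of the low-passed waveform over candidate glottal periods, and (ii) the
#' event's level above the noise floor, minus a calibration offset. Positive
#' scores indicate snore-like events (strong low-frequency harmonic
#' structure at high level); plain breaths score negative. Level enters only
#' relative to the noise floor, so the score is invariant to a global gain
#' change of the recording.
#'
#' @param signal The enhanced [audio_signal()].
#' @param event One-row event (needs `start_s`, `end_s`, `peak_db`).
#' @param cfg Settings: `w_harm` (4), `w_level_per_db` (0.05), `offset`
#'   (2.5), `lowpass_hz` (1000), `f0_range_hz` (c(60, 200)),
#'   `noise_floor_db` (required), `max_scored_s` (3).
#' @return A single numeric SLS.
#' @export
score_sls <- function(signal, event, cfg = list()) {
  stopifnot(inherits(signal, "audio_signal"))
  d <- list(w_harm = 4, w_level_per_db = 0.05, offset = 2.5,
            lowpass_hz = 1000, f0_range_hz = c(60, 200),
            noise_floor_db = NULL, max_scored_s = 3)
  cfg <- utils::modifyList(d, cfg)
  if (is.null(cfg$noise_floor_db)) stop("cfg$noise_floor_db is required")
  fs <- signal$sample_rate_hz
  i0 <- max(1L, floor((event$start_s - signal$start_time_s) * fs) + 1L)
  i1 <- min(length(signal$samples),
            ceiling((event$end_s - signal$start_time_s) * fs))
  if (i1 <= i0) stop("degenerate (zero-length) event")
  i1 <- min(i1, i0 + round(cfg$max_scored_s * fs))
  x <- signal$samples[i0:i1]
  harm <- lowband_harmonicity(x, fs, cfg$lowpass_hz, cfg$f0_range_hz)
  level <- cfg$w_level_per_db * (event$peak_db - cfg$noise_floor_db)
  cfg$w_harm * harm + level - cfg$offset
}

## Max normalized autocorrelation of the low-passed event waveform over lags
## corresponding to f0_range; ~1 for a harmonic (voiced/snore-like) event,
## near 0 for band-limited breath noise. After low-pass filtering the
## waveform is decimated to 4 kHz (well above twice the cutoff), which makes
## the lag scan cheap without moving the autocorrelation peak.
lowband_harmonicity <- function(x, fs, lowpass_hz, f0_range_hz) {
  x <- x - mean(x)
  if (length(x) < 4L || all(x == 0)) return(0)
  key <- paste0(fs, ":", lowpass_hz)
  bf <- .filter_cache[[key]]
  if (is.null(bf)) {
    bf <- signal::butter(4, lowpass_hz / (fs / 2), type = "low")
    .filter_cache[[key]] <- bf
  }
  y <- iir_filter(bf$b, bf$a, x)
  dec <- max(1L, floor(fs / (4 * lowpass_hz)))
  if (dec > 1L) y <- y[seq(1L, length(y), by = dec)]
  fs2 <- fs / dec
  lag_min <- max(2L, floor(fs2 / f0_range_hz[2]))
  lag_max <- ceiling(fs2 / f0_range_hz[1])
  if (lag_max >= length(y)) return(0)
  ac <- autocorr_rows(matrix(y, nrow = 1L), lag_max, FALSE)[1L, ]
  if (ac[1] <= 0) return(0)
  max(ac[(lag_min + 1L):(lag_max + 1L)]) / ac[1]
}

#' Score all events of a night
#'
#' Fills the `sls` column of an event list, deriving the noise floor from the
#' envelope when not supplied.
#'
#' @param signal Enhanced [audio_signal()].
#' @param events `acoustic_events` from [detect_events()].
#' @param cfg See [score_sls()]; `noise_floor_db` defaults to the detection
#'   floor attribute.
#' @return `events` with `sls` filled.
#' @export
score_events <- function(signal, events, cfg = list()) {
  if (is.null(cfg$noise_floor_db)) {
    cfg$noise_floor_db <- attr(events, "noise_floor_db")
  }
  if (nrow(events) == 0L) return(events)
  events$sls <- vapply(seq_len(nrow(events)), function(i) {
    score_sls(signal, events[i, ], cfg)
  }, numeric(1))
  events
}

#' Breathing signal-to-noise estimate
#'
#' Mean event peak level above the noise floor (10th percentile of the frame
#' energies), in dB.
#'
#' @param env `energy_signal`.
#' @param events `acoustic_events`; at least one event required.
#' @return List with `breathing_snr_db` and `noise_floor_db`.
#' @export
estimate_snr <- function(env, events) {
  stopifnot(inherits(env, "energy_signal"))
  if (nrow(events) == 0L) stop("no breathing detected (empty event list)")
  noise_floor_db <- stats::quantile(env$frame_db, 0.1, names = FALSE)
  list(breathing_snr_db = mean(events$peak_db) - noise_floor_db,
       noise_floor_db = noise_floor_db)
}

#' Read / write an event list as CSV
#'
#' Columns: `start_s`, `end_s`, `peak_db`, `sls`. Allows injecting an
#' external detector's output into the pipeline.
#'
#' @param path CSV path.
#' @return For `read_events`, an `acoustic_events` data frame.
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path)
  need <- c("start_s", "end_s", "peak_db", "sls")
  if (!all(need %in% names(ev))) {
    stop("event CSV must have columns: ", paste(need, collapse = ", "))
  }
  ev <- ev[order(ev$start_s), need]
  class(ev) <- c("acoustic_events", "data.frame")
  ev
}

#' @rdname read_events
#' @param events `acoustic_events`.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events)[, c("start_s", "end_s", "peak_db", "sls")],
                   path, row.names = FALSE)
  invisible(path)
}
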
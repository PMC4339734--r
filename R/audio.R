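#' Construct an audio signal object
#'
#' A mono PCM signal: amplitudes in \[-1, 1\] at a known sampling rate.
#' All internal processing runs at the canonical 16 kHz rate (see
#' [standardize_audio()]).
#'
#' @param samples Numeric vector of amplitudes.
#' @param sample_rate_hz Positive sampling rate in Hz.
#' @param start_time_s Time offset of the first sample, seconds.
#' @return An object of class `audio_signal`.
#' @export
audio_signal <- function(samples, sample_rate_hz, start_time_s = 0) {
  stopifnot(is.numeric(samples), length(sample_rate_hz) == 1L,
            sample_rate_hz > 0, is.finite(start_time_s))
  structure(
    list(samples = as.numeric(samples),
         sample_rate_hz = as.numeric(sample_rate_hz),
         start_time_s = as.numeric(start_time_s)),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal> %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$sample_rate_hz,
              length(x$samples) / x$sample_rate_hz))
  invisible(x)
}

#' Duration of an audio signal in seconds
#' @param signal An `audio_signal`.
#' @return Duration in seconds.
#' @export
audio_duration <- function(signal) {
  length(signal$samples) / signal$sample_rate_hz
}

## ---- WAV I/O ----------------------------------------------------------------
## Minimal RIFF/WAVE reader and writer (PCM 8/16/24/32-bit and IEEE float).
## No WAV-capable package is available as a dependency, so the container is
## parsed directly; only uncompressed encodings are supported.

#' Read a WAV file
#'
#' Reads a PCM or IEEE-float WAV file. Multi-channel files are averaged to
#' mono; amplitudes are scaled to \[-1, 1\]. The original sampling rate is
#' preserved (use [standardize_audio()] to resample to 16 kHz).
#'
#' @param path Path to a WAV file.
#' @return An [audio_signal()].
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        audio_format = sum(as.integer(body[1:2]) * c(1L, 256L)),
        n_channels   = sum(as.integer(body[3:4]) * c(1L, 256L)),
        sample_rate  = sum(as.integer(body[5:8]) * 256^(0:3)),
        bits         = sum(as.integer(body[15:16]) * c(1L, 256L))
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
    if (size %% 2 == 1) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("corrupt WAV (missing chunk): ", path)
  if (fmt$audio_format == 65534 && fmt$bits %in% c(16L, 24L, 32L)) {
    fmt$audio_format <- 1L  # WAVE_FORMAT_EXTENSIBLE carrying PCM
  }

  if (fmt$audio_format == 1L) {          # integer PCM
    if (fmt$bits == 16L) {
      x <- readBin(data_raw, "integer", length(data_raw) %/% 2L, 2L,
                   signed = TRUE, endian = "little") / 32768
    } else if (fmt$bits == 8L) {
      x <- (as.integer(readBin(data_raw, "raw", length(data_raw))) - 128) / 128
    } else if (fmt$bits == 32L) {
      x <- readBin(data_raw, "integer", length(data_raw) %/% 4L, 4L,
                   signed = TRUE, endian = "little") / 2147483648
    } else if (fmt$bits == 24L) {
      b <- as.integer(data_raw)
      n <- length(b) %/% 3L
      v <- b[seq(1L, 3L * n, 3L)] + 256 * b[seq(2L, 3L * n, 3L)] +
        65536 * b[seq(3L, 3L * n, 3L)]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      x <- v / 8388608
    } else stop("unsupported PCM bit depth: ", fmt$bits)
  } else if (fmt$audio_format == 3L) {   # IEEE float
    if (fmt$bits == 32L) {
      x <- readBin(data_raw, "double", length(data_raw) %/% 4L, 4L,
                   endian = "little")
    } else if (fmt$bits == 64L) {
      x <- readBin(data_raw, "double", length(data_raw) %/% 8L, 8L,
                   endian = "little")
    } else stop("unsupported float bit depth: ", fmt$bits)
  } else {
    stop("unsupported WAV encoding (format tag ", fmt$audio_format, ")")
  }

  if (fmt$n_channels > 1L) {
    n <- length(x) %/% fmt$n_channels
    x <- rowMeans(matrix(x[seq_len(n * fmt$n_channels)],
                         nrow = n, byrow = TRUE))
  }
  audio_signal(x, fmt$sample_rate)
}

#' Write a WAV file
#'
#' @param signal An [audio_signal()].
#' @param path Output path.
#' @param bits 16 (PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, bits = 16L) {
  stopifnot(inherits(signal, "audio_signal"), bits %in% c(16L, 32L))
  x <- signal$samples
  fs <- as.integer(round(signal$sample_rate_hz))
  bytes_per <- bits %/% 8L
  data_size <- length(x) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  fmt_tag <- if (bits == 16L) 1L else 3L
  writeBin(fmt_tag, con, 2L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")                 # mono
  writeBin(fs, con, 4L, endian = "little")
  writeBin(as.integer(fs * bytes_per), con, 4L, endian = "little")
  writeBin(as.integer(bytes_per), con, 2L, endian = "little")
  writeBin(as.integer(bits), con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4L, endian = "little")
  ## convert and write in chunks: whole-night vectors would otherwise cost
  ## several transient full-length copies
  chunk <- 4000000L
  i <- 1L
  while (i <= length(x)) {
    j <- min(length(x), i + chunk - 1L)
    xi <- pmin(pmax(x[i:j], -1), 1)
    if (bits == 16L) {
      writeBin(as.integer(pmin(pmax(round(xi * 32768), -32768), 32767)),
               con, 2L, endian = "little")
    } else {
      writeBin(as.numeric(xi), con, 4L, endian = "little")
    }
    i <- j + 1L
  }
  invisible(path)
}

#' Resample an audio signal to the canonical 16 kHz rate
#'
#' Band-limited polyphase resampling; signals already at the target rate are
#' returned unchanged. Duration is preserved to within one sample period.
#'
#' @param signal An [audio_signal()].
#' @param target_rate_hz Target rate, default 16000.
#' @return An [audio_signal()] at `target_rate_hz`.
#' @export
standardize_audio <- function(signal, target_rate_hz = 16000) {
  stopifnot(inherits(signal, "audio_signal"))
  fs <- signal$sample_rate_hz
  if (fs == target_rate_hz) return(signal)
  if (length(signal$samples) == 0L) {
    return(audio_signal(numeric(0), target_rate_hz, signal$start_time_s))
  }
  g <- gcd_int(round(target_rate_hz), round(fs))
  p <- round(target_rate_hz) %/% g
  q <- round(fs) %/% g
  y <- signal::resample(signal$samples, p, q)
  n_out <- round(length(signal$samples) * target_rate_hz / fs)
  if (length(y) >= n_out) y <- y[seq_len(n_out)] else y <- c(y, rep(0, n_out - length(y)))
  audio_signal(y, target_rate_hz, signal$start_time_s)
}

gcd_int <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' Running energy envelope in dB
#'
#' Frame-wise mean-square energy: `frame_db[m] = 10*log10(meansq(frame) + eps)`.
#' Silence maps to `floor_db` exactly (eps = 10^(floor_db/10)).
#'
#' @param signal An [audio_signal()].
#' @param frame_len_s Frame length, seconds (default 0.060).
#' @param hop_s Hop between frames, seconds (default 0.030).
#' @param floor_db Value assigned to silent frames (default -120).
#' @return An `energy_signal`: list with `frame_db`, `frame_len_s`, `hop_s`,
#'   `floor_db`, `sample_rate_hz`, `start_time_s`.
#' @export
energy_envelope <- function(signal, frame_len_s = 0.060, hop_s = 0.030,
                            floor_db = -120) {
  stopifnot(inherits(signal, "audio_signal"), frame_len_s > 0, hop_s > 0,
            hop_s <= frame_len_s)
  fs <- signal$sample_rate_hz
  L <- round(frame_len_s * fs)
  H <- round(hop_s * fs)
  x <- signal$samples
  n <- length(x)
  eps <- 10^(floor_db / 10)
  if (n < L) {
    frame_db <- numeric(0)
  } else {
    frame_db <- 10 * log10(frame_msq(x, L, H) + eps)
  }
  structure(
    list(frame_db = frame_db, frame_len_s = frame_len_s, hop_s = hop_s,
         floor_db = floor_db, sample_rate_hz = fs,
         start_time_s = signal$start_time_s),
    class = "energy_signal"
  )
}

#' @export
print.energy_signal <- function(x, ...) {
  cat(sprintf("<energy_signal> %d frames (%.0f ms / %.0f ms hop)\n",
              length(x$frame_db), x$frame_len_s * 1000, x$hop_s * 1000))
  invisible(x)
}

#' Frame center times of an energy envelope
#' @param env An `energy_signal`.
#' @return Numeric vector of frame-center times in seconds.
#' @export
frame_times <- function(env) {
  stopifnot(inherits(env, "energy_signal"))
  env$start_time_s + (seq_along(env$frame_db) - 1L) * env$hop_s +
    env$frame_len_s / 2
}
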
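test_that("WAV round trip preserves samples to 16-bit quantization", {
  withr::with_seed(1, x <- runif(16000, -0.9, 0.9))
  sig <- audio_signal(x, 16000)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(sig, path)
  back <- read_wav(path)
  expect_equal(back$sample_rate_hz, 16000)
  expect_equal(length(back$samples), 16000)
  expect_lt(max(abs(back$samples - x)), 2^-15)
})

test_that("silence reads back as silence and float WAVs are exact", {
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(audio_signal(numeric(16000), 16000), path)
  z <- read_wav(path)
  expect_true(all(z$samples == 0))
  withr::with_seed(2, x <- runif(5000, -1, 1))
  write_wav(audio_signal(x, 8000), path, bits = 32L)
  back <- read_wav(path)
  expect_equal(back$sample_rate_hz, 8000)
  expect_lt(max(abs(back$samples - x)), 1e-6)
})

test_that("a 440 Hz sine fixture is recovered at the right DFT bin", {
  fs <- 16000
  t <- (0:(fs - 1)) / fs
  sig <- audio_signal(0.5 * sin(2 * pi * 440 * t), fs)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(sig, path)
  x <- read_wav(path)$samples
  spec <- Mod(fft(x))[1:(fs / 2)]
  peak_hz <- which.max(spec) - 1          # 1-s signal: bin index = Hz
  expect_lte(abs(peak_hz - 440), 1)
})

test_that("read_wav rejects missing and corrupt files", {
  expect_error(read_wav(file.path(tempdir(), "nope.wav")), "not found")
  bad <- withr::local_tempfile(fileext = ".wav")
  writeBin(as.raw(1:40), bad)
  expect_error(read_wav(bad))
})

test_that("multi-channel WAVs are averaged to mono", {
  ## hand-build a 2-channel PCM WAV with L = 0.5, R = -0.5
  path <- withr::local_tempfile(fileext = ".wav")
  con <- file(path, "wb")
  n <- 100L
  writeChar("RIFF", con, eos = NULL)
  writeBin(36L + n * 4L, con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL); writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(1L, con, 2L, endian = "little")
  writeBin(2L, con, 2L, endian = "little")
  writeBin(8000L, con, 4L, endian = "little")
  writeBin(8000L * 4L, con, 4L, endian = "little")
  writeBin(4L, con, 2L, endian = "little")
  writeBin(16L, con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n * 4L, con, 4L, endian = "little")
  writeBin(rep(c(16384L, -16384L), n), con, 2L, endian = "little")
  close(con)
  sig <- read_wav(path)
  expect_equal(length(sig$samples), n)
  expect_true(all(abs(sig$samples) < 1e-4))
})

test_that("standardization resamples to 16 kHz, preserving duration and tone", {
  sig16 <- audio_signal(sin(2 * pi * 100 * (0:15999) / 16000), 16000)
  expect_identical(standardize_audio(sig16), sig16)

  withr::with_seed(3, x48 <- rnorm(48000))
  out <- standardize_audio(audio_signal(x48, 48000))
  expect_equal(out$sample_rate_hz, 16000)
  expect_lte(abs(length(out$samples) - 16000), 1)

  fs <- 8000
  tone <- audio_signal(sin(2 * pi * 1000 * (0:(fs - 1)) / fs), fs)
  up <- standardize_audio(tone)
  spec <- Mod(fft(up$samples))[1:8000]
  expect_lte(abs((which.max(spec) - 1) - 1000), 1)
  expect_equal(length(standardize_audio(audio_signal(numeric(0), 44100))$samples), 0)
})

test_that("energy envelope matches its closed form and a brute-force oracle", {
  fs <- 16000
  env <- energy_envelope(audio_signal(rep(0.1, fs), fs))
  expect_equal(env$frame_db, rep(10 * log10(0.01 + 1e-12), length(env$frame_db)))
  expect_equal(length(env$frame_db), floor((fs - 960) / 480) + 1)

  silent <- energy_envelope(audio_signal(numeric(fs), fs))
  expect_true(all(silent$frame_db == -120))

  withr::with_seed(4, x <- rnorm(8000) * 0.05)
  env <- energy_envelope(audio_signal(x, fs))
  brute <- vapply(seq_along(env$frame_db), function(m) {
    fr <- x[(m - 1) * 480 + 1:960]
    10 * log10(mean(fr^2) + 1e-12)
  }, numeric(1))
  expect_lt(max(abs(env$frame_db - brute)), 1e-9)
})

test_that("envelope is unchanged by sub-quantization perturbations", {
  fs <- 16000
  withr::with_seed(5, x <- rnorm(fs) * 0.1)
  withr::with_seed(6, d <- runif(fs, -1, 1) * 1e-9)
  e1 <- energy_envelope(audio_signal(x, fs))
  e2 <- energy_envelope(audio_signal(x + d - mean(d), fs))
  expect_lt(max(abs(e1$frame_db - e2$frame_db)), 1e-4)
})
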
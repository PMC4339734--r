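## Build an energy_signal directly from a dB vector.
as_env <- function(frame_db, hop_s = 0.03, frame_len_s = 0.06) {
  structure(list(frame_db = frame_db, frame_len_s = frame_len_s,
                 hop_s = hop_s, floor_db = -120, sample_rate_hz = 16000,
                 start_time_s = 0),
            class = "energy_signal")
}

## Unimodal burst pattern over a -60 dB floor.
burst_env <- function(burst_starts_s, burst_dur_s = 0.5, level_db = -40,
                      total_s = 60) {
  m <- round(total_s / 0.03)
  fdb <- rep(-60, m)
  for (b in burst_starts_s) {
    i0 <- round(b / 0.03) + 1
    i1 <- min(m, i0 + round(burst_dur_s / 0.03))
    fdb[i0:i1] <- level_db
  }
  as_env(fdb)
}

test_that("silence yields no events; clear bursts are each found once", {
  expect_equal(nrow(detect_events(as_env(rep(-120, 2000)))), 0)
  ev <- detect_events(burst_env(c(10, 15, 20)))
  expect_equal(nrow(ev), 3)
  for (i in 1:3) {
    expect_lt(ev$start_s[i], c(10, 15, 20)[i] + 0.1)
    expect_gt(ev$end_s[i], c(10, 15, 20)[i] + 0.3)
  }
  expect_true(all(diff(ev$start_s) > 0))
})

test_that("bursts closer than the merge gap fuse into one event", {
  ## two bursts 50 ms apart with merge_gap = 100 ms
  ev <- detect_events(burst_env(c(10, 10.55), burst_dur_s = 0.5),
                      cfg = list(merge_gap_s = 0.1))
  expect_equal(nrow(ev), 1)
  ev2 <- detect_events(burst_env(c(10, 11)), cfg = list(merge_gap_s = 0.1))
  expect_equal(nrow(ev2), 2)
})

test_that("raising the margin never increases the event count", {
  night <- quick_night(seed = 31, n_epochs = 6)
  env <- energy_envelope(spectral_subtract(night$audio))
  counts <- vapply(c(3, 6, 10, 14, 18), function(m) {
    nrow(detect_events(env, cfg = list(margin_db = m)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detected event count matches simulator ground truth within 10%", {
  for (snr in c(15, 20)) {
    night <- quick_night(seed = 32 + snr, n_epochs = 10,
                         background_snr_db = snr)
    env <- energy_envelope(spectral_subtract(night$audio))
    ev <- detect_events(env)
    n_true <- nrow(night$truth$events)
    expect_lte(abs(nrow(ev) - n_true) / n_true, 0.10)
  }
})

test_that("SLS separates harmonic snore-like events from breath noise", {
  fs <- 16000
  t <- (0:(fs - 1)) / fs
  stack <- rowSums(sapply(1:6, function(k) sin(2 * pi * k * 80 * t) / k))
  snore <- audio_signal(0.3 * stack / max(abs(stack)), fs)
  ev <- data.frame(start_s = 0, end_s = 1, peak_db = -20, sls = NA)
  s_snore <- score_sls(snore, ev[1, ], cfg = list(noise_floor_db = -40))
  expect_gt(s_snore, 0)

  withr::with_seed(7, nz <- rnorm(fs))
  bf <- signal::butter(4, c(300, 3000) / (fs / 2), type = "pass")
  breath <- audio_signal(0.02 * as.numeric(signal::filter(bf, nz)), fs)
  ev$peak_db <- -34
  s_breath <- score_sls(breath, ev[1, ], cfg = list(noise_floor_db = -40))
  expect_lt(s_breath, 0)

  expect_error(score_sls(snore, data.frame(start_s = 0.5, end_s = 0.5,
                                           peak_db = -20, sls = NA),
                         cfg = list(noise_floor_db = -40)),
               "degenerate")
})

test_that("on a simulated night >= 90% of snores and breaths score correctly", {
  night <- quick_night(seed = 33, n_epochs = 10, p_stay_sleep = 1)
  enh <- spectral_subtract(night$audio)
  env <- energy_envelope(enh)
  ev <- score_events(enh, detect_events(env))
  tru <- night$truth$events
  mid <- (ev$start_s + ev$end_s) / 2
  truth_type <- vapply(mid, function(m) {
    i <- which(tru$start_s <= m & tru$end_s >= m)
    if (length(i)) tru$type[i[1]] else NA_character_
  }, character(1))
  snore <- !is.na(truth_type) & truth_type == "snore"
  breath <- !is.na(truth_type) & truth_type == "breath"
  expect_gte(mean(ev$sls[snore] > 0), 0.9)
  expect_gte(mean(ev$sls[breath] < 0), 0.9)
})

test_that("SLS is invariant to a global gain change of the whole night", {
  night <- quick_night(seed = 34, n_epochs = 4)
  enh <- spectral_subtract(night$audio)
  env <- energy_envelope(enh)
  ev <- detect_events(env)[1:3, ]
  floor_db <- attr(detect_events(env), "noise_floor_db")

  gain_db <- -12
  scaled <- audio_signal(enh$samples * 10^(gain_db / 20), 16000)
  s1 <- vapply(1:3, function(i) {
    score_sls(enh, ev[i, ], cfg = list(noise_floor_db = floor_db))
  }, numeric(1))
  ev2 <- ev
  ev2$peak_db <- ev$peak_db + gain_db
  s2 <- vapply(1:3, function(i) {
    score_sls(scaled, ev2[i, ], cfg = list(noise_floor_db = floor_db + gain_db))
  }, numeric(1))
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("breathing SNR is estimated from events over the noise floor", {
  env <- as_env(c(rep(-60, 500), rep(-40, 20), rep(-60, 500)))
  ev <- detect_events(env, cfg = list(margin_db = 6))
  est <- estimate_snr(env, ev)
  expect_equal(est$breathing_snr_db, 20, tolerance = 1)
  expect_error(estimate_snr(env, detect_events(as_env(rep(-120, 100)))),
               "no breathing")
})

test_that("configured simulator SNR is recovered within 3 dB", {
  night <- quick_night(seed = 35, n_epochs = 10, background_snr_db = 15)
  env <- energy_envelope(night$audio)   # raw envelope reflects the mix SNR
  ev <- detect_events(env)
  est <- estimate_snr(env, ev)
  expect_lte(abs(est$breathing_snr_db - 15), 3)
})

test_that("event lists survive a CSV round trip", {
  ev <- data.frame(start_s = c(1, 5), end_s = c(1.8, 5.7),
                   peak_db = c(-30, -28), sls = c(1.2, -0.5))
  class(ev) <- c("acoustic_events", "data.frame")
  path <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, path)
  back <- read_events(path)
  expect_equal(as.data.frame(back), as.data.frame(ev), tolerance = 1e-12)
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("start_s,end_s", empty)     # wrong schema
  expect_error(read_events(empty), "columns")
})
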
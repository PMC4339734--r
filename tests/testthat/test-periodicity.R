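test_that("interval spectrogram concentrates a pure tone in its bin", {
  fs <- 16000
  t <- (0:(fs * 12 - 1)) / fs
  sig <- audio_signal(sin(2 * pi * 1000 * t), fs)
  sp <- interval_spectrogram(sig, 0, 12)
  peak_bins <- apply(sp$x, 2, which.max)
  expect_true(all(sp$freq_hz[peak_bins] == 1000))
  ## frame-to-frame stability of the tone's magnitude
  tone_row <- sp$x[which(sp$freq_hz == 1000), ]
  expect_lt(sd(tone_row) / mean(tone_row), 0.01)

  silent <- interval_spectrogram(audio_signal(numeric(fs * 12), fs), 0, 12)
  expect_true(all(silent$x == 0))
  expect_error(interval_spectrogram(sig, 6, 12), "out of")
})

test_that("interval spectrogram equals a direct frame-by-frame DFT", {
  fs <- 16000
  withr::with_seed(11, x <- rnorm(fs * 2) * 0.1)
  sp <- interval_spectrogram(audio_signal(x, fs), 0, 2)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:959) / 960)
  direct <- sapply(seq_len(ncol(sp$x)), function(m) {
    fr <- x[(m - 1) * 480 + 1:960] * w
    Mod(fft(fr))[1:481]
  })
  expect_lt(max(abs(sp$x - direct)), 1e-9)
})

test_that("per-band autocorrelation matches hand and brute-force evaluation", {
  ## hand example, raw form: row [1,2,3,4]
  sp <- as_spec(matrix(c(1, 2, 3, 4), 1, 4), hop_s = 1)
  ac <- per_band_autocorr(sp, 2, demean = FALSE)
  expect_equal(ac$r[1, ], c(7.5, 20 / 3, 5.5))

  ## lag 0 is the mean square of each row
  withr::with_seed(12, A <- matrix(abs(rnorm(5 * 30)), 5, 30))
  ac0 <- per_band_autocorr(as_spec(A), 0.3, demean = FALSE)
  expect_equal(ac0$r[, 1], rowMeans(A^2))

  ## brute-force equivalence with mean removal, odd and even row counts
  for (K in c(16, 17)) {
    withr::with_seed(K, A <- matrix(abs(rnorm(K * 64)), K, 64))
    ac <- per_band_autocorr(as_spec(A), 20 * 0.03, demean = TRUE)
    expect_lt(max(abs(ac$r - brute_autocorr(A, 20))), 1e-9)
  }

  expect_error(per_band_autocorr(as_spec(A), 64 * 0.03), "too large")
})

test_that("a cosine row autocorrelates maximally at its period", {
  P <- 8
  row <- cos(2 * pi * (0:199) / P)
  ac <- per_band_autocorr(as_spec(matrix(row, 1), hop_s = 1), 30)
  r <- ac$r[1, -1]                        # exclude zero lag
  expect_equal(which.max(r[1:12]), P)
})

test_that("emphasis selects the periodic rows and averages them", {
  n <- 400
  P <- 100                                 # 3 s at 30-ms lag resolution
  periodic <- cos(2 * pi * (0:(n - 1)) / P)
  withr::with_seed(13, {
    rows <- rbind(
      t(sapply(1:5, function(i) periodic + rnorm(n) * 0.05)),
      t(sapply(1:5, function(i) rnorm(n)))
    )
  })
  ac <- per_band_autocorr(as_spec(rows), 10)
  eac <- emphasize_autocorr(ac, top_fraction = 0.5)
  expect_true(eac$valid)
  expect_setequal(eac$selected, 1:5)
  expect_equal(eac$r[1], 1)
  pk <- nightbreath:::positive_peaks(eac$r, seq_along(eac$r))
  expect_lte(abs(pk[1] - 1 - P), 2)      # noise can nudge the flat peak top

  ## all rows identical: the average equals any single normalized row
  same <- matrix(rep(periodic, 6), 6, byrow = TRUE)
  ac2 <- per_band_autocorr(as_spec(same), 10)
  e2 <- emphasize_autocorr(ac2, 0.5)
  expect_equal(e2$r, ac2$r[1, ] / ac2$r[1, 1], tolerance = 1e-9)

  ## top_fraction = 1 is the plain mean of normalized rows
  e_all <- emphasize_autocorr(ac, 1.0)
  rn <- ac$r / ac$r[, 1]
  expect_equal(e_all$r, colMeans(rn) / mean(rn[, 1]), tolerance = 1e-9)

  ## degenerate all-zero matrix flags invalid
  z <- per_band_autocorr(as_spec(matrix(0, 4, 50)), 0.5)
  expect_false(emphasize_autocorr(z)$valid)
})

test_that("cycle features recover period, intensity, and consistency", {
  lag_s <- 0.03
  lags <- (0:400) * lag_s
  P <- 4.02                                # a multiple of the lag grid
  eac <- structure(list(r = cos(2 * pi * lags / P), lag_s = lag_s,
                        valid = TRUE, selected = 1L),
                   class = "emphasized_autocorr")
  cf <- extract_cycle_features(eac)
  expect_true(cf$valid)
  expect_equal(cf$cp_s, P)
  expect_equal(cf$ci, 1, tolerance = 1e-9)
  expect_equal(cf$cc, 0, tolerance = 1e-9)

  mono <- structure(list(r = exp(-lags), lag_s = lag_s, valid = TRUE,
                         selected = 1L), class = "emphasized_autocorr")
  expect_false(extract_cycle_features(mono)$valid)
})

test_that("simulated 4-s sleep breathing yields CP near 4 s", {
  h <- hypnogram(rep("sleep", 2))
  cfg <- sim_config(seed = 41, n_epochs = 2, background_snr_db = 20,
                    sleep_period_s = c(4.0, 0.05))
  night <- synthesize_night(h, cfg)
  enh <- spectral_subtract(night$audio)
  sp <- interval_spectrogram(enh, 12, 12, max_freq_hz = 3000)
  eac <- emphasize_autocorr(per_band_autocorr(sp, 10))
  cf <- extract_cycle_features(eac)
  expect_true(cf$valid)
  expect_lte(abs(cf$cp_s - 4.0), 0.2)
})

test_that("CP is invariant to global amplitude scaling; CI stays in [0,1]", {
  night <- quick_night(seed = 42, n_epochs = 2, p_stay_sleep = 1)
  enh <- spectral_subtract(night$audio)
  cf_of <- function(sig) {
    sp <- interval_spectrogram(sig, 12, 12, max_freq_hz = 3000)
    extract_cycle_features(emphasize_autocorr(per_band_autocorr(sp, 10)))
  }
  a <- cf_of(enh)
  b <- cf_of(audio_signal(enh$samples * 0.1, 16000))
  expect_equal(a$cp_s, b$cp_s)
  expect_gte(a$ci, 0); expect_lte(a$ci, 1)
})

test_that("more period jitter raises cycle consistency", {
  cc_at <- function(sd_s, seed) {
    h <- hypnogram(rep("sleep", 4))
    cfg <- sim_config(seed = seed, n_epochs = 4,
                      sleep_period_s = c(4.0, sd_s), snore_prob = 0)
    night <- synthesize_night(h, cfg)
    enh <- spectral_subtract(night$audio)
    f <- breathing_features(enh)
    mean(f$cc12)
  }
  seeds <- 71:76
  wins <- vapply(seeds, function(s) cc_at(0, s) < cc_at(0.5, s), logical(1))
  expect_gte(mean(wins), 5 / 6)
})

test_that("epoch-grid interpolation is linear with clamped ends", {
  expect_equal(features_to_epoch_grid(c(0, 60), c(0, 60), 2), c(15, 45))
  expect_equal(features_to_epoch_grid(c(10, 50), c(3, 3), 4), rep(3, 4))
  withr::with_seed(14, {
    t <- sort(runif(20, 0, 300))
    v <- rnorm(20)
  })
  got <- features_to_epoch_grid(t, v, 10)
  oracle <- vapply((1:10 - 0.5) * 30, function(x) {
    if (x <= t[1]) return(v[1])
    if (x >= t[20]) return(v[20])
    i <- findInterval(x, t)
    v[i] + (v[i + 1] - v[i]) * (x - t[i]) / (t[i + 1] - t[i])
  }, numeric(1))
  expect_lt(max(abs(got - oracle)), 1e-12)
  expect_error(features_to_epoch_grid(1, NA_real_, 4), "no valid")
})

test_that("12-s and 24-s feature streams share the epoch grid length", {
  night <- quick_night(seed = 43, n_epochs = 4)
  f <- breathing_features(spectral_subtract(night$audio))
  expect_equal(nrow(f), 4)
  expect_named(f, c("cp12", "ci12", "cc12", "cp24", "ci24", "cc24"))
  expect_true(all(is.finite(as.matrix(f))))
})
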
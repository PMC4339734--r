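#' Simulation configuration
#'
#' Settings for the seeded synthetic-night generators. The acoustic model
#' encodes the physiology the system exploits: during sleep, breathing is
#' more energetic, more periodic and snore-prone; during wake it is
#' quieter and irregular, with sporadic movement noise.
#'
#' @param seed Integer seed; all generators are pure functions of
#'   (config, seed).
#' @param n_epochs Number of 30-s epochs (default 240, a 2-h night).
#' @param p_stay_sleep,p_stay_wake Markov self-transition probabilities per
#'   epoch (defaults 0.95 / 0.85, about 25% wake in the long run).
#' @param sleep_period_s,wake_period_s Breathing period mean and sd in each
#'   state (defaults c(4.0, 0.15) and c(3.5, 1.2)).
#' @param snore_prob Probability a sleep breath is a snore (default 0.3).
#' @param snore_f0_hz Snore fundamental-frequency range (default 80-150 Hz).
#' @param breath_level_db Sleep breath peak level, dBFS (default -20).
#' @param wake_level_drop_db Level drop of wake breaths, dB (default 6).
#' @param movement_rate_per_min Movement bursts per wake minute (default 2).
#' @param background_snr_db Breath peak over stationary background, dB
#'   (default 20).
#' @param sample_rate_hz Sampling rate (default 16000).
#' @param keep_clean Keep the pre-noise clean waveform in the ground truth
#'   (default TRUE; disable for long nights to save memory).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_epochs = 240L,
                       p_stay_sleep = 0.95, p_stay_wake = 0.85,
                       sleep_period_s = c(4.0, 0.15),
                       wake_period_s = c(3.5, 1.2),
                       snore_prob = 0.3, snore_f0_hz = c(80, 150),
                       breath_level_db = -20, wake_level_drop_db = 6,
                       movement_rate_per_min = 2, background_snr_db = 20,
                       sample_rate_hz = 16000, keep_clean = TRUE) {
  cfg <- list(seed = as.integer(seed), n_epochs = as.integer(n_epochs),
              p_stay_sleep = p_stay_sleep, p_stay_wake = p_stay_wake,
              sleep_period_s = sleep_period_s, wake_period_s = wake_period_s,
              snore_prob = snore_prob, snore_f0_hz = snore_f0_hz,
              breath_level_db = breath_level_db,
              wake_level_drop_db = wake_level_drop_db,
              movement_rate_per_min = movement_rate_per_min,
              background_snr_db = background_snr_db,
              sample_rate_hz = sample_rate_hz, keep_clean = keep_clean)
  stopifnot(cfg$n_epochs >= 1,
            cfg$p_stay_sleep >= 0, cfg$p_stay_sleep <= 1,
            cfg$p_stay_wake >= 0, cfg$p_stay_wake <= 1,
            cfg$snore_prob >= 0, cfg$snore_prob <= 1,
            cfg$sleep_period_s[2] >= 0, cfg$wake_period_s[2] >= 0)
  structure(cfg, class = "sim_config")
}

#' Simulate a two-state sleep/wake hypnogram
#'
#' A Markov chain over 30-s epochs starting in wake, so the initial wake run
#' (the simulated sleep latency) is geometric with continuation probability
#' `p_stay_wake`.
#'
#' @param cfg A [sim_config()].
#' @return A [hypnogram()], reproducible from `cfg$seed`.
#' @export
simulate_hypnogram <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    n <- cfg$n_epochs
    lab <- character(n)
    state <- "wake"
    u <- stats::runif(n)
    for (i in seq_len(n)) {
      lab[i] <- state
      stay <- if (state == "sleep") cfg$p_stay_sleep else cfg$p_stay_wake
      if (u[i] > stay) state <- if (state == "sleep") "wake" else "sleep"
    }
    hypnogram(lab)
  })
}

#' Synthesize whole-night breathing audio over a hypnogram
#'
#' Breath events are placed sequentially with state-dependent periods
#' (regular in sleep, jittered in wake). Each breath is band-limited
#' (300-3000 Hz) noise under a 0.8-s raised-cosine envelope (0.4-s inhale
#' rise). Sleep breaths become snores with probability `snore_prob`, adding
#' a 6-partial harmonic stack at a fundamental drawn from `snore_f0_hz`.
#' Wake epochs drop the breath level and add sporadic 0.5-s broadband
#' movement bursts. Stationary white background noise is mixed so that
#' breath peaks sit `background_snr_db` above it. Bit-exact reproducible
#' from the seed.
#'
#' @param h A [hypnogram()] (typically from [simulate_hypnogram()]).
#' @param cfg A [sim_config()].
#' @return List with `audio` (the noisy [audio_signal()]) and `truth`:
#'   `hypnogram`, `events` (data frame `start_s`, `end_s`, `peak_db`,
#'   `is_snore`, `type`), and `clean_audio` (NULL when
#'   `cfg$keep_clean = FALSE`).
#' @export
synthesize_night <- function(h, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  fs <- cfg$sample_rate_hz
  el <- attr(h, "epoch_len_s")
  n_ep <- length(h)
  dur <- n_ep * el
  n <- as.integer(round(dur * fs))
  a_sleep <- 10^(cfg$breath_level_db / 20)
  a_wake <- a_sleep * 10^(-cfg$wake_level_drop_db / 20)
  breath_dur <- 0.8
  move_dur <- 0.5

  withr::with_seed(cfg$seed + 1L, {
    ## --- event timeline -----------------------------------------------------
    ev <- list(); t <- stats::runif(1, 0.2, 1.5)
    while (t + breath_dur < dur) {
      ep <- min(n_ep, floor((t + breath_dur / 2) / el) + 1L)
      sleeping <- h[ep] == "sleep"
      is_snore <- sleeping && stats::runif(1) < cfg$snore_prob
      amp <- if (sleeping) a_sleep else a_wake
      f0 <- if (is_snore) {
        stats::runif(1, cfg$snore_f0_hz[1], cfg$snore_f0_hz[2])
      } else NA_real_
      ev[[length(ev) + 1L]] <-
        list(start = t, end = t + breath_dur, amp = amp, f0 = f0,
             is_snore = is_snore, type = if (is_snore) "snore" else "breath")
      prm <- if (sleeping) cfg$sleep_period_s else cfg$wake_period_s
      t <- t + max(1.2, stats::rnorm(1, prm[1], prm[2]))
    }
    ## movement bursts in wake epochs, placed only where no event overlaps
    starts <- vapply(ev, `[[`, numeric(1), "start")
    ends <- vapply(ev, `[[`, numeric(1), "end")
    for (ep in which(h == "wake")) {
      n_mov <- stats::rpois(1, cfg$movement_rate_per_min * el / 60)
      if (n_mov == 0) next
      for (tm in stats::runif(n_mov, (ep - 1) * el, ep * el - move_dur)) {
        if (any(tm < ends + 0.05 & tm + move_dur > starts - 0.05)) next
        ev[[length(ev) + 1L]] <-
          list(start = tm, end = tm + move_dur, amp = a_sleep,
               f0 = NA_real_, is_snore = FALSE, type = "movement")
        starts <- c(starts, tm); ends <- c(ends, tm + move_dur)
      }
    }
    o <- order(vapply(ev, `[[`, numeric(1), "start"))
    ev <- ev[o]

    ## --- waveform -----------------------------------------------------------
    ## band-limited (300-3000 Hz) unit-RMS noise stream, sliced per breath:
    ## generating only the samples under breath envelopes keeps whole-night
    ## synthesis cheap
    bf <- signal::butter(4, c(300, 3000) / (fs / 2), type = "pass")
    snore_partials <- 6L
    stack_rms <- sqrt(sum((1 / seq_len(snore_partials))^2) / 2)
    is_breath <- vapply(ev, function(e) e$type != "movement", logical(1))
    lens <- vapply(ev, function(e) {
      i0 <- floor(e$start * fs) + 1
      as.integer(max(0, min(n, i0 + round((e$end - e$start) * fs) - 1) - i0 + 1))
    }, integer(1))
    total_breath <- sum(lens[is_breath])
    stream <- iir_filter(bf$b, bf$a, stats::rnorm(total_breath + fs))
    stream <- stream / stats::sd(stream[fs %/% 4 + seq_len(min(
      length(stream) - fs %/% 4, 400000L))])
    spos <- fs %/% 4                       # skip filter transient
    clean <- numeric(n)
    tt_full <- (seq_len(max(lens, 2L)) - 1L) / fs
    for (j in seq_along(ev)) {
      e <- ev[[j]]
      len <- lens[j]
      if (len < 2L) next
      i0 <- floor(e$start * fs) + 1L
      i1 <- i0 + len - 1L
      win <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = len))
      if (e$type == "movement") {
        clean[i0:i1] <- clean[i0:i1] + e$amp * win * stats::rnorm(len)
      } else {
        seg <- stream[spos + seq_len(len)]
        spos <- spos + len
        br <- e$amp * win * seg
        if (e$is_snore) {
          tt <- tt_full[seq_len(len)]
          ph <- stats::runif(snore_partials, 0, 2 * pi)
          stack <- numeric(len)
          for (k in seq_len(snore_partials)) {
            stack <- stack + sin(2 * pi * k * e$f0 * tt + ph[k]) / k
          }
          br <- br + 1.5 * e$amp * win * stack / stack_rms
        }
        clean[i0:i1] <- clean[i0:i1] + br
      }
    }
    ## white uniform background noise scaled to the target level: any iid
    ## white process gives complex-Gaussian spectral bins at these frame
    ## sizes, and uniform draws are markedly cheaper than Gaussian over a
    ## whole night; added in chunks to bound peak memory
    sigma <- a_sleep * 10^(-cfg$background_snr_db / 20)
    if (cfg$keep_clean) {
      clean_audio <- audio_signal(clean, fs)
      noisy <- clean + 0                 # force a copy; clean is kept
    } else {
      clean_audio <- NULL
      noisy <- clean                     # single reference: modified in place
    }
    rm(clean)
    chunk <- 4000000L
    i <- 1L
    while (i <= n) {
      j <- min(n, i + chunk - 1L)
      noisy[i:j] <- noisy[i:j] +
        (sigma * sqrt(12)) * (stats::runif(j - i + 1L) - 0.5)
      i <- j + 1L
    }

    events <- data.frame(
      start_s = vapply(ev, `[[`, numeric(1), "start"),
      end_s = vapply(ev, `[[`, numeric(1), "end"),
      peak_db = 20 * log10(vapply(ev, `[[`, numeric(1), "amp")),
      is_snore = vapply(ev, `[[`, logical(1), "is_snore"),
      type = vapply(ev, `[[`, character(1), "type")
    )
    list(audio = audio_signal(noisy, fs),
         truth = list(hypnogram = h, events = events,
                      clean_audio = clean_audio))
  })
}

#' Simulate feature-level epoch data
#'
#' Draws the 8 per-epoch features from state-conditional normal
#' distributions with unit within-class standard deviation; class means
#' differ by `separation` standard deviations in the directions seen in
#' real data (sleep: higher cycle intensity, MaxSLS and snore index; lower
#' cycle consistency; slower, steadier cycle period).
#'
#' @param h A [hypnogram()].
#' @param separation Class-mean separation in within-class sd units (>= 0).
#' @param cfg A [sim_config()] (only `seed` is used).
#' @return Data frame, one row per epoch, columns `cp12`, `ci12`, `cc12`,
#'   `cp24`, `ci24`, `cc24`, `max_sls`, `si`.
#' @export
simulate_features <- function(h, separation, cfg) {
  stopifnot(inherits(cfg, "sim_config"), separation >= 0)
  dirs <- c(cp12 = 1, ci12 = 1, cc12 = -1, cp24 = 1, ci24 = 1, cc24 = -1,
            max_sls = 1, si = 1)
  n <- length(h)
  sleep <- as.character(h) == "sleep"
  withr::with_seed(cfg$seed + 2L, {
    out <- lapply(names(dirs), function(f) {
      mu <- ifelse(sleep, separation * dirs[[f]], 0)
      stats::rnorm(n, mean = mu, sd = 1)
    })
    names(out) <- names(dirs)
    as.data.frame(out)
  })
}

#' Write a simulated subject to disk (WAV + hypnogram CSV + events CSV)
#'
#' @param dir Output directory (created if needed).
#' @param cfg A [sim_config()].
#' @param name Base file name (default "subject").
#' @return Named list of the three paths, invisibly.
#' @export
simulate_subject <- function(dir, cfg, name = "subject") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- simulate_hypnogram(cfg)
  night <- synthesize_night(h, cfg)
  paths <- list(
    wav = file.path(dir, paste0(name, ".wav")),
    hypnogram = file.path(dir, paste0(name, "_hypnogram.csv")),
    events = file.path(dir, paste0(name, "_events.csv"))
  )
  write_wav(night$audio, paths$wav)
  write_hypnogram(h, paths$hypnogram)
  utils::write.csv(night$truth$events, paths$events, row.names = FALSE)
  invisible(paths)
}
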
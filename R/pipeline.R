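#' Default pipeline configuration
#'
#' All tunable settings of the pipeline, grouped by stage, serializable to
#' YAML. Unknown keys are rejected when merging or loading, so typos fail
#' loudly.
#'
#' @return A nested `bsa_config` list with sections `preprocess`, `events`,
#'   `sls`, `features`, `classifier`, `threshold` and a `version` string.
#' @export
bsa_config <- function() {
  structure(list(
    version = as.character(utils::packageVersion("nightbreath")),
    preprocess = list(denoise = TRUE, frame_len_s = 0.060, hop_s = 0.030,
                      noise_window_s = 30, update_s = 5,
                      noise_quantile = 0.10, oversubtraction = 2.5,
                      gain_floor = 0.05, floor_db = -120),
    events = list(margin_db = 6, merge_gap_s = 0.1, min_dur_s = 0.2,
                  floor_window_s = 30, floor_quantile = 0.1,
                  floor_update_s = 5),
    sls = list(w_harm = 4, w_level_per_db = 0.05, offset = 2.5,
               lowpass_hz = 1000, f0_range_hz = c(60, 200),
               max_scored_s = 3),
    features = list(interval_lens_s = c(12, 24), band_s = c(1.5, 10),
                    max_lag_s = 10, max_freq_hz = 3000, top_fraction = 0.5,
                    epoch_len_s = 30, sls_floor = -3),
    classifier = list(k = 100, n_lags = 2),
    threshold = list(method = "exact", n_bins = 256)
  ), class = "bsa_config")
}

#' Merge user overrides into a configuration
#'
#' @param config A `bsa_config`.
#' @param overrides Nested list of overrides; unknown keys are an error.
#' @return The merged `bsa_config`.
#' @export
merge_config <- function(config = bsa_config(), overrides = list()) {
  check_keys(overrides, config, path = "")
  out <- utils::modifyList(config, overrides)
  class(out) <- "bsa_config"
  out
}

check_keys <- function(user, ref, path) {
  if (!is.list(user)) return(invisible(TRUE))
  unknown <- setdiff(names(user), names(ref))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(sub("^\\.", "", paste0(path, ".", unknown)), collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(ref[[k]])) check_keys(user[[k]], ref[[k]], paste0(path, ".", k))
  }
  invisible(TRUE)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML path.
#' @return A `bsa_config` (read) or `path` invisibly (write).
#' @export
read_config <- function(path) {
  merge_config(bsa_config(), yaml::read_yaml(path))
}

#' @rdname read_config
#' @param config A `bsa_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Extract the full per-epoch feature set of one night
#'
#' Runs preprocessing (standardization to 16 kHz, optional spectral
#' subtraction), event detection and snore-likelihood scoring, and the
#' breathing-periodicity features, returning the 8-feature table on the
#' 30-s epoch grid.
#'
#' @param audio An [audio_signal()] or WAV path.
#' @param config A `bsa_config`.
#' @param events Optional externally supplied `acoustic_events` (bypasses
#'   the internal detector; unscored events are scored).
#' @return List with `features` (data frame, 8 columns), `events`,
#'   `envelope`, `n_epochs`.
#' @export
extract_night_features <- function(audio, config = bsa_config(),
                                   events = NULL) {
  if (is.character(audio)) audio <- read_wav(audio)
  sig <- standardize_audio(audio)
  rm(audio)                              # keep one whole-night copy live
  pp <- config$preprocess
  stft <- NULL
  if (isTRUE(pp$denoise)) {
    enh <- spectral_subtract(sig, pp[c("frame_len_s", "noise_window_s",
                                       "update_s", "noise_quantile",
                                       "oversubtraction", "gain_floor")],
                             return_stft = TRUE,
                             stft_max_freq_hz = config$features$max_freq_hz)
    sig <- enh$audio
    stft <- enh[c("mag", "freq_hz", "frame_len_s", "hop_s")]
  }
  env <- energy_envelope(sig, pp$frame_len_s, pp$hop_s, pp$floor_db)
  if (is.null(events)) {
    events <- detect_events(env, config$events)
  }
  if (nrow(events) > 0 && anyNA(events$sls)) {
    events <- score_events(sig, events, config$sls)
  }
  n_epochs <- floor(audio_duration(sig) / config$features$epoch_len_s)
  if (n_epochs < 1) stop("recording shorter than one epoch")
  bf <- breathing_features(sig, config$features, stft = stft)
  sf <- snore_features(events, n_epochs, config$features$epoch_len_s,
                       config$features$sls_floor)
  list(features = cbind(bf, sf), events = events, envelope = env,
       n_epochs = n_epochs)
}

#' Train the sleep/wake model on a set of subjects
#'
#' Extracts features per subject, pools all epochs into one lagged matrix,
#' and trains the AdaBoost classifier on the pooled design data.
#' Per-subject adaptation happens later, at prediction time, through the
#' individual decision threshold. Subjects whose audio or labels cannot be
#' used are skipped with a warning.
#'
#' @param subjects List; each element a list with `audio` (an
#'   [audio_signal()] or WAV path) and `hypnogram` (a [hypnogram()] or CSV
#'   path).
#' @param config A `bsa_config`.
#' @return List with `model` (an `adaboost_model`), `report` (per-subject
#'   training kappa/accuracy data frame), `n_epochs_used`.
#' @export
bsa_train <- function(subjects, config = bsa_config()) {
  stopifnot(length(subjects) >= 1)
  xs <- list(); ys <- list(); keep_names <- character(0)
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    res <- tryCatch({
      if (is.null(s$hypnogram)) stop("missing hypnogram")
      h <- if (inherits(s$hypnogram, "hypnogram")) {
        s$hypnogram
      } else if (is.character(s$hypnogram) && length(s$hypnogram) == 1L) {
        read_hypnogram(s$hypnogram)        # a CSV path
      } else {
        hypnogram(s$hypnogram)
      }
      fx <- extract_night_features(s$audio, config, events = s$events)
      n <- min(fx$n_epochs, length(h))
      list(x = build_lagged_matrix(fx$features[seq_len(n), ],
                                   config$classifier$n_lags),
           y = labels_to_pm1(as.character(h)[seq_len(n)]))
    }, error = function(e) {
      warning("subject ", i, " skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) {
      xs[[length(xs) + 1L]] <- res$x
      ys[[length(ys) + 1L]] <- res$y
      keep_names <- c(keep_names, paste0("subject", i))
    }
    rm(res)
    gc(verbose = FALSE)                  # whole-night vectors per subject
  }
  if (!length(xs)) stop("no usable subjects")
  x <- do.call(rbind, xs)
  y <- unlist(ys)
  model <- train_adaboost(x, y, config$classifier$k)
  report <- do.call(rbind, lapply(seq_along(xs), function(i) {
    swl <- swl_score(model, xs[[i]])
    pred <- tryCatch({
      prof <- time_varying_threshold(otsu_threshold(swl,
                                                    config$threshold$method,
                                                    config$threshold$n_bins),
                                     length(swl))
      classify_epochs(swl, prof)
    }, error = function(e) hypnogram(ifelse(swl < 0, "sleep", "wake")))
    ref <- hypnogram(ifelse(ys[[i]] < 0, "sleep", "wake"))
    m <- epoch_metrics(confusion_counts(pred, ref))
    data.frame(subject = keep_names[i], kappa = m$kappa, acu = m$acu)
  }))
  list(model = model, report = report, n_epochs_used = length(y))
}

#' Predict a night's hypnogram and sleep quality from audio
#'
#' The full estimation pipeline: preprocessing, event detection and
#' scoring, feature extraction, SWL scoring by the trained model, the
#' individual Otsu baseline with the early-night time-varying offset,
#' epoch classification, and sleep-quality parameterization.
#'
#' @param audio An [audio_signal()] or WAV path.
#' @param model An `adaboost_model` or model JSON path.
#' @param config A `bsa_config`.
#' @param events Optional external `acoustic_events` (or CSV path).
#' @return List with `hypnogram`, `swl`, `profile`, `features`, `events`,
#'   `quality` (a `sleep_quality_report`).
#' @export
bsa_predict <- function(audio, model, config = bsa_config(), events = NULL) {
  if (is.character(model)) model <- read_model(model)
  if (is.character(events)) events <- read_events(events)
  fx <- extract_night_features(audio, config, events = events)
  x <- build_lagged_matrix(fx$features, config$classifier$n_lags)
  if (ncol(x) != length(model$feature_names)) {
    stop("model/feature version mismatch: model expects ",
         length(model$feature_names), " columns, features provide ", ncol(x))
  }
  swl <- swl_score(model, x)
  ## a night spent in one state gives a degenerate score distribution; fall
  ## back to the global model's natural cut at zero
  l_th <- tryCatch(
    otsu_threshold(swl, config$threshold$method, config$threshold$n_bins),
    error = function(e) {
      warning("degenerate SWL distribution; using threshold 0")
      0
    })
  profile <- time_varying_threshold(l_th, length(swl))
  h <- classify_epochs(swl, profile)
  list(hypnogram = h, swl = swl, profile = profile,
       features = fx$features, events = fx$events,
       quality = sleep_quality(h))
}
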
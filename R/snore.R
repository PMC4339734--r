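#' Maximum snore-likelihood score within an epoch
#'
#' Events are assigned to epochs by their midpoint. Epochs containing no
#' event return the configured floor, a sentinel below any calibrated snore
#' score, so the feature stays finite and monotone in snore evidence.
#'
#' @param events `acoustic_events` with `sls` filled.
#' @param l 1-based epoch index.
#' @param epoch_len_s Epoch length (default 30).
#' @param floor Value for empty epochs (default -3).
#' @return Numeric MaxSLS.
#' @export
epoch_max_sls <- function(events, l, epoch_len_s = 30, floor = -3) {
  mid <- (events$start_s + events$end_s) / 2
  sel <- mid >= (l - 1) * epoch_len_s & mid < l * epoch_len_s
  if (!any(sel)) return(floor)
  max(events$sls[sel])
}

#' Snore index of an epoch (events/hour)
#'
#' Count of snore events (SLS > 0) whose midpoint falls in the epoch,
#' multiplied by the number of epochs per hour (120 for 30-s epochs).
#'
#' @inheritParams epoch_max_sls
#' @return Numeric snore index, a multiple of 3600 / `epoch_len_s` per count.
#' @export
epoch_snore_index <- function(events, l, epoch_len_s = 30) {
  mid <- (events$start_s + events$end_s) / 2
  sel <- mid >= (l - 1) * epoch_len_s & mid < l * epoch_len_s &
    events$sls > 0
  sum(sel) * 3600 / epoch_len_s
}

#' Per-epoch snore features for a whole night
#'
#' @param events Scored `acoustic_events`.
#' @param n_epochs Number of epochs.
#' @param epoch_len_s Epoch length (default 30).
#' @param sls_floor MaxSLS floor for empty epochs (default -3).
#' @return Data frame with columns `max_sls`, `si`.
#' @export
snore_features <- function(events, n_epochs, epoch_len_s = 30, sls_floor = -3) {
  mid <- (events$start_s + events$end_s) / 2
  ep <- floor(mid / epoch_len_s) + 1L
  max_sls <- rep(sls_floor, n_epochs)
  si <- numeric(n_epochs)
  keep <- ep >= 1L & ep <= n_epochs & is.finite(events$sls)
  if (any(keep)) {
    agg <- tapply(events$sls[keep], ep[keep], max)
    max_sls[as.integer(names(agg))] <- agg
    sn <- keep & events$sls > 0
    if (any(sn)) {
      cnt <- table(ep[sn])
      si[as.integer(names(cnt))] <- as.integer(cnt) * 3600 / epoch_len_s
    }
  }
  data.frame(max_sls = max_sls, si = si)
}
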
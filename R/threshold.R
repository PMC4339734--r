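#' Otsu threshold of a score distribution
#'
#' The per-subject baseline decision threshold: the SWL score distribution
#' is treated as bimodal (sleep and wake modes) and cut at the value
#' minimizing the weighted intra-class variance. The default method
#' evaluates every midpoint between consecutive distinct sorted scores
#' exactly; `method = "hist"` is a classical binned variant for comparison.
#' Ties break toward the lower threshold.
#'
#' @param scores Numeric scores (an `swl_curve` or plain vector); at least
#'   two distinct values.
#' @param method "exact" (default) or "hist".
#' @param n_bins Bin count for the histogram variant (default 256).
#' @return The threshold, a single numeric.
#' @export
otsu_threshold <- function(scores, method = c("exact", "hist"),
                           n_bins = 256) {
  method <- match.arg(method)
  x <- as.numeric(scores)
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2L) {
    stop("degenerate score distribution (fewer than 2 distinct values)")
  }
  if (method == "hist") {
    h <- graphics::hist(x, breaks = seq(min(x), max(x), length.out = n_bins + 1),
                        plot = FALSE)
    centers <- h$mids; counts <- h$counts
    keep <- which(cumsum(counts) > 0 & rev(cumsum(rev(counts))) > 0)
    keep <- keep[keep < length(counts)]
    wiv <- vapply(keep, function(i) {
      lo <- rep(centers[1:i], counts[1:i])
      hi <- rep(centers[(i + 1):length(centers)],
                counts[(i + 1):length(centers)])
      binned_intra_var(lo, hi, length(x))
    }, numeric(1))
    return(h$breaks[keep[which.min(wiv)] + 1L])
  }
  xs <- sort(x)
  n <- length(xs)
  s1 <- cumsum(xs)
  s2 <- cumsum(xs^2)
  i <- which(diff(xs) > 0)                      # split after these positions
  ## weighted intra-class variance * n = SSE(lower) + SSE(upper)
  sse_lo <- s2[i] - s1[i]^2 / i
  n_hi <- n - i
  sse_hi <- (s2[n] - s2[i]) - (s1[n] - s1[i])^2 / n_hi
  wiv <- (sse_lo + sse_hi) / n
  best <- i[which.min(wiv)]
  (xs[best] + xs[best + 1L]) / 2
}

binned_intra_var <- function(lo, hi, n) {
  (sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)) / n
}

#' Time-varying decision threshold profile
#'
#' The per-epoch threshold starts half an SWL unit above the per-subject
#' baseline and decays linearly to the baseline over the first 90 minutes:
#' `L_TH(t) = L_TH + max(0.5 - t/360, 0)`, with `t` the 0-based 30-s epoch
#' index (the offset vanishes at t = 180 epochs = 90 min). Since sleep is
#' called when the score falls below the threshold, the raised early
#' threshold makes the sleep decision more permissive at the start of the
#' recording, so that sleep onset — which dominates the sleep-latency
#' estimate — is not missed.
#'
#' @param l_th Baseline threshold (from [otsu_threshold()]).
#' @param n_epochs Number of epochs (>= 1).
#' @return A `threshold_profile`: list with `l_th`, `per_epoch` (length
#'   `n_epochs`), `offset0 = 0.5`, `decay_epochs = 360`.
#' @export
time_varying_threshold <- function(l_th, n_epochs) {
  stopifnot(is.finite(l_th), n_epochs >= 1)
  t <- seq_len(n_epochs) - 1L
  structure(
    list(l_th = l_th, per_epoch = l_th + pmax(0.5 - t / 360, 0),
         offset0 = 0.5, decay_epochs = 360),
    class = "threshold_profile"
  )
}

#' @export
print.threshold_profile <- function(x, ...) {
  cat(sprintf("<threshold_profile> baseline %.4f, %d epochs\n",
              x$l_th, length(x$per_epoch)))
  invisible(x)
}

#' Threshold the SWL curve into a binary hypnogram
#'
#' Epoch t is labeled sleep iff its score is strictly below the per-epoch
#' threshold; a score exactly at the threshold is wake (conservative toward
#' not over-calling sleep).
#'
#' @param swl `swl_curve` or numeric scores.
#' @param profile `threshold_profile` of matching length.
#' @return A `hypnogram` (see [hypnogram()]).
#' @export
classify_epochs <- function(swl, profile) {
  stopifnot(inherits(profile, "threshold_profile"))
  s <- as.numeric(swl)
  if (length(s) != length(profile$per_epoch)) {
    stop("SWL curve and threshold profile lengths differ")
  }
  hypnogram(ifelse(s < profile$per_epoch, "sleep", "wake"))
}

#' Construct a hypnogram
#'
#' Per-epoch binary sleep/wake labels at 30-s resolution.
#'
#' @param labels Character vector of "sleep"/"wake".
#' @param epoch_len_s Epoch length (default 30).
#' @return A `hypnogram` character vector with attribute `epoch_len_s`.
#' @export
hypnogram <- function(labels, epoch_len_s = 30) {
  labels <- as.character(labels)
  if (length(labels) == 0L) stop("empty hypnogram")
  if (!all(labels %in% c("sleep", "wake"))) {
    stop("labels must be 'sleep' or 'wake'")
  }
  structure(labels, epoch_len_s = epoch_len_s, class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat(sprintf("<hypnogram> %d epochs: %d sleep, %d wake\n", length(x),
              sum(x == "sleep"), sum(x == "wake")))
  invisible(x)
}

#' Read / write a hypnogram CSV
#'
#' Columns `epoch_index` (1-based), `label`; `write_hypnogram` adds
#' `epoch_start_s` and, when given, `swl_score` and `threshold`.
#'
#' @param path CSV path.
#' @return A `hypnogram` (read) or `path` invisibly (write).
#' @export
read_hypnogram <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("epoch_index", "label") %in% names(df))) {
    stop("hypnogram CSV must have columns epoch_index, label")
  }
  hypnogram(df$label[order(df$epoch_index)])
}

#' @rdname read_hypnogram
#' @param h `hypnogram`.
#' @param swl,profile Optional `swl_curve` / `threshold_profile` to include.
#' @export
write_hypnogram <- function(h, path, swl = NULL, profile = NULL) {
  el <- attr(h, "epoch_len_s")
  df <- data.frame(epoch_index = seq_along(h),
                   epoch_start_s = (seq_along(h) - 1L) * el,
                   label = as.character(h))
  if (!is.null(swl)) df$swl_score <- as.numeric(swl)
  if (!is.null(profile)) df$threshold <- profile$per_epoch
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
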
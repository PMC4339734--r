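#' Sleep-quality parameters of a night
#'
#' Derives the standard summary parameters from a binary hypnogram of 30-s
#' epochs (each epoch is 0.5 min):
#' \itemize{
#'   \item TIB — time in bed, the whole recording, minutes;
#'   \item SL — sleep latency: recording start to the first sleep epoch;
#'   \item TST — total sleep time: count of sleep epochs;
#'   \item SE — sleep efficiency: 100 * TST / TIB, percent;
#'   \item WASO — wake after sleep onset: wake time strictly between the
#'     first and the last sleep epoch (the terminal wake run, after the
#'     final awakening, is excluded by default);
#'   \item AwI — awakening index: number of distinct wake runs strictly
#'     between the first and last sleep epoch, per hour of TIB.
#' }
#' A night with no sleep epoch reports SL = TIB and TST = SE = WASO =
#' AwI = 0.
#'
#' @param h A [hypnogram()].
#' @param include_terminal_wake Count the terminal wake run in WASO and the
#'   awakening count (default FALSE).
#' @return A `sleep_quality_report`: list with `tib_min`, `tst_min`,
#'   `sl_min`, `se_pct`, `waso_min`, `awi_per_hr`, `n_awakenings`.
#' @export
sleep_quality <- function(h, include_terminal_wake = FALSE) {
  stopifnot(inherits(h, "hypnogram") || is.character(h))
  labels <- as.character(h)
  if (!length(labels)) stop("empty hypnogram")
  el_min <- (if (inherits(h, "hypnogram")) attr(h, "epoch_len_s") else 30) / 60
  n <- length(labels)
  tib <- n * el_min
  sleep_idx <- which(labels == "sleep")
  if (!length(sleep_idx)) {
    return(new_quality_report(tib, tst = 0, sl = tib, se = 0, waso = 0,
                              awi = 0, n_awakenings = 0L))
  }
  first_s <- sleep_idx[1L]
  last_s <- if (include_terminal_wake) n else sleep_idx[length(sleep_idx)]
  sl <- (first_s - 1L) * el_min
  tst <- length(sleep_idx) * el_min
  se <- 100 * tst / tib
  between <- labels[first_s:last_s]
  waso <- sum(between == "wake") * el_min
  r <- rle(between)
  n_awake <- sum(r$values == "wake")
  awi <- n_awake / (tib / 60)
  new_quality_report(tib, tst, sl, se, waso, awi, n_awake)
}

new_quality_report <- function(tib, tst, sl, se, waso, awi, n_awakenings) {
  structure(
    list(tib_min = tib, tst_min = tst, sl_min = sl, se_pct = se,
         waso_min = waso, awi_per_hr = awi,
         n_awakenings = as.integer(n_awakenings)),
    class = "sleep_quality_report"
  )
}

#' @export
print.sleep_quality_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<sleep_quality_report>\n",
    "  TIB  %6.1f min\n  TST  %6.1f min\n  SL   %6.1f min\n",
    "  SE   %6.2f %%\n  WASO %6.1f min\n  AwI  %6.2f /hr (%d awakenings)\n"),
    x$tib_min, x$tst_min, x$sl_min, x$se_pct, x$waso_min, x$awi_per_hr,
    x$n_awakenings))
  invisible(x)
}

#' @export
as.data.frame.sleep_quality_report <- function(x, ...) {
  data.frame(tib_min = x$tib_min, tst_min = x$tst_min, sl_min = x$sl_min,
             se_pct = x$se_pct, waso_min = x$waso_min,
             awi_per_hr = x$awi_per_hr)
}
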
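#' Build the lagged time-series feature matrix
#'
#' Each epoch's row concatenates its own feature vector with those of the
#' two previous epochs (lags 0, 1, 2 by default), so the classifier sees a
#' short history of the quasi-stationary sleep/wake process: with 8 base
#' features and 2 lags the matrix is 24 columns wide. The first epochs,
#' which lack a full history, are padded by replicating the earliest
#' available epoch.
#'
#' @param features Data frame or matrix, one row per epoch, one column per
#'   base feature.
#' @param n_lags Number of previous epochs appended (default 2).
#' @return Numeric matrix, `nrow(features)` rows and
#'   `(n_lags + 1) * ncol(features)` columns, named `<feature>_lag<k>`.
#' @export
build_lagged_matrix <- function(features, n_lags = 2) {
  x <- as.matrix(features)
  if (nrow(x) < 1L) stop("empty feature input")
  storage.mode(x) <- "double"
  nms <- colnames(x)
  if (is.null(nms)) nms <- paste0("f", seq_len(ncol(x)))
  blocks <- lapply(0:n_lags, function(k) {
    idx <- pmax(seq_len(nrow(x)) - k, 1L)
    b <- x[idx, , drop = FALSE]
    colnames(b) <- paste0(nms, "_lag", k)
    b
  })
  out <- do.call(cbind, blocks)
  rownames(out) <- NULL
  out
}

#' Train a discrete AdaBoost classifier with decision stumps
#'
#' From-scratch discrete AdaBoost over depth-1 stumps on the lagged feature
#' matrix. Sleep is labeled -1, wake +1. At each of up to `k` rounds the
#' stump minimizing the weighted error is selected among all columns, with
#' thresholds at midpoints between consecutive distinct sorted values; ties
#' break toward the lowest column index, then the lowest threshold. Round
#' weights are `alpha = 0.5 * log((1 - eps)/eps)`; sample weights update
#' multiplicatively and renormalize. Training stops early when a round's
#' error reaches 0.5 (stump not added) or 0 (alpha capped at the eps = 1e-8
#' value, stump added).
#'
#' @param x Numeric matrix from [build_lagged_matrix()].
#' @param y Labels: numeric -1/+1, or characters "sleep"/"wake".
#' @param k Maximum boosting rounds (default 100).
#' @return An `adaboost_model`: list with `stumps` (data frame `column`,
#'   `threshold`, `polarity`), `alphas`, `feature_names`, `k`,
#'   `train_error`, `round_errors`.
#' @export
train_adaboost <- function(x, y, k = 100) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  y <- labels_to_pm1(y)
  n <- nrow(x)
  stopifnot(length(y) == n, n >= 2)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  p <- ncol(x)
  ord <- lapply(seq_len(p), function(j) order(x[, j]))
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric(0); eps_hist <- numeric(0)
  H <- numeric(n)  # running unnormalized vote
  for (m in seq_len(k)) {
    best <- list(err = Inf)
    for (j in seq_len(p)) {
      o <- ord[[j]]
      xs <- x[o, j]
      dw <- w[o] * y[o]
      ## err(+1 polarity, threshold after position i) =
      ##   W(y=+1, x<=thr) + W(y=-1, x>thr)
      cum <- cumsum((dw + abs(dw)) / 2)          # weights of +1 labels
      wneg_tot <- sum((abs(dw) - dw) / 2)
      cumneg <- cumsum((abs(dw) - dw) / 2)
      cand <- which(diff(xs) > 0)                # split after these positions
      if (!length(cand)) next
      err_pos <- cum[cand] + (wneg_tot - cumneg[cand])
      err_neg <- 1 - err_pos
      for (pol in c(1, -1)) {
        e <- if (pol == 1) err_pos else err_neg
        i_best <- which.min(e)
        if (e[i_best] < best$err - 1e-15) {
          thr <- (xs[cand[i_best]] + xs[cand[i_best] + 1L]) / 2
          best <- list(err = e[i_best], column = j, threshold = thr,
                       polarity = pol)
        }
      }
    }
    if (!is.finite(best$err) || best$err >= 0.5 - 1e-10) break
    eps <- max(best$err, 1e-8)
    alpha <- 0.5 * log((1 - eps) / eps)
    h <- stump_predict(x[, best$column], best$threshold, best$polarity)
    stumps[[length(stumps) + 1L]] <-
      data.frame(column = best$column, threshold = best$threshold,
                 polarity = best$polarity)
    alphas <- c(alphas, alpha)
    eps_hist <- c(eps_hist, best$err)
    H <- H + alpha * h
    if (best$err < 1e-12) break                  # perfect stump: stop
    w <- w * exp(-alpha * y * h)
    w <- w / sum(w)
  }
  if (!length(stumps)) stop("no stump achieved error below 0.5")
  model <- structure(
    list(stumps = do.call(rbind, stumps), alphas = alphas,
         feature_names = colnames(x), k = k,
         round_errors = eps_hist,
         train_error = mean(sign(H) != y),
         label_convention = c(sleep = -1, wake = 1)),
    class = "adaboost_model"
  )
  model
}

stump_predict <- function(xj, threshold, polarity) {
  polarity * (2 * (xj > threshold) - 1)
}

labels_to_pm1 <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    bad <- !y %in% c("sleep", "wake")
    if (any(bad)) stop("labels must be 'sleep' or 'wake'")
    ifelse(y == "sleep", -1, 1)
  } else {
    stopifnot(all(y %in% c(-1, 1)))
    as.numeric(y)
  }
}

#' @export
print.adaboost_model <- function(x, ...) {
  cat(sprintf("<adaboost_model> %d stumps (k = %d), training error %.4f\n",
              nrow(x$stumps), x$k, x$train_error))
  invisible(x)
}

#' Sleep-wake likelihood (SWL) curve
#'
#' Normalized weighted vote of the boosted stumps:
#' `score = sum(alpha_m h_m(x)) / sum(alpha_m)`, one value per epoch in
#' \[-1, +1\]. Negative scores are sleep-like, positive wake-like.
#'
#' @param model An `adaboost_model`.
#' @param x Lagged feature matrix with the model's columns.
#' @return An `swl_curve`: numeric vector of per-epoch scores with
#'   attribute `epoch_len_s = 30`.
#' @export
swl_score <- function(model, x) {
  stopifnot(inherits(model, "adaboost_model"))
  x <- as.matrix(x)
  if (ncol(x) != length(model$feature_names)) {
    stop("feature-column mismatch: model expects ",
         length(model$feature_names), " columns, got ", ncol(x))
  }
  if (!is.null(colnames(x)) &&
      !identical(colnames(x), model$feature_names)) {
    stop("feature-column names do not match the model")
  }
  H <- numeric(nrow(x))
  st <- model$stumps
  for (m in seq_len(nrow(st))) {
    H <- H + model$alphas[m] *
      stump_predict(x[, st$column[m]], st$threshold[m], st$polarity[m])
  }
  scores <- H / sum(model$alphas)
  structure(scores, epoch_len_s = 30, class = "swl_curve")
}

#' @export
print.swl_curve <- function(x, ...) {
  cat(sprintf("<swl_curve> %d epochs, range [%.3f, %.3f]\n",
              length(x), min(x), max(x)))
  invisible(x)
}

#' Serialize / load an AdaBoost model as versioned JSON
#'
#' @param model `adaboost_model`.
#' @param path JSON path.
#' @return `path` (write) or the model (read).
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "adaboost_model"))
  obj <- list(
    format = "nightbreath-adaboost",
    version = as.character(utils::packageVersion("nightbreath")),
    k = model$k,
    feature_names = model$feature_names,
    stumps = model$stumps,
    alphas = model$alphas,
    round_errors = model$round_errors,
    train_error = model$train_error,
    label_convention = as.list(model$label_convention)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "nightbreath-adaboost")) {
    stop("not a nightbreath model file: ", path)
  }
  structure(
    list(stumps = as.data.frame(obj$stumps), alphas = as.numeric(obj$alphas),
         feature_names = as.character(obj$feature_names), k = obj$k,
         round_errors = as.numeric(obj$round_errors),
         train_error = obj$train_error,
         label_convention = unlist(obj$label_convention)),
    class = "adaboost_model"
  )
}
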
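#' Threshold-based up-state prediction from the mean silence time
#'
#' Emits a prediction event at each upward crossing of `<T>(t)` through
#' `threshold`; crossings within `refractory` of the previous event are
#' suppressed. When state segments are supplied, each event is matched to the
#' next up-state onset no further than `horizon` ahead: the first event
#' matching an onset is a hit with lead time `tau = onset - t_pred`; later
#' events matching the same onset are dropped (one event per pre-ictal
#' window); events with no onset in reach are false alarms. Without segments
#' all events are reported as `unmatched`.
#'
#' @param meanT mean silence time series (ms) on a uniform grid
#' @param t_grid evaluation times (ms); may be omitted when `meanT` is a
#'   [biomarker_series()]
#' @param threshold prediction threshold on `<T>` (ms); the up-state
#'   predictor default is 120 ms (distinct from the suppression trigger)
#' @param refractory minimum separation between events (ms); 0 keeps every
#'   crossing
#' @param segments optional [classify_states()] output for matching
#' @param horizon matching horizon (ms)
#' @param dedup which event to keep when several match the same onset:
#'   `"first"` keeps the earliest alarm (what a real-time alarm system
#'   reports); `"closest"` keeps the crossing nearest before the onset — the
#'   most recent prior threshold crossing, i.e. the silence episode that
#'   directly precedes the transition, which is the lead time the biomarker
#'   analysis quotes
#' @return data frame of class `prediction_events` with columns `t_pred`,
#'   `matched_onset`, `tau`, `outcome`
#' @export
threshold_predict <- function(meanT, t_grid = NULL, threshold = 120,
                              refractory = 1000, segments = NULL,
                              horizon = 2000, dedup = c("first", "closest")) {
  dedup <- match.arg(dedup)
  if (inherits(meanT, "biomarker_series")) {
    t_grid <- meanT$t
    meanT <- meanT$meanT
  }
  if (is.null(t_grid)) stop_param("`t_grid` is required")
  stopifnot(length(t_grid) == length(meanT))
  above <- meanT > threshold
  cross <- which(above & !c(FALSE, above[-length(above)]))
  t_cross <- t_grid[cross]
  keep <- numeric(0)
  last <- -Inf
  for (tc in t_cross) {
    if (tc - last >= refractory) {
      keep <- c(keep, tc)
      last <- tc
    }
  }
  ev <- data.frame(t_pred = keep,
                   matched_onset = rep(NA_real_, length(keep)),
                   tau = rep(NA_real_, length(keep)),
                   outcome = rep("unmatched", length(keep)),
                   stringsAsFactors = FALSE)
  if (!is.null(segments) && nrow(ev)) {
    onsets <- segments$t_on[segments$label == "up"]
    match_of <- integer(nrow(ev))
    for (i in seq_len(nrow(ev))) {
      nxt <- which(onsets >= ev$t_pred[i] &
                     onsets - ev$t_pred[i] <= horizon)
      match_of[i] <- if (length(nxt)) nxt[1] else 0L
    }
    ev$outcome[match_of == 0L] <- "false_alarm"
    drop <- logical(nrow(ev))
    for (k in unique(match_of[match_of > 0L])) {
      cand <- which(match_of == k)
      keep_i <- if (dedup == "first") cand[1] else cand[length(cand)]
      drop[setdiff(cand, keep_i)] <- TRUE
      ev$matched_onset[keep_i] <- onsets[k]
      ev$tau[keep_i] <- onsets[k] - ev$t_pred[keep_i]
      ev$outcome[keep_i] <- "hit"
    }
    ev <- ev[!drop, , drop = FALSE]
    rownames(ev) <- NULL
    attr(ev, "n_onsets") <- length(onsets)
  }
  class(ev) <- c("prediction_events", "data.frame")
  ev
}

#' Lead-time statistics of threshold predictions
#'
#' Summarizes the lead times (tau) of hits; false alarms and unmatched
#' events are counted separately.
#'
#' @param events a [threshold_predict()] result (or a row-bound combination)
#' @param breaks histogram breaks (ms) passed to [hist()]
#' @return list with `tau` (vector, ms), `median`, `quantiles` (10/25/50/75/90),
#'   `hist` (counts/breaks or NULL), `n_hits`, `n_false_alarms`, `n_unmatched`
#' @export
lead_time_stats <- function(events, breaks = "Sturges") {
  tau <- events$tau[events$outcome == "hit"]
  h <- if (length(tau)) hist(tau, breaks = breaks, plot = FALSE) else NULL
  list(tau = tau,
       median = if (length(tau)) median(tau) else NA_real_,
       quantiles = if (length(tau))
         quantile(tau, c(0.1, 0.25, 0.5, 0.75, 0.9)) else NULL,
       hist = h,
       n_hits = length(tau),
       n_false_alarms = sum(events$outcome == "false_alarm"),
       n_unmatched = sum(events$outcome == "unmatched"))
}

#' Lagged mean-silence-time features for synchrony forecasting
#'
#' Builds the feature rows `[<T>(t - lag), <T>(t - 2 lag)]` aligned to the
#' target `R(t)`. Rows are defined only for `t >= t_start + 2 lag`; the lag
#' must be an integer multiple of the grid spacing.
#'
#' @param series a [biomarker_series()] (needs `t`, `meanT` and, for
#'   modelling, `R`)
#' @param lag feature delay (ms)
#' @return data frame with columns `t`, `T_lag1`, `T_lag2`, `R`
#' @export
make_lagged_features <- function(series, lag = 10) {
  stopifnot(all(c("t", "meanT") %in% names(series)))
  t <- series$t
  spacing <- t[2] - t[1]
  steps <- lag / spacing
  if (abs(steps - round(steps)) > 1e-9)
    stop_param("`lag` must be an integer multiple of the grid spacing")
  steps <- as.integer(round(steps))
  G <- length(t)
  if (G <= 2L * steps) stop_param("series shorter than 2*lag")
  row <- (2L * steps + 1L):G
  data.frame(t = t[row],
             T_lag1 = series$meanT[row - steps],
             T_lag2 = series$meanT[row - 2L * steps],
             R = if ("R" %in% names(series)) series$R[row] else NA_real_)
}

#' Random-forest forecast of the order parameter from lagged silence times
#'
#' Fits an ensemble of `n_trees` regression trees predicting R(t) from the
#' two lagged `<T>` features, using a contiguous-in-time split: the first
#' `split_fraction` of the rows train the model, the remainder is held out.
#' Hyperparameters (tree depth, minimum node size) are chosen by k-fold
#' cross-validation on contiguous blocks of the training window, so the
#' features never see future values. Rows with undefined targets are
#' dropped. Reproducible for a fixed seed.
#'
#' @param features a [make_lagged_features()] data frame with a defined `R`
#' @param n_trees ensemble size
#' @param split_fraction training share (temporal split)
#' @param grid data frame of candidate `max_depth`, `min_node` pairs
#' @param n_folds cross-validation folds (contiguous blocks)
#' @param seed RNG seed for the forest
#' @return object of class `forecast_model` with elements `fit` (the ranger
#'   forest), `grid` (per-candidate CV error), `train_idx`, `test_idx`
#' @export
fit_forecast <- function(features, n_trees = 200, split_fraction = 0.5,
                         grid = expand.grid(max_depth = c(0L, 6L, 12L),
                                            min_node = c(5L, 25L)),
                         n_folds = 5, seed = 1) {
  stopifnot(all(c("T_lag1", "T_lag2", "R") %in% names(features)))
  check_fraction(split_fraction, "split_fraction")
  ok <- !is.na(features$R)
  dat <- features[ok, c("T_lag1", "T_lag2", "R")]
  ntr <- floor(nrow(dat) * split_fraction)
  if (ntr < n_folds || nrow(dat) - ntr < 2L)
    stop_param("not enough rows for the temporal split")
  train <- dat[seq_len(ntr), ]
  fold <- cut(seq_len(ntr), n_folds, labels = FALSE)
  cv_mae <- vapply(seq_len(nrow(grid)), function(g) {
    errs <- vapply(seq_len(n_folds), function(f) {
      tr <- train[fold != f, ]
      te <- train[fold == f, ]
      fit <- ranger::ranger(R ~ T_lag1 + T_lag2, data = tr,
                            num.trees = 50,
                            max.depth = grid$max_depth[g],
                            min.node.size = grid$min_node[g],
                            seed = seed, num.threads = 1)
      mean(abs(predict(fit, te, num.threads = 1)$predictions - te$R))
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  best <- which.min(cv_mae)
  fit <- ranger::ranger(R ~ T_lag1 + T_lag2, data = train,
                        num.trees = n_trees,
                        max.depth = grid$max_depth[best],
                        min.node.size = grid$min_node[best],
                        seed = seed, num.threads = 1)
  out <- list(fit = fit,
              grid = cbind(grid, cv_mae = cv_mae),
              best = grid[best, ],
              train_idx = which(ok)[seq_len(ntr)],
              test_idx = which(ok)[(ntr + 1L):nrow(dat)],
              seed = seed)
  class(out) <- "forecast_model"
  out
}

#' @rdname fit_forecast
#' @param model a fitted `forecast_model`
#' @export
predict_forecast <- function(model, features) {
  stopifnot(inherits(model, "forecast_model"))
  predict(model$fit, features, num.threads = 1)$predictions
}

#' @export
print.forecast_model <- function(x, ...) {
  cat(sprintf("forecast_model: %d trees, max_depth = %d, min_node = %d\n",
              x$fit$num.trees, x$best$max_depth, x$best$min_node))
  cat(sprintf("  training rows: %d, held-out rows: %d\n",
              length(x$train_idx), length(x$test_idx)))
  invisible(x)
}

#' Forecast evaluation metrics
#'
#' Coefficient of determination `R^2 = 1 - SS_res / SS_tot`, Pearson
#' correlation and mean absolute error between observed and predicted
#' series; the parity pairs are retained for plotting.
#'
#' @param R observed series
#' @param R_pred predicted series (same length, co-aligned)
#' @return list of class `forecast_evaluation`: `r_squared`, `pearson_r`,
#'   `mae`, `pairs`
#' @export
evaluate_forecast <- function(R, R_pred) {
  if (length(R) != length(R_pred))
    stop_param("series lengths differ")
  ok <- !is.na(R) & !is.na(R_pred)
  R <- R[ok]; R_pred <- R_pred[ok]
  ss_res <- sum((R - R_pred)^2)
  ss_tot <- sum((R - mean(R))^2)
  out <- list(r_squared = 1 - ss_res / ss_tot,
              pearson_r = suppressWarnings(cor(R, R_pred)),
              mae = mean(abs(R - R_pred)),
              pairs = data.frame(R = R, R_pred = R_pred))
  class(out) <- "forecast_evaluation"
  out
}

#' @export
print.forecast_evaluation <- function(x, ...) {
  cat(sprintf("forecast evaluation: R^2 = %.3f, r = %.3f, MAE = %.3f (n = %d)\n",
              x$r_squared, x$pearson_r, x$mae, nrow(x$pairs)))
  invisible(x)
}
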
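# Threshold predictor, lead-time statistics and the lagged-feature forest.

test_that("threshold crossings are detected, deduplicated and matched", {
  t <- seq(0, 10000, by = 10)
  # never exceeds threshold
  ev0 <- threshold_predict(rep(50, length(t)), t, threshold = 120)
  expect_equal(nrow(ev0), 0)
  # two crossings 20 ms apart with a 500 ms refractory collapse to one event
  mT <- rep(50, length(t))
  mT[t %in% c(5000, 5020)] <- 130
  ev1 <- threshold_predict(mT, t, threshold = 120, refractory = 500)
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$t_pred, 5000)
  # matching to the next up onset gives tau = onset - t_pred
  seg <- data.frame(t_on = c(0, 5110), t_off = c(5110, 10000),
                    label = c("down", "up"))
  ev2 <- threshold_predict(mT, t, threshold = 120, refractory = 500,
                           segments = seg, horizon = 2000)
  expect_equal(ev2$outcome, "hit")
  expect_equal(ev2$tau, 110)
  # an event with no onset in reach is a false alarm
  seg2 <- data.frame(t_on = 0, t_off = 10000, label = "down")
  ev3 <- threshold_predict(mT, t, threshold = 120, segments = seg2)
  expect_equal(ev3$outcome, "false_alarm")
})

test_that("threshold prediction is stable under grid refinement", {
  t1 <- seq(0, 10000, by = 10)
  mT1 <- 60 + 60 * sin(2 * pi * t1 / 4000)
  t2 <- seq(0, 10000, by = 5)
  mT2 <- 60 + 60 * sin(2 * pi * t2 / 4000)
  e1 <- threshold_predict(mT1, t1, threshold = 100)
  e2 <- threshold_predict(mT2, t2, threshold = 100)
  expect_equal(nrow(e1), nrow(e2))
  expect_true(all(abs(e1$t_pred - e2$t_pred) <= 10))
})

test_that("lead-time statistics summarize hits and count the rest", {
  ev <- data.frame(t_pred = c(1, 2, 3, 4),
                   matched_onset = c(101, 112, 123, NA),
                   tau = c(100, 110, 120, NA),
                   outcome = c("hit", "hit", "hit", "false_alarm"))
  st <- lead_time_stats(ev)
  expect_equal(st$median, 110)
  expect_equal(st$n_hits, 3)
  expect_equal(st$n_false_alarms, 1)
  empty <- lead_time_stats(ev[0, ])
  expect_equal(empty$n_hits, 0)
  expect_null(empty$hist)
})

test_that("lagged features align exactly and respect the boundary rule", {
  series <- data.frame(t = seq(0, 100, by = 10), meanT = seq(0, 100, by = 10),
                       R = 0.5)
  ft <- make_lagged_features(series, lag = 10)
  expect_equal(ft$t[1], 20)                       # first valid target
  row40 <- ft[ft$t == 40, ]
  expect_equal(row40$T_lag1, 30)
  expect_equal(row40$T_lag2, 20)
  cst <- data.frame(t = seq(0, 100, by = 10), meanT = 7, R = 0.5)
  ftc <- make_lagged_features(cst, lag = 10)
  expect_true(all(ftc$T_lag1 == 7 & ftc$T_lag2 == 7))
  expect_error(make_lagged_features(series, lag = 15), "multiple")
})

test_that("the forest learns a deterministic threshold map and not noise", {
  set.seed(42)
  n <- 5000
  meanT <- runif(n, 0, 250)
  series <- data.frame(t = seq_len(n) * 10, meanT = meanT)
  ft <- make_lagged_features(series, lag = 10)
  ft$R <- ifelse(ft$T_lag1 > 120, 0.9, 0.2)
  fit <- fit_forecast(ft, n_trees = 100, seed = 1)
  pred <- predict_forecast(fit, ft[seq(nrow(ft)) > length(fit$train_idx), ])
  ev <- evaluate_forecast(ft$R[seq(nrow(ft)) > length(fit$train_idx)], pred)
  expect_lt(ev$mae, 0.02)
  # permuted pairing: no signal
  ftp <- ft
  set.seed(7)
  ftp$R <- sample(ftp$R)
  fitp <- fit_forecast(ftp, n_trees = 100, seed = 1)
  predp <- predict_forecast(fitp, ftp[seq(nrow(ftp)) > length(fitp$train_idx), ])
  evp <- evaluate_forecast(ftp$R[seq(nrow(ftp)) > length(fitp$train_idx)], predp)
  expect_lte(evp$r_squared, 0.1)
})

test_that("shifting test targets by one step degrades a learned mapping", {
  set.seed(11)
  n <- 3000
  meanT <- 120 + 100 * sin(seq_len(n) / 15) + rnorm(n, 0, 5)
  series <- data.frame(t = seq_len(n) * 10, meanT = meanT)
  ft <- make_lagged_features(series, lag = 10)
  ft$R <- 0.5 + 0.4 * tanh((ft$T_lag1 - 120) / 40)
  fit <- fit_forecast(ft, n_trees = 100, seed = 2)
  hold <- ft[seq(nrow(ft)) > length(fit$train_idx), ]
  pred <- predict_forecast(fit, hold)
  mae0 <- mean(abs(hold$R - pred))
  mae_shift <- mean(abs(hold$R[-1] - pred[-length(pred)]))
  expect_lt(mae0, mae_shift)
})

test_that("forecast metrics follow their definitions", {
  R <- c(0.1, 0.4, 0.9, 0.3, 0.7)
  expect_equal(evaluate_forecast(R, R)$r_squared, 1)
  expect_equal(evaluate_forecast(R, R)$mae, 0)
  expect_equal(evaluate_forecast(R, rep(mean(R), 5))$r_squared, 0)
  P <- c(0.2, 0.5, 0.7, 0.4, 0.6)
  ev <- evaluate_forecast(R, P)
  expect_equal(ev$mae, mean(abs(R - P)))
  expect_equal(ev$pearson_r, cor(R, P))
  expect_equal(ev$r_squared, 1 - sum((R - P)^2) / sum((R - mean(R))^2))
  expect_error(evaluate_forecast(R, P[-1]), "length")
})

test_that("programmed pre-up silences are all recovered with exact lead times", {
  spec <- surrogate_spec(n_units = 40,
                         epochs = data.frame(
                           label = c("down", "silence", "up",
                                     "down", "silence", "up", "down"),
                           duration = c(8, 0.3, 3, 8, 0.3, 3, 5)),
                         down_rate = 20, seed = 3)
  sur <- surrogate_intermittent(spec)
  bs <- biomarker_series(sur$spikes, grid_ms = 1)
  truth_on <- sur$truth$t_on[sur$truth$label == "up"]
  seg <- data.frame(t_on = truth_on, t_off = truth_on + 3000,
                    label = "up")
  ev <- threshold_predict(bs, threshold = 120, refractory = 1000,
                          segments = seg, horizon = 2000)
  expect_equal(sum(ev$outcome == "hit"), 2)
  expect_equal(sum(ev$outcome == "false_alarm"), 0)
  # programmed silence 300 ms, threshold 120 ms: the crossing happens once
  # the pre-silence mean elapsed time (~1/down_rate) has grown past the
  # threshold, so tau ~ 300 - (120 - 50) ~ 230 ms up to sampling noise
  expect_true(all(ev$tau > 150 & ev$tau < 300))
})
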
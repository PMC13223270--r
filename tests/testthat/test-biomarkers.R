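# Synchrony, variability and silence metrics against naive oracles and
# closed-form cases.

test_that("every metric matches its direct-formula oracle on a small fixture", {
  sp <- small_fixture()
  t_grid <- seq(100, 900, by = 50)
  bs_R <- kuramoto_R(sp, t_grid)
  bs_cv <- cv_instantaneous(sp, t_grid, k = 2)
  bs_T <- silence_times(sp, t_grid)$meanT
  for (i in seq_along(t_grid)) {
    expect_equal(bs_R[i], oracle_R(sp, t_grid[i]), tolerance = 1e-9)
    expect_equal(bs_cv[i], oracle_cv_inst(sp, t_grid[i], k = 2),
                 tolerance = 1e-9)
    expect_equal(bs_T[i], oracle_meanT(sp, t_grid[i]), tolerance = 1e-9)
  }
  expect_equal(cv_global(sp)$cv, oracle_cv_global(sp), tolerance = 1e-9)
  # the combined single-pass series agrees with the standalone metrics
  bs <- biomarker_series(sp, grid_ms = 50)
  sel <- bs$t %in% t_grid
  expect_equal(bs$R[sel], bs_R, tolerance = 1e-12)
  expect_equal(bs$meanT[sel], bs_T, tolerance = 1e-12)
})

test_that("spike phases interpolate linearly and unwrap monotonically", {
  sp <- spike_train_set(list(seq(0, 1000, by = 100)), 0, 1000)
  # midway through the m-th ISI the interpolated phase is 2*pi*m + pi
  ph <- spike_phases(sp, c(150, 250, 350))
  expect_equal(ph[1, ], 2 * pi * c(1, 2, 3) + pi)
  # gain over one full ISI is 2*pi
  ph2 <- spike_phases(sp, c(120, 220))
  expect_equal(ph2[1, 2] - ph2[1, 1], 2 * pi)
  # masked outside [first, last) and for sparse trains
  ph3 <- spike_phases(sp, c(1000))
  expect_true(is.na(ph3[1, 1]))
  sp2 <- spike_train_set(list(c(500)), 0, 1000)
  expect_true(all(is.na(spike_phases(sp2, c(250, 750)))))
  # random train: unwrapped phase non-decreasing
  set.seed(8)
  spr <- spike_train_set(list(sort(runif(30, 0, 1000))), 0, 1000)
  phr <- spike_phases(spr, seq(0, 1000, by = 1))
  expect_true(all(diff(phr[1, !is.na(phr[1, ])]) >= 0))
})

test_that("order parameter hits its coherent, antiphase and incoherent limits", {
  tt <- seq(0, 950, by = 50)
  coher <- spike_train_set(list(tt, tt, tt), 0, 1000)
  expect_equal(unname(kuramoto_R(coher, c(125, 333))), c(1, 1))
  anti <- spike_train_set(list(tt, tt + 25), 0, 1000)
  expect_equal(kuramoto_R(anti, 300), 0, tolerance = 1e-12)
  # many uniformly spread phases: R = O(1/sqrt(N))
  big <- periodic_trains(n = 1000, period = 100, t_end = 2000)
  expect_lt(kuramoto_R(big, 1000), 0.1)
  # mean_R of a constant series is that constant; empty window errors
  expect_equal(mean_R(rep(0.7, 10)), 0.7)
  expect_error(mean_R(1:3, t_grid = 1:3, window = c(10, 20)), "empty")
})

test_that("global CV separates periodic from Poisson statistics", {
  expect_equal(cv_global(periodic_trains())$cv, 0)
  pois <- poisson_trains(n = 100, rate_hz = 10, t_end = 100000)
  expect_equal(cv_global(pois)$cv, 1, tolerance = 0.05)
  expect_error(cv_global(spike_train_set(list(c(1), c(2)), 0, 10)), "interspike")
  # the 0.5 boundary is the spike/burst classification rule
  expect_lt(cv_global(periodic_trains())$cv, 0.5)
  # per-neuron sigma mode: zero for common-period periodic trains, defined
  # and positive on irregular ones
  expect_equal(cv_global(periodic_trains(), "per_neuron")$cv, 0)
  expect_gt(cv_global(small_fixture(), "per_neuron")$cv, 0)
})

test_that("instantaneous CV flags an inserted burst and masks edges", {
  # stationary periodic network: CV(t) = 0 (to rounding) where defined
  per <- periodic_trains(n = 3, period = 50, t_end = 3000)
  cvp <- cv_instantaneous(per, seq(500, 2500, by = 100))
  expect_true(all(cvp[!is.na(cvp)] < 1e-6))
  # regular train with a 5-spike burst in the middle
  base <- seq(0, 4000, by = 80)
  burst <- 2000 + c(5, 15, 25, 35, 45)
  tt <- sort(c(base, burst))
  spb <- spike_train_set(list(tt), 0, 4000)
  cvb <- cv_instantaneous(spb, c(700, 2020))
  expect_lt(cvb[1], 0.5)
  expect_gt(cvb[2], 0.5)
  # earlier than the 7th ISI: masked
  expect_true(is.na(cv_instantaneous(spb, 10)))
  # pooled mode coincides with per-neuron mode for a single train
  one <- spike_train_set(list(tt), 0, 4000)
  tgq <- c(700, 1500, 2020)
  expect_equal(cv_instantaneous(one, tgq, mode = "pooled"),
               cv_instantaneous(one, tgq, mode = "per_neuron"),
               tolerance = 1e-12)
  # time-reversal symmetry up to grid alignment
  spf <- small_fixture()
  rev_trains <- lapply(spf$trains, function(x) sort(1000 - x))
  spr <- spike_train_set(rev_trains, 0, 1000)
  tg <- seq(200, 800, by = 25)
  a <- cv_instantaneous(spf, tg)
  b <- rev(cv_instantaneous(spr, 1000 - rev(tg)))
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("silence times follow the last-spike and first-spike conventions", {
  sp <- spike_train_set(list(c(100), c(300)), 0, 500)
  st <- silence_times(sp, c(150, 120, 450), per_neuron = TRUE)
  expect_equal(st$T_i[1, 1], 50)       # last spike 100, t = 150
  expect_equal(st$T_i[2, 2], 120)      # no spike yet: measured from t_start
  expect_equal(st$meanT[2], (20 + 120) / 2)
  # masked convention
  stm <- silence_times(sp, c(120), before_first = "mask", per_neuron = TRUE)
  expect_true(is.na(stm$T_i[2, 1]))
  expect_equal(stm$meanT[1], 20)
  # periodic network with uniform phases: time-average of <T> ~ P/2
  per <- periodic_trains(n = 50, period = 100, t_end = 10000)
  mt <- silence_times(per, seq(1000, 9000, by = 7))$meanT
  expect_equal(mean(mt), 50, tolerance = 0.05)
  # piecewise linear with slope <= 1, resets only at spikes
  expect_true(all(diff(mt) <= 7 + 1e-9))
  expect_true(all(mt >= 0))
})

test_that("state segmentation applies thresholds and debouncing", {
  t <- seq(0, 10000)
  up_all <- data.frame(t = t, R = 0.9, CV = 0.8)
  seg <- classify_states(up_all)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$label, "up")
  expect_equal(seg$t_off - seg$t_on, 10000)
  down_all <- data.frame(t = t, R = 0.2, CV = 0.1)
  expect_equal(classify_states(down_all)$label, "down")
  # short up excursion absorbed into surrounding down state
  R <- rep(0.2, length(t)); CV <- rep(0.1, length(t))
  R[5000:5100] <- 0.9; CV[5000:5100] <- 0.9
  seg2 <- classify_states(data.frame(t = t, R = R, CV = CV), debounce = 200)
  expect_equal(seg2$label, "down")
  # infinite CV threshold: a single down segment
  seg3 <- classify_states(up_all, cv_thr = Inf)
  expect_equal(seg3$label, "down")
  # boundary behavior: exactly-threshold values are up
  seg4 <- classify_states(data.frame(t = t, R = 0.6, CV = 0.5))
  expect_equal(seg4$label, "up")
  expect_error(classify_states(data.frame(t = t, R = NA_real_, CV = NA_real_)),
               "masked")
})

test_that("ISI return map labels the four clusters by rule", {
  # build one neuron whose consecutive ISI pairs exercise each rule;
  # use k = 0 surrogate CV via constructed trains is awkward, so check the
  # rule table on a fabricated points path through the internal labeller
  sp <- spike_train_set(list(cumsum(c(10, rep(c(60, 70), 12)))), 0, 2000)
  rm1 <- isi_return_map(sp)
  lab <- rm1$points$cluster[!is.na(rm1$points$cv)]
  expect_true(all(lab == 1L))          # regular band, CV 0 < 0.5
  # bursty: all ISIs short, CV >= 0.5 requires variability inside the band
  sp4 <- spike_train_set(list(cumsum(c(10, rep(c(10, 12, 14, 38), 8)))), 0, 2000)
  rm4 <- isi_return_map(sp4)
  p4 <- rm4$points
  inb <- p4$isi_n <= 40 & p4$isi_np1 <= 40 & !is.na(p4$cv)
  expect_true(any(p4$cluster[inb] == 4L))
  # transitions: short->long is cluster 2, long->short cluster 3
  expect_true(all(p4$cluster[p4$isi_n <= 40 & p4$isi_np1 > 40] == 2L,
                  na.rm = TRUE))
  expect_true(all(p4$cluster[p4$isi_n > 40 & p4$isi_np1 <= 40] == 3L,
                  na.rm = TRUE))
  # the rule table applied to specific pairs
  mixed <- spike_train_set(list(cumsum(c(100, rep(60, 20), 200, 15, 20, 15,
                                         20, 15, 20, 15, 200, rep(60, 8)))),
                           0, 3000)
  rmm <- isi_return_map(mixed)
  pt <- rmm$points[rmm$points$isi_n == 200 & rmm$points$isi_np1 == 15, ]
  expect_true(all(pt$cluster == 3L))
  expect_true(length(rmm$transitions) >= 2)
})
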
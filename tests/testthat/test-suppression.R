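# Target selection, closed-loop controller mechanics and condition comparison.

test_that("random-fraction target selection picks the right count of excitatory cells", {
  topo <- build_er_topology(1000, 0.05, 0.8, seed = 1)
  proto <- stim_protocol(fraction = 0.01)
  ids <- select_targets(topo, proto, seed = 5)
  expect_length(ids, 8)                      # round(0.01 * 800)
  expect_true(all(topo$is_excitatory[ids]))
  expect_identical(ids, select_targets(topo, proto, seed = 5))
  expect_warning(select_targets(topo, stim_protocol(fraction = 0)), "empty")
})

test_that("radius mode selects by distance and honors the E/I switch", {
  pos <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 20, 0), c(50, 0, 0), c(0, 0, 5))
  topo <- network_topology(5, integer(0), integer(0),
                           c(TRUE, TRUE, TRUE, TRUE, FALSE), positions = pos)
  proto <- stim_protocol(target_mode = "radius", center = c(0, 0, 0),
                         radius = 30)
  expect_setequal(select_targets(topo, proto), c(1, 2, 3))
  proto_i <- stim_protocol(target_mode = "radius", center = c(0, 0, 0),
                           radius = 30, include_inhibitory = TRUE)
  expect_setequal(select_targets(topo, proto_i), c(1, 2, 3, 5))
  bare <- network_topology(5, integer(0), integer(0), rep(TRUE, 5))
  expect_error(select_targets(bare, proto), "positions")
})

test_that("a zero-amplitude or never-triggered controller is a bit-exact no-op", {
  topo <- build_er_topology(100, 0.1, 0.8, seed = 2)
  p <- model_params(g_syn = 1.8)
  plain <- simulate_network(topo, p, duration = 4000, dt = 0.05, seed = 6)
  noamp <- closed_loop_run(topo, p, stim_protocol(I_sup = 0,
                                                  trigger_threshold = 10),
                           duration = 4000, dt = 0.05, seed = 6)
  expect_identical(noamp$spikes$trains, plain$spikes$trains)
  never <- closed_loop_run(topo, p, stim_protocol(trigger_threshold = Inf),
                           duration = 4000, dt = 0.05, seed = 6)
  expect_identical(never$spikes$trains, plain$spikes$trains)
  expect_equal(nrow(never$stim_log), 0)
})

test_that("the controller fires on silence, stimulates its targets, and logs episodes", {
  # quiet network: subthreshold drive, silence accumulates from t = 0
  one <- network_topology(1, integer(0), integer(0), TRUE)
  p <- model_params(g_syn = 0, I_ext = 0, init_v_range = c(-85, -84))
  proto <- stim_protocol(trigger_threshold = 100, I_sup = 300, t_sup = 500,
                         fraction = 1, cooldown = 200)
  r <- closed_loop_run(one, p, proto, duration = 2000, dt = 0.05, seed = 1)
  expect_gt(nrow(r$stim_log), 0)
  expect_equal(r$stim_log$t_off - r$stim_log$t_on, rep(500, nrow(r$stim_log)))
  # spikes occur only inside stimulation episodes
  tt <- r$spikes$trains[[1]]
  expect_gt(length(tt), 0)
  inside <- vapply(tt, function(x)
    any(x >= r$stim_log$t_on & x <= r$stim_log$t_off + 1), logical(1))
  expect_true(all(inside))
  # episodes respect t_sup + cooldown spacing
  if (nrow(r$stim_log) > 1)
    expect_true(all(diff(r$stim_log$t_on) >= 500 + 200))
})

test_that("up-state durations extract and flag truncated segments", {
  seg <- data.frame(t_on = c(0, 2000, 5000), t_off = c(2000, 5000, 9000),
                    label = c("down", "up", "down"))
  attr(seg, "window") <- c(0, 9000)
  class(seg) <- c("state_segments", "data.frame")
  expect_equal(as.numeric(up_state_durations(seg)), 3)
  none <- seg[seg$label == "down", ]
  attr(none, "window") <- c(0, 9000)
  expect_length(up_state_durations(none), 0)
  segt <- data.frame(t_on = c(0, 8000), t_off = c(8000, 9000),
                     label = c("down", "up"))
  attr(segt, "window") <- c(0, 9000)
  class(segt) <- c("state_segments", "data.frame")
  d <- up_state_durations(segt)
  expect_length(d, 0)
  expect_equal(attr(d, "n_truncated"), 1)
})

test_that("Mann-Whitney comparison matches brute-force pair counting", {
  a <- c(5, 7, 9)
  b <- c(1, 2, 3)
  cmp <- compare_conditions(a, b)
  U_brute <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  expect_equal(cmp$mann_whitney_U, U_brute)
  expect_equal(cmp$rank_biserial, 1 - 2 * U_brute / 9)
  expect_equal(abs(cmp$rank_biserial), 1)      # fully separated
  # identical samples: U = n^2/2, effect size 0
  same <- compare_conditions(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$rank_biserial, 0)
  # randomized brute-force agreement with ties
  set.seed(31)
  for (k in 1:5) {
    x <- sample(1:6, 8, replace = TRUE)
    y <- sample(1:6, 5, replace = TRUE)
    cc <- compare_conditions(x, y)
    Ub <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    expect_equal(cc$mann_whitney_U, Ub)
    expect_equal(cc$rank_biserial, 1 - 2 * Ub / 40)
    expect_true(cc$rank_biserial >= -1 && cc$rank_biserial <= 1)
  }
  expect_equal(compare_conditions(c(10, 10), c(5, 5))$percent_reduction, 50)
  expect_error(compare_conditions(numeric(0), 1), "non-empty")
})
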
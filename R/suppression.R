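#' Closed-loop stimulation protocol
#'
#' Parameters of the silence-triggered suppression controller: the network
#' mean silence time is monitored online during the simulation and, once it
#' crosses `trigger_threshold` upward while the controller is armed, a
#' constant depolarizing current `I_sup` is added to the membrane equation of
#' every target neuron for `t_sup`, after which the current is removed and
#' the controller stays disarmed for `cooldown`. Targets are either a random
#' fraction of the excitatory population or all (excitatory, optionally also
#' inhibitory) neurons within `radius` of an electrode `center`.
#'
#' @param trigger_threshold `<T>` level that triggers stimulation (ms)
#' @param I_sup stimulation amplitude (pA)
#' @param t_sup stimulation duration (ms)
#' @param target_mode `"random_excitatory_fraction"` or `"radius"`
#' @param fraction fraction of excitatory neurons targeted (random mode)
#' @param center electrode position (um; radius mode)
#' @param radius electrode reach (um; radius mode)
#' @param include_inhibitory also stimulate inhibitory neurons in reach
#' @param cooldown disarm interval after stimulation ends (ms)
#' @return an object of class `stim_protocol`
#' @export
stim_protocol <- function(trigger_threshold = 100, I_sup = 210, t_sup = 4000,
                          target_mode = c("random_excitatory_fraction",
                                          "radius"),
                          fraction = 0.01, center = NULL, radius = 30,
                          include_inhibitory = FALSE, cooldown = 1000) {
  target_mode <- match.arg(target_mode)
  check_fraction(fraction, "fraction")
  check_positive(t_sup, "t_sup")
  if (target_mode == "radius") check_positive(radius, "radius")
  out <- list(trigger_threshold = trigger_threshold, I_sup = I_sup,
              t_sup = t_sup, target_mode = target_mode, fraction = fraction,
              center = center, radius = radius,
              include_inhibitory = include_inhibitory, cooldown = cooldown)
  class(out) <- "stim_protocol"
  out
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("stim_protocol: trigger <T> > %g ms, I_sup = %g pA for %g ms\n",
              x$trigger_threshold, x$I_sup, x$t_sup))
  if (x$target_mode == "random_excitatory_fraction")
    cat(sprintf("  targets: random %g%% of excitatory neurons\n",
                100 * x$fraction))
  else
    cat(sprintf("  targets: neurons within %g um of the electrode%s\n",
                x$radius,
                if (x$include_inhibitory) " (incl. inhibitory)" else ""))
  invisible(x)
}

#' Select stimulation targets
#'
#' Random mode samples `round(fraction * n_excitatory)` excitatory neurons
#' uniformly without replacement (deterministic per seed). Radius mode
#' returns every excitatory neuron (plus inhibitory ones when
#' `include_inhibitory`) within `radius` of `center`; it requires positions.
#'
#' @param topology a [network_topology()]
#' @param protocol a [stim_protocol()]
#' @param seed RNG seed (random mode)
#' @return integer vector of neuron ids (1-based); empty selections produce
#'   a warning (the controller is then inert)
#' @export
select_targets <- function(topology, protocol, seed = 1) {
  stopifnot(inherits(topology, "network_topology"),
            inherits(protocol, "stim_protocol"))
  if (protocol$target_mode == "random_excitatory_fraction") {
    exc <- which(topology$is_excitatory)
    k <- round(protocol$fraction * length(exc))
    ids <- if (k > 0) with_seed(seed, sort(sample(exc, k))) else integer(0)
  } else {
    pos <- topology$positions
    if (is.null(pos))
      stop_param("radius-based targeting requires neuron positions")
    center <- protocol$center
    if (is.null(center)) stop_param("radius mode requires `center`")
    d2 <- colSums((t(pos[, seq_along(center), drop = FALSE]) - center)^2)
    inreach <- d2 <= protocol$radius^2
    keep <- topology$is_excitatory | protocol$include_inhibitory
    ids <- which(inreach & keep)
  }
  if (!length(ids)) warning("empty stimulation target set; controller inert")
  as.integer(ids)
}

#' Run the network under closed-loop silence-triggered stimulation
#'
#' Convenience wrapper around [simulate_network()] that selects targets from
#' the protocol and enables the online controller. The controller computes
#' the mean silence time at every step from its own last-spike table (same
#' first-spike convention as [silence_times()]). With `I_sup = 0` or an
#' empty target set the spike output is bit-identical to an uncontrolled run
#' at the same seed.
#'
#' @inheritParams simulate_network
#' @param protocol a [stim_protocol()]
#' @return a `sim_result` whose `stim_log` lists the applied episodes
#' @export
closed_loop_run <- function(topology, params = model_params(), protocol,
                            duration, dt = 0.05, seed = 1, targets = NULL,
                            record = NULL) {
  stopifnot(inherits(protocol, "stim_protocol"))
  if (is.null(targets))
    targets <- select_targets(topology, protocol, seed = seed)
  simulate_network(topology, params, duration, dt = dt, seed = seed,
                   controller = protocol, targets = targets, record = record)
}

#' Up-state durations from state segments
#'
#' Returns the durations (seconds) of all up segments. Segments truncated by
#' the analysis window boundaries are excluded by default and their count is
#' reported in the `"n_truncated"` attribute.
#'
#' @param segments a [classify_states()] result
#' @param exclude_truncated drop boundary-truncated up segments
#' @return numeric vector of durations (s) with attribute `n_truncated`
#' @export
up_state_durations <- function(segments, exclude_truncated = TRUE) {
  stopifnot(inherits(segments, "state_segments") ||
              all(c("t_on", "t_off", "label") %in% names(segments)))
  win <- attr(segments, "window")
  ups <- segments[segments$label == "up", , drop = FALSE]
  trunc <- rep(FALSE, nrow(ups))
  if (!is.null(win) && nrow(ups))
    trunc <- ups$t_on <= win[1] | ups$t_off >= win[2]
  keep <- if (exclude_truncated) !trunc else rep(TRUE, nrow(ups))
  out <- (ups$t_off[keep] - ups$t_on[keep]) / 1000
  attr(out, "n_truncated") <- sum(trunc)
  out
}

#' Compare up-state duration samples between two conditions
#'
#' Two-sided Mann-Whitney U test (tie-corrected) between condition a
#' (typically no suppression) and condition b (suppression), with the
#' rank-biserial effect size `r_rb = 1 - 2U / (n_a n_b)` and the percent
#' reduction of the summary statistic
#' `100 * (1 - summary_b / summary_a)`.
#'
#' @param durations_a,durations_b duration samples (s)
#' @param summary summary statistic for the percent reduction
#' @return list of class `condition_comparison`: per-condition `mean`,
#'   `median`, `sd`, `max`, plus `percent_reduction`, `mann_whitney_U`,
#'   `p_value`, `rank_biserial`
#' @export
compare_conditions <- function(durations_a, durations_b,
                               summary = c("mean", "median", "max")) {
  summary <- match.arg(summary)
  a <- as.numeric(durations_a)
  b <- as.numeric(durations_b)
  if (!length(a) || !length(b)) stop_param("both samples must be non-empty")
  wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = FALSE))
  U <- unname(wt$statistic)
  sfun <- switch(summary, mean = mean, median = median, max = max)
  out <- list(
    n_a = length(a), n_b = length(b),
    mean_a = mean(a), mean_b = mean(b),
    median_a = median(a), median_b = median(b),
    sd_a = sd(a), sd_b = sd(b),
    max_a = max(a), max_b = max(b),
    summary = summary,
    percent_reduction = 100 * (1 - sfun(b) / sfun(a)),
    mann_whitney_U = U,
    p_value = wt$p.value,
    rank_biserial = 1 - 2 * U / (length(a) * length(b)))
  class(out) <- "condition_comparison"
  out
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("condition comparison (n = %d vs %d)\n", x$n_a, x$n_b))
  cat(sprintf("  %s duration: %.2f s vs %.2f s (%.1f%% reduction)\n",
              x$summary, x[[paste0(x$summary, "_a")]],
              x[[paste0(x$summary, "_b")]], x$percent_reduction))
  cat(sprintf("  Mann-Whitney U = %g, p = %.4g, rank-biserial = %.3f\n",
              x$mann_whitney_U, x$p_value, x$rank_biserial))
  invisible(x)
}
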
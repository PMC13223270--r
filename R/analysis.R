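#' Coupling-strength sweep of the global synchrony metrics
#'
#' Simulates the network once per coupling value, discards a transient, and
#' summarizes the stationary window with the global ISI coefficient of
#' variation and the time-averaged Kuramoto order parameter. The smallest
#' coupling whose global CV reaches the spike/burst boundary locates the
#' transition from asynchronous spiking to synchronized bursting.
#'
#' @param topology a [network_topology()]
#' @param g_values couplings to simulate (uS/cm^2)
#' @param duration analysis window per coupling (ms), after the transient
#' @param transient discarded initial interval (ms)
#' @param params base [model_params()]; `g_syn` is overridden per run
#' @param dt integration step (ms)
#' @param seed seed shared by all runs
#' @param cv_boundary spike/burst classification boundary on the global CV
#' @return data frame of class `coupling_sweep` with columns `g_syn`, `rate`
#'   (Hz), `cv`, `mean_R`; the transition estimate is in the
#'   `"g_transition"` attribute (NA when no coupling reaches the boundary)
#' @export
coupling_sweep <- function(topology, g_values = seq(1.4, 2.2, by = 0.1),
                           duration = 15000, transient = 5000,
                           params = model_params(), dt = 0.05, seed = 1,
                           cv_boundary = 0.5) {
  rows <- lapply(g_values, function(g) {
    params$g_syn <- g
    r <- simulate_network(topology, params, duration + transient,
                          dt = dt, seed = seed)
    keep <- lapply(r$spikes$trains, function(tt) tt[tt > transient])
    sp <- spike_train_set(keep, transient, duration + transient)
    cv <- tryCatch(cv_global(sp)$cv, error = function(e) NA_real_)
    R <- tryCatch(
      mean_R(kuramoto_R(sp, seq(transient, transient + duration, by = 10))),
      error = function(e) NA_real_)
    data.frame(g_syn = g, rate = 1000 * mean(lengths(keep)) / duration,
               cv = cv, mean_R = R)
  })
  out <- do.call(rbind, rows)
  hit <- which(!is.na(out$cv) & out$cv >= cv_boundary)
  attr(out, "g_transition") <- if (length(hit)) out$g_syn[min(hit)] else NA_real_
  class(out) <- c("coupling_sweep", "data.frame")
  out
}

#' @export
print.coupling_sweep <- function(x, ...) {
  cat("coupling sweep:\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  cat(sprintf("transition (first CV >= boundary): g_syn = %s uS/cm^2\n",
              format(attr(x, "g_transition"))))
  invisible(x)
}

#' Simulate, analyze and segment one run near the transition
#'
#' Convenience driver for intermittency analyses: runs the network at one
#' coupling, computes the biomarker series and the up/down segmentation, and
#' returns everything needed for prediction and suppression comparisons.
#'
#' @inheritParams coupling_sweep
#' @param g_syn coupling for this run (uS/cm^2)
#' @param duration simulated time (ms)
#' @param controller optional [stim_protocol()] enabling the closed loop
#' @param grid_ms biomarker grid spacing (ms)
#' @param debounce segmentation debounce (ms)
#' @return list of class `intermittency_run`: `sim` (a `sim_result`),
#'   `series` (a [biomarker_series()]), `segments` (a [classify_states()]
#'   result), `up_durations` (s)
#' @export
intermittency_run <- function(topology, g_syn, duration = 100000,
                              params = model_params(), dt = 0.05, seed = 1,
                              controller = NULL, grid_ms = 1,
                              debounce = 200) {
  params$g_syn <- g_syn
  sim <- if (is.null(controller)) {
    simulate_network(topology, params, duration, dt = dt, seed = seed)
  } else {
    closed_loop_run(topology, params, controller, duration, dt = dt,
                    seed = seed)
  }
  series <- biomarker_series(sim$spikes, grid_ms = grid_ms)
  segments <- classify_states(series, debounce = debounce)
  out <- list(sim = sim, series = series, segments = segments,
              up_durations = up_state_durations(segments),
              g_syn = g_syn, seed = seed)
  class(out) <- "intermittency_run"
  out
}

#' @export
print.intermittency_run <- function(x, ...) {
  ups <- x$segments[x$segments$label == "up", ]
  cat(sprintf("intermittency run at g_syn = %g (seed %d): %d up state(s)\n",
              x$g_syn, x$seed, nrow(ups)))
  if (length(x$up_durations))
    cat(sprintf("  up durations (s): %s\n",
                paste(sprintf("%.1f", sort(x$up_durations, decreasing = TRUE)),
                      collapse = " ")))
  if (nrow(x$sim$stim_log))
    cat(sprintf("  stimulation episodes: %d\n", nrow(x$sim$stim_log)))
  invisible(x)
}
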
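#' Simulate the conductance-based network
#'
#' Integrates the membrane equation of every neuron with a fixed-step RK4
#' scheme. Ionic currents are written in driving-force form (potassium-type
#' currents always hyperpolarize); synaptic conductance jumps are applied at
#' step boundaries and decay exponentially with `tau_s` in between. A spike is
#' registered at the first step where the voltage crosses `spike_threshold`
#' upward (1 ms lockout by default), at which moment the neuron's outgoing
#' conductance jumps by `g_syn` (excitatory) or `inh_weight_factor * g_syn`
#' (inhibitory). Initial voltages are drawn uniformly from
#' `params$init_v_range` using `seed`; gates start at their voltage-dependent
#' steady state. The run is fully deterministic given
#' (topology, params, dt, seed, controller).
#'
#' @param topology a [network_topology()]
#' @param params a [model_params()]
#' @param duration simulated time (ms)
#' @param dt integration step (ms)
#' @param seed seed for the initial conditions
#' @param controller optional [stim_protocol()] for closed-loop stimulation;
#'   see [closed_loop_run()] for the convenience wrapper
#' @param targets neuron ids stimulated by the controller (1-based); when
#'   `NULL` and a controller is given, targets are selected with
#'   [select_targets()] using `seed`
#' @param record optional trace spec `list(neurons =, every_ms =)`: sample
#'   voltage, M-current and outgoing conductance of the given neurons every
#'   `every_ms` (must be an integer multiple of `dt`)
#' @return an object of class `sim_result` with elements `spikes`
#'   (a [spike_train_set()]), `stim_log` (data frame of stimulation episodes),
#'   `traces`, `params`, `dt`, `seed`
#' @export
simulate_network <- function(topology, params = model_params(), duration,
                             dt = 0.05, seed = 1, controller = NULL,
                             targets = NULL, record = NULL) {
  stopifnot(inherits(topology, "network_topology"),
            inherits(params, "model_params"))
  check_positive(duration, "duration")
  check_positive(dt, "dt")

  n <- topology$n
  # CSR of outgoing targets keyed by presynaptic neuron
  ord <- order(topology$pre)
  pre <- topology$pre[ord]
  tgt_idx <- topology$post[ord] - 1L
  tgt_ptr <- c(0L, cumsum(tabulate(pre, nbins = n)))

  ctl <- list(enabled = FALSE, targets = integer(0), trigger_threshold = Inf,
              I_sup_internal = 0, t_sup = 1, cooldown = 0)
  stim_targets <- integer(0)
  if (!is.null(controller)) {
    stopifnot(inherits(controller, "stim_protocol"))
    if (is.null(targets))
      targets <- select_targets(topology, controller, seed = seed)
    stim_targets <- as.integer(targets)
    ctl <- list(enabled = TRUE, targets = stim_targets - 1L,
                trigger_threshold = controller$trigger_threshold,
                I_sup_internal = controller$I_sup * params$current_scale,
                t_sup = controller$t_sup,
                cooldown = controller$cooldown)
  }

  rec <- list(idx = integer(0), every = 0L)
  if (!is.null(record)) {
    every <- record$every_ms / dt
    if (abs(every - round(every)) > 1e-9)
      stop_param("`record$every_ms` must be an integer multiple of dt")
    rec <- list(idx = as.integer(record$neurons) - 1L,
                every = as.integer(round(every)))
  }

  raw <- sim_core(n, tgt_ptr, tgt_idx, topology$is_excitatory,
                  internal_params(params), duration, dt, as.integer(seed),
                  ctl, rec)

  spikes <- as_spike_train_set(raw$spike_id, pmin(raw$spike_t, duration),
                               n = n, t_start = 0, t_end = duration)
  stim_log <- data.frame(t_on = raw$stim_on, t_off = raw$stim_off)
  attr(stim_log, "targets") <- stim_targets
  out <- list(spikes = spikes, stim_log = stim_log, traces = raw$traces,
              params = params, topology = topology, duration = duration,
              dt = dt, seed = as.integer(seed))
  class(out) <- "sim_result"
  out
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %g ms at dt = %g ms, seed %d\n",
              x$duration, x$dt, x$seed))
  print(x$spikes)
  if (nrow(x$stim_log))
    cat(sprintf("  stimulation episodes: %d (%d targets)\n",
                nrow(x$stim_log), length(attr(x$stim_log, "targets"))))
  invisible(x)
}
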
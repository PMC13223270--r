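#' Spike train sets
#'
#' A `spike_train_set` holds one strictly increasing vector of spike times
#' (ms) per neuron plus the recording window. It is the substrate of every
#' biomarker in the package.
#'
#' @param trains list of numeric vectors, one per neuron (ms)
#' @param t_start,t_end recording window (ms)
#' @return an object of class `spike_train_set`
#' @export
spike_train_set <- function(trains, t_start, t_end) {
  if (!is.list(trains)) stop_param("`trains` must be a list")
  if (t_end <= t_start) stop_param("t_end must exceed t_start")
  trains <- lapply(trains, as.numeric)
  for (i in seq_along(trains)) {
    tt <- trains[[i]]
    if (length(tt)) {
      if (is.unsorted(tt, strictly = TRUE))
        stop_param("train %d is not strictly increasing", i)
      if (tt[1] < t_start || tt[length(tt)] > t_end)
        stop_param("train %d has spikes outside [t_start, t_end]", i)
    }
  }
  out <- list(trains = trains, t_start = as.numeric(t_start),
              t_end = as.numeric(t_end))
  class(out) <- "spike_train_set"
  out
}

#' @export
print.spike_train_set <- function(x, ...) {
  ns <- lengths(x$trains)
  cat(sprintf("spike_train_set: %d neurons, %d spikes over [%g, %g] ms\n",
              length(x$trains), sum(ns), x$t_start, x$t_end))
  cat(sprintf("  active neurons: %d; mean rate %.2f Hz\n", sum(ns > 0),
              1000 * mean(ns) / (x$t_end - x$t_start)))
  invisible(x)
}

#' Convert a (neuron id, time) table to a spike train set
#'
#' @param neuron integer neuron/unit ids (1-based)
#' @param time spike times (ms)
#' @param n number of neurons (defaults to `max(neuron)`)
#' @param t_start,t_end recording window (ms); default spans the data
#' @return a [spike_train_set()]
#' @export
as_spike_train_set <- function(neuron, time, n = max(neuron),
                               t_start = 0, t_end = max(time, t_start + 1)) {
  ord <- order(time)
  trains <- split(time[ord], factor(neuron[ord], levels = seq_len(n)))
  names(trains) <- NULL
  spike_train_set(trains, t_start, t_end)
}

n_neurons <- function(spikes) length(spikes$trains)
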
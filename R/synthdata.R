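#' Surrogate specification for intermittent spike trains
#'
#' Describes a seeded surrogate recording built from labelled epochs:
#' `down` epochs contain independent Poisson trains at `down_rate`; `silence`
#' epochs contain no spikes; `up` epochs contain network-wide synchronized
#' bursts (regular burst onsets, `spikes_per_burst` spikes separated by
#' `intra_isi`, per-unit onset jitter uniform in +/- `jitter`). The default
#' burst pattern keeps within-burst intervals inside the short interburst ISI
#' band and the between-burst gaps well below the silence thresholds, so up
#' epochs read as sustained synchronized bursting. Surrogates
#' emulate the spike-time statistics of intermittent seizure-like dynamics —
#' a low-rate asynchronous epoch, a prolonged pre-onset silence, then a
#' high-rate synchronized epoch — without any biophysics.
#'
#' @param n_units number of units
#' @param epochs data frame with columns `label`
#'   (`"down"`/`"silence"`/`"up"`) and `duration` (s)
#' @param down_rate Poisson rate of down epochs (Hz)
#' @param bursts_per_s burst onset rate inside up epochs (1/s)
#' @param spikes_per_burst spikes per burst per unit
#' @param intra_isi within-burst ISI (ms)
#' @param jitter across-unit burst-onset jitter (ms)
#' @param seed RNG seed
#' @return an object of class `surrogate_spec`
#' @export
surrogate_spec <- function(n_units = 50,
                           epochs = data.frame(
                             label = c("down", "silence", "up", "down"),
                             duration = c(10, 0.15, 3, 10)),
                           down_rate = 10, bursts_per_s = 8,
                           spikes_per_burst = 4, intra_isi = 15,
                           jitter = 1, seed = 1) {
  stopifnot(all(c("label", "duration") %in% names(epochs)))
  if (!all(epochs$label %in% c("down", "silence", "up")))
    stop_param("epoch labels must be down/silence/up")
  if (any(epochs$duration <= 0)) stop_param("epoch durations must be positive")
  if (down_rate < 0 || jitter < 0) stop_param("rates and jitter must be >= 0")
  out <- list(n_units = n_units, epochs = epochs, down_rate = down_rate,
              bursts_per_s = bursts_per_s,
              spikes_per_burst = spikes_per_burst, intra_isi = intra_isi,
              jitter = jitter, seed = seed)
  class(out) <- "surrogate_spec"
  out
}

#' Generate a surrogate intermittent recording with ground-truth states
#'
#' @param spec a [surrogate_spec()]
#' @return list with `spikes` (a [spike_train_set()]) and `truth`
#'   (data frame `t_on`, `t_off` in ms, `label` from the spec)
#' @export
surrogate_intermittent <- function(spec) {
  stopifnot(inherits(spec, "surrogate_spec"))
  n <- spec$n_units
  dur_ms <- spec$epochs$duration * 1000
  t_off <- cumsum(dur_ms)
  t_on <- c(0, t_off[-length(t_off)])
  total <- t_off[length(t_off)]
  with_seed(spec$seed, {
    trains <- vector("list", n)
    for (u in seq_len(n)) trains[[u]] <- numeric(0)
    for (e in seq_len(nrow(spec$epochs))) {
      lab <- spec$epochs$label[e]
      if (lab == "silence") next
      if (lab == "down") {
        lam <- spec$down_rate * spec$epochs$duration[e]
        for (u in seq_len(n)) {
          k <- rpois(1, lam)
          if (k > 0)
            trains[[u]] <- c(trains[[u]],
                             t_on[e] + sort(runif(k, 0, dur_ms[e])))
        }
      } else {                          # synchronized bursts
        period <- 1000 / spec$bursts_per_s
        onsets <- seq(t_on[e] + period / 2, t_off[e] - period / 2,
                      by = period)
        burst <- (seq_len(spec$spikes_per_burst) - 1L) * spec$intra_isi
        for (u in seq_len(n)) {
          jit <- runif(length(onsets), -spec$jitter, spec$jitter)
          tt <- rep(onsets + jit, each = length(burst)) + burst
          trains[[u]] <- c(trains[[u]], tt[tt >= t_on[e] & tt < t_off[e]])
        }
      }
    }
    trains <- lapply(trains, function(tt) sort(unique(tt)))
    truth <- data.frame(t_on = t_on, t_off = t_off,
                        label = spec$epochs$label,
                        stringsAsFactors = FALSE)
    list(spikes = spike_train_set(trains, 0, total), truth = truth)
  })
}
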
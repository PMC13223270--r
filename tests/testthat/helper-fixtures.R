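# Small deterministic fixtures and naive reference (oracle) implementations.
# The oracles evaluate each metric's defining formula directly with plain
# loops; they share no code with the package's vectorized implementations.

periodic_trains <- function(n = 5, period = 100, t_end = 1000, offsets = NULL) {
  if (is.null(offsets)) offsets <- seq(0, period * (n - 1) / n, length.out = n)
  trains <- lapply(offsets, function(o) seq(o, t_end, by = period))
  spike_train_set(trains, 0, t_end)
}

poisson_trains <- function(n = 20, rate_hz = 10, t_end = 10000, seed = 99) {
  set.seed(seed)
  trains <- lapply(seq_len(n), function(i) {
    k <- rpois(1, rate_hz * t_end / 1000)
    sort(runif(k, 0, t_end))
  })
  spike_train_set(trains, 0, t_end)
}

# an irregular 5-neuron fixture with about 50 spikes for oracle equivalence
small_fixture <- function() {
  set.seed(1234)
  trains <- lapply(1:5, function(i) sort(runif(10, 0, 1000)))
  spike_train_set(trains, 0, 1000)
}

# --- oracle implementations -------------------------------------------------

oracle_phase <- function(spikes, j, t) {
  tt <- spikes$trains[[j]]
  if (length(tt) < 2) return(NA_real_)
  if (t < tt[1] || t >= tt[length(tt)]) return(NA_real_)
  m <- max(which(tt <= t))
  2 * pi * (m - 1) + 2 * pi * (t - tt[m]) / (tt[m + 1] - tt[m])
}

oracle_R <- function(spikes, t) {
  z <- 0 + 0i
  k <- 0
  for (j in seq_along(spikes$trains)) {
    ph <- oracle_phase(spikes, j, t)
    if (!is.na(ph)) {
      z <- z + exp(1i * ph)
      k <- k + 1
    }
  }
  if (k == 0) NA_real_ else Mod(z) / k
}

oracle_cv_global <- function(spikes) {
  per_means <- c()
  pooled <- c()
  for (tt in spikes$trains) {
    if (length(tt) >= 2) {
      isis <- diff(tt)
      per_means <- c(per_means, mean(isis))
      pooled <- c(pooled, isis)
    }
  }
  mu <- mean(per_means)
  sigma <- sqrt(sum((pooled - mean(pooled))^2) / length(pooled))
  sigma / mu
}

oracle_cv_inst <- function(spikes, t, k = 7) {
  vals <- c()
  for (tt in spikes$trains) {
    d <- diff(tt)
    if (length(d) < 2 * k) next
    m <- findInterval(t, tt)
    if (m < k + 1 || m > length(d) - k + 1) next
    w <- d[(m - k):(m + k - 1)]
    vals <- c(vals, sqrt(mean((w - mean(w))^2)) / mean(w))
  }
  if (!length(vals)) NA_real_ else mean(vals)
}

oracle_meanT <- function(spikes, t) {
  Ts <- vapply(spikes$trains, function(tt) {
    prior <- tt[tt <= t]
    if (!length(prior)) t - spikes$t_start else t - max(prior)
  }, numeric(1))
  mean(Ts)
}
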
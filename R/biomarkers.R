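#' Interpolated spike phases
#'
#' Between consecutive spikes of neuron j the phase advances linearly by one
#' full cycle: for t in (t_j^m, t_j^(m+1)),
#' `phi = 2*pi*m + 2*pi*(t - t_j^m) / (t_j^(m+1) - t_j^m)`.
#' The phase is undefined (NA) before a neuron's first spike and from its
#' last spike onward; neurons with fewer than two spikes yield an all-NA row.
#'
#' @param spikes a [spike_train_set()]
#' @param t_grid evaluation times (ms) within the recording window
#' @return numeric matrix, neurons x grid points, NA where undefined
#' @export
spike_phases <- function(spikes, t_grid) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (any(t_grid < spikes$t_start | t_grid > spikes$t_end))
    stop_param("t_grid must lie within the recording window")
  n <- n_neurons(spikes)
  out <- matrix(NA_real_, n, length(t_grid))
  for (j in seq_len(n)) {
    tt <- spikes$trains[[j]]
    if (length(tt) < 2L) next
    idx <- findInterval(t_grid, tt)
    def <- idx >= 1L & idx < length(tt)
    i <- idx[def]
    out[j, def] <- 2 * pi * (i - 1) +
      2 * pi * (t_grid[def] - tt[i]) / (tt[i + 1L] - tt[i])
  }
  out
}

#' Kuramoto order parameter from spike phases
#'
#' `R(t) = | sum_j exp(i phi_j(t)) | / N_defined(t)`, computed over the
#' neurons whose phase is defined at t. `R` lies in [0, 1]; values near 1
#' indicate burst synchronization, values near 0 incoherent spiking.
#'
#' @param x a phase matrix from [spike_phases()], or a [spike_train_set()]
#'   (phases are then computed internally without materializing the matrix)
#' @param t_grid evaluation times (required when `x` is a spike train set)
#' @return numeric vector of R(t), NA where no neuron has a defined phase
#' @export
kuramoto_R <- function(x, t_grid = NULL) {
  if (inherits(x, "spike_train_set")) {
    if (is.null(t_grid)) stop_param("`t_grid` is required with spike trains")
    acc <- phase_accumulate(x, t_grid)
    R <- sqrt(acc$re^2 + acc$im^2) / acc$cnt
    R[acc$cnt == 0] <- NA_real_
    return(pmin(R, 1))
  }
  phases <- x
  re <- colSums(cos(phases), na.rm = TRUE)
  im <- colSums(sin(phases), na.rm = TRUE)
  cnt <- colSums(!is.na(phases))
  R <- sqrt(re^2 + im^2) / cnt
  R[cnt == 0] <- NA_real_
  pmin(R, 1)
}

phase_accumulate <- function(spikes, t_grid) {
  G <- length(t_grid)
  re <- im <- numeric(G)
  cnt <- integer(G)
  for (j in seq_len(n_neurons(spikes))) {
    tt <- spikes$trains[[j]]
    if (length(tt) < 2L) next
    idx <- findInterval(t_grid, tt)
    def <- which(idx >= 1L & idx < length(tt))
    if (!length(def)) next
    i <- idx[def]
    frac <- 2 * pi * (t_grid[def] - tt[i]) / (tt[i + 1L] - tt[i])
    re[def] <- re[def] + cos(frac)
    im[def] <- im[def] + sin(frac)
    cnt[def] <- cnt[def] + 1L
  }
  list(re = re, im = im, cnt = cnt)
}

#' Time-averaged order parameter
#'
#' @param R a vector of R(t) values (NA allowed)
#' @param t_grid matching evaluation times; optional
#' @param window optional `c(from, to)` (ms) restricting the average
#' @return scalar mean of R over the (restricted) window
#' @export
mean_R <- function(R, t_grid = NULL, window = NULL) {
  keep <- rep(TRUE, length(R))
  if (!is.null(window)) {
    if (is.null(t_grid)) stop_param("`t_grid` is required with `window`")
    keep <- t_grid >= window[1] & t_grid <= window[2]
  }
  if (!any(keep)) stop_param("empty averaging window")
  mean(R[keep], na.rm = TRUE)
}

#' Global coefficient of variation of the interspike intervals
#'
#' The network mean ISI averages per-neuron mean ISIs
#' (`mean_isi = (1/N') sum_i mean(ISI_i)` over neurons with at least one
#' ISI); the ISI standard deviation is computed by default over the pooled
#' ISI multiset with the population denominator. `cv = sd_isi / mean_isi`.
#' A global CV below 0.5 indicates tonic spiking, at or above 0.5 bursting.
#'
#' @param spikes a [spike_train_set()]
#' @param sigma_mode `"pooled"` (default) computes the ISI standard deviation
#'   over all ISIs pooled across neurons; `"per_neuron"` averages per-neuron
#'   standard deviations
#' @return a list of class `summary_stats`: `cv`, `mean_isi`, `sd_isi`,
#'   `isi_counts` (per-neuron number of ISIs)
#' @export
cv_global <- function(spikes, sigma_mode = c("pooled", "per_neuron")) {
  stopifnot(inherits(spikes, "spike_train_set"))
  sigma_mode <- match.arg(sigma_mode)
  isis <- lapply(spikes$trains, diff)
  counts <- lengths(isis)
  if (!any(counts > 0)) stop_param("no interspike intervals in the recording")
  per_mean <- vapply(isis[counts > 0], mean, numeric(1))
  mean_isi <- mean(per_mean)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  sd_isi <- if (sigma_mode == "pooled") {
    pop_sd(unlist(isis, use.names = FALSE))
  } else {
    mean(vapply(isis[counts > 1], pop_sd, numeric(1)))
  }
  out <- list(cv = sd_isi / mean_isi, mean_isi = mean_isi, sd_isi = sd_isi,
              isi_counts = counts)
  class(out) <- "summary_stats"
  out
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("ISI summary: mean %.2f ms, sd %.2f ms, CV = %.3f (%s)\n",
              x$mean_isi, x$sd_isi, x$cv,
              if (x$cv >= 0.5) "burst" else "spike"))
  invisible(x)
}

# windowed per-spike CV: for the ISI sequence d of one neuron, cv_win[m] is
# the CV of the 14 consecutive ISIs d[m-7 .. m+6] surrounding the m-th ISI
# (7 ending at or before its start, 7 beginning at or after it).
isi_window_cv <- function(d, k = 7L) {
  L <- length(d)
  w <- 2L * k
  if (L < w) return(NULL)
  c1 <- c(0, cumsum(d))
  c2 <- c(0, cumsum(d * d))
  m <- (k + 1L):(L - k + 1L)            # valid ISI indices
  mu <- (c1[m + k] - c1[m - k]) / w
  v <- (c2[m + k] - c2[m - k]) / w - mu^2
  cv <- sqrt(pmax(v, 0)) / mu
  list(first = k + 1L, last = L - k + 1L, cv = cv)
}

#' Instantaneous coefficient of variation CV(t)
#'
#' For each neuron with enough activity, CV at time t is computed over the 14
#' consecutive ISIs surrounding t (the 7 ending by the spike that precedes t
#' and the 7 that follow, including the interval containing t). The network
#' CV(t) is the mean over neurons with a defined value (`mode = "per_neuron"`,
#' default) or the CV of the 14 pooled network ISIs nearest t
#' (`mode = "pooled"`). Masked (NA) where no neuron qualifies.
#'
#' @param spikes a [spike_train_set()]
#' @param t_grid uniform evaluation grid (ms)
#' @param k ISIs per side (default 7)
#' @param mode aggregation across neurons
#' @return numeric vector of CV(t) with NA masking
#' @export
cv_instantaneous <- function(spikes, t_grid, k = 7L,
                             mode = c("per_neuron", "pooled")) {
  stopifnot(inherits(spikes, "spike_train_set"))
  mode <- match.arg(mode)
  G <- length(t_grid)
  if (mode == "pooled") {
    st <- sort(unlist(spikes$trains, use.names = FALSE))
    d <- diff(st)
    win <- isi_window_cv(d, k)
    out <- rep(NA_real_, G)
    if (is.null(win)) return(out)
    idx <- findInterval(t_grid, st)
    def <- idx >= win$first & idx <= win$last
    out[def] <- win$cv[idx[def] - win$first + 1L]
    return(out)
  }
  acc <- numeric(G)
  cnt <- integer(G)
  for (j in seq_len(n_neurons(spikes))) {
    tt <- spikes$trains[[j]]
    d <- diff(tt)
    win <- isi_window_cv(d, k)
    if (is.null(win)) next
    idx <- findInterval(t_grid, tt)
    def <- which(idx >= win$first & idx <= win$last)
    if (!length(def)) next
    acc[def] <- acc[def] + win$cv[idx[def] - win$first + 1L]
    cnt[def] <- cnt[def] + 1L
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  out
}

#' Silence times
#'
#' The silence time of neuron i is the elapsed time since its most recent
#' spike, `T_i(t) = t - t_last(i, t)`. Before a neuron's first spike the
#' silence is measured from the start of the recording
#' (`before_first = "t_start"`, default) or masked. The network mean silence
#' time `<T>(t)` averages T_i over all N neurons and is the package's
#' up-state prediction biomarker.
#'
#' @param spikes a [spike_train_set()]
#' @param t_grid evaluation times (ms)
#' @param per_neuron return the per-neuron matrix as well
#' @param before_first convention before the first spike of a neuron
#' @return list with `meanT` (vector, ms) and optionally `T_i`
#'   (neurons x grid matrix)
#' @export
silence_times <- function(spikes, t_grid, per_neuron = FALSE,
                          before_first = c("t_start", "mask")) {
  stopifnot(inherits(spikes, "spike_train_set"))
  before_first <- match.arg(before_first)
  if (any(t_grid < spikes$t_start | t_grid > spikes$t_end))
    stop_param("t_grid must lie within the recording window")
  n <- n_neurons(spikes)
  G <- length(t_grid)
  sumT <- numeric(G)
  cntT <- if (before_first == "mask") integer(G) else NULL
  Ti <- if (per_neuron) matrix(NA_real_, n, G) else NULL
  for (j in seq_len(n)) {
    tt <- spikes$trains[[j]]
    idx <- findInterval(t_grid, tt)
    last <- if (length(tt)) c(spikes$t_start, tt)[idx + 1L]
            else rep(spikes$t_start, G)
    Tj <- t_grid - last
    if (before_first == "mask") {
      def <- idx >= 1L
      sumT[def] <- sumT[def] + Tj[def]
      cntT[def] <- cntT[def] + 1L
      Tj[!def] <- NA_real_
    } else {
      sumT <- sumT + Tj
    }
    if (per_neuron) Ti[j, ] <- Tj
  }
  meanT <- if (before_first == "mask") {
    out <- sumT / cntT
    out[cntT == 0] <- NA_real_
    out
  } else sumT / n
  out <- list(meanT = meanT, t_grid = t_grid)
  if (per_neuron) out$T_i <- Ti
  out
}

#' Biomarker time series on a common grid
#'
#' One pass over the spike trains computing the Kuramoto order parameter
#' R(t), the instantaneous coefficient of variation CV(t) (per-neuron,
#' 14-ISI windows) and the network mean silence time `<T>(t)` on a uniform
#' grid. NA marks masked (undefined) values.
#'
#' @param spikes a [spike_train_set()]
#' @param grid_ms grid spacing (ms)
#' @param k ISIs per side for CV(t)
#' @return a data frame of class `biomarker_series` with columns
#'   `t`, `R`, `CV`, `meanT`
#' @export
biomarker_series <- function(spikes, grid_ms = 1, k = 7L) {
  stopifnot(inherits(spikes, "spike_train_set"))
  check_positive(grid_ms, "grid_ms")
  t_grid <- seq(spikes$t_start, spikes$t_end, by = grid_ms)
  G <- length(t_grid)
  re <- im <- sumT <- cvs <- numeric(G)
  pcnt <- ccnt <- integer(G)
  t0 <- spikes$t_start
  for (j in seq_len(n_neurons(spikes))) {
    tt <- spikes$trains[[j]]
    idx <- findInterval(t_grid, tt)
    len <- length(tt)
    # silence
    last <- if (len) c(t0, tt)[idx + 1L] else rep(t0, G)
    sumT <- sumT + (t_grid - last)
    if (len < 2L) next
    # phase
    def <- which(idx >= 1L & idx < len)
    if (length(def)) {
      i <- idx[def]
      frac <- 2 * pi * (t_grid[def] - tt[i]) / (tt[i + 1L] - tt[i])
      re[def] <- re[def] + cos(frac)
      im[def] <- im[def] + sin(frac)
      pcnt[def] <- pcnt[def] + 1L
    }
    # instantaneous CV
    win <- isi_window_cv(diff(tt), k)
    if (!is.null(win)) {
      def <- which(idx >= win$first & idx <= win$last)
      if (length(def)) {
        cvs[def] <- cvs[def] + win$cv[idx[def] - win$first + 1L]
        ccnt[def] <- ccnt[def] + 1L
      }
    }
  }
  R <- sqrt(re^2 + im^2) / pcnt
  R[pcnt == 0] <- NA_real_
  CV <- cvs / ccnt
  CV[ccnt == 0] <- NA_real_
  out <- data.frame(t = t_grid, R = pmin(R, 1), CV = CV,
                    meanT = sumT / n_neurons(spikes))
  attr(out, "grid_ms") <- grid_ms
  class(out) <- c("biomarker_series", "data.frame")
  out
}

#' Segment up (burst-synchronized) and down (asynchronous) states
#'
#' Pointwise, a time belongs to the up state iff `CV(t) >= cv_thr` and
#' `R(t) >= r_thr`; all other times (including masked ones) are down state.
#' Runs shorter than `debounce` are merged into the surrounding state, so the
#' returned segments tile the analyzed window with alternating labels.
#'
#' @param series a [biomarker_series()] (or any data frame with `t`, `R`,
#'   `CV` columns)
#' @param cv_thr,r_thr classification thresholds
#' @param debounce minimum dwell time (ms)
#' @return a data frame of class `state_segments` with columns `t_on`,
#'   `t_off`, `label` (`"down"`/`"up"`)
#' @export
classify_states <- function(series, cv_thr = 0.5, r_thr = 0.6,
                            debounce = 200) {
  stopifnot(all(c("t", "R", "CV") %in% names(series)))
  t <- series$t
  if (all(is.na(series$R)) && all(is.na(series$CV)))
    stop_param("biomarker series is fully masked")
  up <- !is.na(series$CV) & !is.na(series$R) &
    series$CV >= cv_thr & series$R >= r_thr
  grid_ms <- if (length(t) > 1) t[2] - t[1] else 1
  # debounce: iteratively flip the shortest run below the minimum dwell
  repeat {
    r <- rle(up)
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths * grid_ms < debounce)
    if (!length(short)) break
    k <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    pos <- (ends[k] - r$lengths[k] + 1L):ends[k]
    up[pos] <- !r$values[k]
  }
  r <- rle(up)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(t_on = t[starts], t_off = t[ends],
                    label = ifelse(r$values, "up", "down"),
                    stringsAsFactors = FALSE)
  attr(out, "cv_thr") <- cv_thr
  attr(out, "r_thr") <- r_thr
  attr(out, "debounce") <- debounce
  attr(out, "window") <- c(t[1], t[length(t)])
  class(out) <- c("state_segments", "data.frame")
  out
}

#' ISI return map with rule-based cluster labels
#'
#' Builds the (ISI_n, ISI_(n+1)) return map over all neurons, attaches the
#' instantaneous CV at the shared spike, and labels each point by the
#' four-cluster rule set: cluster 1 (sustained down state / regular spiking)
#' when both ISIs fall in the regular band and CV < `cv_thr`; cluster 4
#' (active burst) when both ISIs fall in the short interburst band and
#' CV >= `cv_thr`; cluster 2 (short-to-long transition) when ISI_n is short
#' and ISI_(n+1) exceeds the short band; cluster 3 (pre-burst, long-to-short)
#' when ISI_n exceeds the short band and ISI_(n+1) is short; everything else
#' is unassigned (NA).
#'
#' @param spikes a [spike_train_set()]
#' @param short,regular ISI bands (ms) for interburst and regular spiking
#' @param cv_thr spike/burst CV boundary
#' @param k ISIs per side for the per-spike CV
#' @return list with `points` (data frame `neuron`, `t`, `isi_n`, `isi_np1`,
#'   `cv`, `cluster`) and `transitions` (time-ordered cluster sequence with
#'   consecutive repeats collapsed)
#' @export
isi_return_map <- function(spikes, short = c(10, 40), regular = c(50, 90),
                           cv_thr = 0.5, k = 7L) {
  stopifnot(inherits(spikes, "spike_train_set"))
  pts <- lapply(seq_len(n_neurons(spikes)), function(j) {
    tt <- spikes$trains[[j]]
    d <- diff(tt)
    L <- length(d)
    if (L < 2L) return(NULL)
    kk <- seq_len(L - 1L)                 # return-map point index
    # CV evaluated at the shared spike tt[k+1]: 14 ISIs centred on it
    cv <- rep(NA_real_, L - 1L)
    win <- isi_window_cv(d, k)
    if (!is.null(win)) {
      # window for ISI index m = k+1 surrounds spike tt[k+1]
      m <- kk + 1L
      ok <- m >= win$first & m <= win$last
      cv[ok] <- win$cv[m[ok] - win$first + 1L]
    }
    data.frame(neuron = j, t = tt[kk + 1L], isi_n = d[kk],
               isi_np1 = d[kk + 1L], cv = cv)
  })
  pts <- do.call(rbind, pts)
  if (is.null(pts))
    return(list(points = data.frame(), transitions = integer(0)))
  in_band <- function(x, b) x >= b[1] & x <= b[2]
  cl <- rep(NA_integer_, nrow(pts))
  cl[in_band(pts$isi_n, short) & pts$isi_np1 > short[2]] <- 2L
  cl[pts$isi_n > short[2] & in_band(pts$isi_np1, short)] <- 3L
  c1 <- in_band(pts$isi_n, regular) & in_band(pts$isi_np1, regular) &
    !is.na(pts$cv) & pts$cv < cv_thr
  c4 <- in_band(pts$isi_n, short) & in_band(pts$isi_np1, short) &
    !is.na(pts$cv) & pts$cv >= cv_thr
  cl[c1] <- 1L
  cl[c4] <- 4L
  pts$cluster <- cl
  ord <- order(pts$t)
  seq_cl <- pts$cluster[ord]
  seq_cl <- seq_cl[!is.na(seq_cl)]
  transitions <- rle(seq_cl)$values
  list(points = pts, transitions = transitions)
}
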
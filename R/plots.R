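#' @export
plot.spike_train_set <- function(x, xlim = NULL, max_neurons = Inf,
                                 pch = ".", cex = 1, ...) {
  n <- min(n_neurons(x), max_neurons)
  if (is.null(xlim)) xlim <- c(x$t_start, x$t_end)
  plot(NA, xlim = xlim, ylim = c(1, n), xlab = "time (ms)",
       ylab = "neuron", main = "raster", ...)
  for (j in seq_len(n)) {
    tt <- x$trains[[j]]
    tt <- tt[tt >= xlim[1] & tt <= xlim[2]]
    if (length(tt)) points(tt, rep(j, length(tt)), pch = pch, cex = cex)
  }
  invisible(x)
}

#' @export
plot.biomarker_series <- function(x, xlim = NULL, meanT_thresholds = 120,
                                  ...) {
  op <- par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1))
  on.exit(par(op))
  if (is.null(xlim)) xlim <- range(x$t)
  plot(x$t, x$R, type = "l", col = "firebrick", xlim = xlim, ylim = c(0, 1),
       xlab = "", ylab = "R(t)", ...)
  abline(h = 0.6, lty = 3)
  plot(x$t, x$CV, type = "l", col = "steelblue", xlim = xlim,
       xlab = "", ylab = "CV(t)", ...)
  abline(h = 0.5, lty = 3)
  plot(x$t, x$meanT, type = "l", col = "darkgreen", xlim = xlim,
       xlab = "time (ms)", ylab = "<T> (ms)", ...)
  abline(h = meanT_thresholds, lty = 3)
  invisible(x)
}

#' @export
plot.coupling_sweep <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(2.5, 4, 1, 1))
  on.exit(par(op))
  plot(x$g_syn, x$cv, type = "b", pch = 19, xlab = "",
       ylab = "global CV", ...)
  abline(h = 0.5, lty = 3)
  g_tr <- attr(x, "g_transition")
  if (!is.na(g_tr)) abline(v = g_tr, lty = 2, col = "grey50")
  plot(x$g_syn, x$mean_R, type = "b", pch = 19,
       xlab = "g_syn (uS/cm^2)", ylab = "mean R", ...)
  if (!is.na(g_tr)) abline(v = g_tr, lty = 2, col = "grey50")
  invisible(x)
}
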
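#' Read and write sorted multiunit spike tables
#'
#' The spike table is a TSV with a `unit_id<TAB>time_s` header followed by
#' one row per spike (unit ids are arbitrary integers, times in seconds).
#' An optional JSON sidecar (`<path>.annotations.json`, or `annotations`
#' argument) carries a list of `{"label": ..., "time_s": ...}` entries such
#' as seizure onsets. On load, trains are sorted ascending and exact
#' duplicate (unit, time) rows are removed with a warning; a non-numeric
#' time raises a parse error naming the offending line.
#'
#' @param path spike table path
#' @param annotations optional path to the annotation sidecar; defaults to
#'   `<path>.annotations.json` when that file exists
#' @return an object of class `annotated_recording`: `spikes` (a
#'   [spike_train_set()], times in ms), `units` (original unit ids),
#'   `annotations` (data frame `label`, `time_s`)
#' @export
read_spike_table <- function(path, annotations = NULL) {
  raw <- read.table(path, header = TRUE, sep = "\t",
                    colClasses = "character")
  if (!all(c("unit_id", "time_s") %in% names(raw)))
    stop_param("spike table must have unit_id and time_s columns")
  tnum <- suppressWarnings(as.numeric(raw$time_s))
  if (anyNA(tnum)) {
    bad <- which(is.na(tnum))[1]
    stop_param("non-numeric time %s at line %d", raw$time_s[bad], bad + 1L)
  }
  unit <- suppressWarnings(as.integer(raw$unit_id))
  if (anyNA(unit)) stop_param("non-numeric unit id in spike table")
  dup <- duplicated(data.frame(unit, tnum))
  if (any(dup)) {
    warning(sprintf("%d duplicate (unit, time) rows removed", sum(dup)))
    unit <- unit[!dup]
    tnum <- tnum[!dup]
  }
  units <- sort(unique(unit))
  idx <- match(unit, units)
  spikes <- as_spike_train_set(idx, tnum * 1000, n = length(units),
                               t_start = 0,
                               t_end = max(tnum * 1000, 1))
  ann <- data.frame(label = character(0), time_s = numeric(0))
  if (is.null(annotations)) {
    side <- paste0(path, ".annotations.json")
    if (file.exists(side)) annotations <- side
  }
  if (!is.null(annotations)) {
    ann <- as.data.frame(jsonlite::fromJSON(annotations))
    if (nrow(ann) &&
        any(ann$time_s * 1000 < spikes$t_start |
            ann$time_s * 1000 > spikes$t_end))
      stop_param("annotation time outside the recording window")
  }
  out <- list(spikes = spikes, units = units, annotations = ann,
              path = path)
  class(out) <- "annotated_recording"
  out
}

#' @rdname read_spike_table
#' @param recording an `annotated_recording` (or a [spike_train_set()])
#' @export
write_spike_table <- function(recording, path) {
  spikes <- if (inherits(recording, "annotated_recording"))
    recording$spikes else recording
  units <- if (inherits(recording, "annotated_recording"))
    recording$units else seq_along(spikes$trains)
  rows <- do.call(rbind, lapply(seq_along(spikes$trains), function(i) {
    tt <- spikes$trains[[i]]
    if (!length(tt)) return(NULL)
    data.frame(unit_id = units[i], time_s = tt / 1000)
  }))
  rows <- rows[order(rows$time_s, rows$unit_id), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("unit_id\ttime_s", con)
  writeLines(sprintf("%d\t%s", rows$unit_id, fmt_num(rows$time_s)), con)
  if (inherits(recording, "annotated_recording") &&
      nrow(recording$annotations)) {
    jsonlite::write_json(recording$annotations,
                         paste0(path, ".annotations.json"),
                         dataframe = "rows", auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}

#' @export
print.annotated_recording <- function(x, ...) {
  cat(sprintf("annotated_recording: %d units\n", length(x$units)))
  print(x$spikes)
  if (nrow(x$annotations))
    cat(sprintf("  annotations: %s\n",
                paste(sprintf("%s @ %gs", x$annotations$label,
                              x$annotations$time_s), collapse = ", ")))
  invisible(x)
}

#' Population firing histogram
#'
#' Spike counts over half-open bins `[k w, (k+1) w)` spanning the recording
#' window; the counts sum to the total number of spikes.
#'
#' @param spikes a [spike_train_set()]
#' @param bin_width bin width (ms)
#' @return data frame with `t` (bin left edge, ms) and `count`
#' @export
firing_histogram <- function(spikes, bin_width = 1000) {
  stopifnot(inherits(spikes, "spike_train_set"))
  check_positive(bin_width, "bin_width")
  all_t <- unlist(spikes$trains, use.names = FALSE)
  nb <- ceiling((spikes$t_end - spikes$t_start) / bin_width)
  nb <- max(nb, 1)
  edges <- spikes$t_start + bin_width * (0:nb)
  k <- pmin(floor((all_t - spikes$t_start) / bin_width), nb - 1)
  counts <- tabulate(k + 1, nbins = nb)
  data.frame(t = edges[-length(edges)], count = counts)
}

#' Onset-aligned silence and firing-rate profiles
#'
#' For each annotated onset, evaluates the network mean silence time and the
#' population firing rate on a grid relative to the onset, and reports the
#' peak pre-onset `<T>` together with its latency before the onset. Onsets
#' too close to the recording edges are skipped with a warning.
#'
#' @param recording an [read_spike_table()] result (or `spike_train_set`)
#' @param onsets onset times (s); defaults to the recording's annotations
#' @param window `c(before, after)` extent around each onset (s)
#' @param bin_width firing-rate bin width (s)
#' @return list of class `onset_profile`: `t_rel` (s), `meanT` and `rate`
#'   (matrices, one row per onset), `peak_preonset_T` and `peak_latency` (s)
#' @export
onset_silence_profile <- function(recording, onsets = NULL,
                                  window = c(30, 10), bin_width = 1) {
  spikes <- if (inherits(recording, "annotated_recording"))
    recording$spikes else recording
  if (is.null(onsets)) {
    if (!inherits(recording, "annotated_recording") ||
        !nrow(recording$annotations))
      stop_param("no onset annotations available")
    onsets <- recording$annotations$time_s
  }
  if (!length(onsets)) stop_param("at least one onset is required")
  w_ms <- window * 1000
  bw_ms <- bin_width * 1000
  keep <- onsets * 1000 - w_ms[1] >= spikes$t_start &
    onsets * 1000 + w_ms[2] <= spikes$t_end
  if (any(!keep))
    warning(sprintf("%d onset(s) too close to the recording edge skipped",
                    sum(!keep)))
  onsets <- onsets[keep]
  if (!length(onsets)) stop_param("no usable onsets left")
  t_rel <- seq(-w_ms[1], w_ms[2], by = bw_ms)
  meanT <- matrix(NA_real_, length(onsets), length(t_rel))
  rate <- matrix(NA_real_, length(onsets), length(t_rel))
  all_t <- sort(unlist(spikes$trains, use.names = FALSE))
  n_units <- n_neurons(spikes)
  for (i in seq_along(onsets)) {
    grid <- onsets[i] * 1000 + t_rel
    meanT[i, ] <- silence_times(spikes, grid)$meanT
    lo <- findInterval(grid - bw_ms / 2, all_t)
    hi <- findInterval(grid + bw_ms / 2, all_t)
    rate[i, ] <- (hi - lo) / (bin_width * n_units)
  }
  pre <- t_rel <= 0
  peak_idx <- apply(meanT[, pre, drop = FALSE], 1, which.max)
  out <- list(t_rel = t_rel / 1000, meanT = meanT / 1000, rate = rate,
              onsets = onsets,
              peak_preonset_T = meanT[cbind(seq_along(onsets), peak_idx)] / 1000,
              peak_latency = -t_rel[pre][peak_idx] / 1000)
  class(out) <- "onset_profile"
  out
}

#' @export
print.onset_profile <- function(x, ...) {
  cat(sprintf("onset_profile: %d onset(s), window [%g, %g] s\n",
              length(x$onsets), x$t_rel[1], x$t_rel[length(x$t_rel)]))
  for (i in seq_along(x$onsets))
    cat(sprintf("  onset %g s: peak pre-onset <T> = %.2f s at %.2f s before onset\n",
                x$onsets[i], x$peak_preonset_T[i], x$peak_latency[i]))
  invisible(x)
}
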
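#' Detect action potentials by threshold crossing
#'
#' One spike is reported per maximal contiguous supra-threshold excursion of
#' the voltage: it opens at the upward crossing of `threshold` and closes at
#' the subsequent downward crossing (or at the end of the trace if the
#' excursion is still open there). The spike peak is the maximum sample
#' within the excursion.
#'
#' @param trace A voltage [nf_trace()].
#' @param threshold Detection threshold in mV (default 0, which separates
#'   full action potentials from sub-threshold activity in conductance-based
#'   models at standard resting potentials).
#' @return A data frame with one row per spike and columns `onset_t`,
#'   `peak_t`, `peak_v`, `offset_t`, `threshold_v` (times in ms, voltages in
#'   mV), ordered by onset time. Shape features (`width`, `ahp_depth`) are
#'   added by [spike_features()].
#' @export
detect_spikes <- function(trace, threshold = 0) {
  stopifnot(inherits(trace, "nf_trace"))
  if (trace$kind != "voltage")
    stop("spike detection requires a voltage trace")
  v <- trace$values
  above <- v >= threshold
  n <- length(v)
  # excursion starts: below -> at/above; a trace starting above threshold
  # opens an excursion at its first sample
  starts <- which(!above[-n] & above[-1L]) + 1L
  if (above[1L]) starts <- c(1L, starts)
  ends <- which(above[-n] & !above[-1L])
  if (above[n]) ends <- c(ends, n)
  if (!length(starts))
    return(data.frame(onset_t = numeric(0), peak_t = numeric(0),
                      peak_v = numeric(0), offset_t = numeric(0),
                      threshold_v = numeric(0)))
  tt <- trace_times(trace)
  peak_i <- mapply(function(s, e) s - 1L + which.max(v[s:e]), starts, ends)
  data.frame(onset_t = tt[starts], peak_t = tt[peak_i], peak_v = v[peak_i],
             offset_t = tt[ends], threshold_v = threshold)
}

# linear-interpolated time at which the trace crosses `level` between
# samples i and i+1
cross_time <- function(tt, v, i, level) {
  if (v[i + 1L] == v[i]) return(tt[i])
  tt[i] + (level - v[i]) / (v[i + 1L] - v[i]) * (tt[i + 1L] - tt[i])
}

#' Complete per-spike shape features
#'
#' For each detected spike: the amplitude is peak voltage minus the threshold
#' voltage in force; the width is the time spent above the half-amplitude
#' level (`threshold + amplitude/2`), with the two crossings located by
#' linear interpolation between samples; the after-hyperpolarization (AHP)
#' depth is the threshold voltage minus the minimum voltage between this
#' spike's offset and the next spike's onset (the last spike searches to the
#' stimulus end or trace end, whichever is earlier).
#'
#' @param trace The voltage [nf_trace()] the spikes were detected on.
#' @param spikes Data frame from [detect_spikes()] on the same trace.
#' @param stim_window Optional `c(t_on, t_off)` in ms bounding the AHP search
#'   after the last spike; defaults to the whole trace.
#' @return The `spikes` data frame with columns `amplitude` (mV), `width`
#'   (ms) and `ahp_depth` (mV, nonnegative) added.
#' @export
spike_features <- function(trace, spikes, stim_window = NULL) {
  stopifnot(inherits(trace, "nf_trace"))
  v <- trace$values
  if (length(v) < 2L) stop("empty trace")
  tt <- trace_times(trace)
  ns <- nrow(spikes)
  spikes$amplitude <- spikes$peak_v - spikes$threshold_v
  spikes$width <- rep(NA_real_, ns)
  spikes$ahp_depth <- rep(NA_real_, ns)
  if (!ns) return(spikes)
  if (any(spikes$onset_t < tt[1L] - 1e-9) ||
      any(spikes$offset_t > tt[length(tt)] + 1e-9))
    stop("spike list inconsistent with trace")
  t_end <- if (is.null(stim_window)) tt[length(tt)] else
    min(stim_window[2L], tt[length(tt)])
  for (k in seq_len(ns)) {
    half <- spikes$threshold_v[k] + spikes$amplitude[k] / 2
    ip <- which.min(abs(tt - spikes$peak_t[k]))
    # walk out from the peak to the first samples below the half level
    i1 <- ip
    while (i1 > 1L && v[i1 - 1L] >= half) i1 <- i1 - 1L
    i2 <- ip
    while (i2 < length(v) && v[i2 + 1L] >= half) i2 <- i2 + 1L
    t_left <- if (i1 > 1L) cross_time(tt, v, i1 - 1L, half) else tt[1L]
    t_right <- if (i2 < length(v)) cross_time(tt, v, i2, half) else tt[length(v)]
    spikes$width[k] <- t_right - t_left
    # AHP window: offset of this spike to onset of the next (or stim/trace end)
    w0 <- spikes$offset_t[k]
    w1 <- if (k < ns) spikes$onset_t[k + 1L] else max(t_end, w0)
    sel <- tt >= w0 - 1e-9 & tt <= w1 + 1e-9
    spikes$ahp_depth[k] <- if (any(sel))
      spikes$threshold_v[k] - min(v[sel]) else 0
  }
  spikes
}
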
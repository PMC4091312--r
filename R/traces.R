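#' Construct a single recorded or simulated trace
#'
#' A trace is a uniformly sampled physical time series. Internally all voltage
#' traces are stored in mV, all current traces in nA, and all times in ms;
#' sample `i` (1-based) lies at time `t0 + (i - 1) * dt`.
#'
#' @param values Numeric vector of samples (at least 2, all finite).
#' @param kind Either `"voltage"` or `"current"`.
#' @param dt Sampling interval in ms (> 0).
#' @param t0 Start time in ms (default 0).
#' @return An object of class `nf_trace`.
#' @examples
#' tr <- nf_trace(sin(seq(0, 2 * pi, length.out = 100)), "voltage", dt = 0.1)
#' trace_duration(tr)
#' @export
nf_trace <- function(values, kind = c("voltage", "current"), dt, t0 = 0) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("a trace needs at least 2 samples, got ", length(values))
  if (!all(is.finite(values)))
    stop("trace contains non-finite samples")
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number (ms)")
  structure(list(values = values, kind = kind, dt = as.numeric(dt),
                 t0 = as.numeric(t0)),
            class = "nf_trace")
}

#' @export
print.nf_trace <- function(x, ...) {
  cat(sprintf("<nf_trace> %s, %d samples, dt = %g ms, duration = %g ms\n",
              x$kind, length(x$values), x$dt, trace_duration(x)))
  invisible(x)
}

#' Trace duration in ms
#'
#' Duration spanned by the samples, `(length - 1) * dt`.
#' @param trace An [nf_trace()].
#' @return Duration in ms.
#' @export
trace_duration <- function(trace) (length(trace$values) - 1) * trace$dt

#' Time points of a trace
#' @param trace An [nf_trace()].
#' @return Numeric vector of sample times in ms.
#' @export
trace_times <- function(trace)
  trace$t0 + (seq_along(trace$values) - 1) * trace$dt

#' Construct a set of traces of identical type
#'
#' All member traces must share kind, sampling interval, and length (one set
#' of data of identical types). An optional vector of stimulus amplitudes
#' labels the traces, one per trace.
#'
#' @param traces List of [nf_trace()] objects.
#' @param amplitudes Optional numeric vector of per-trace stimulus labels (nA
#'   for current-clamp steps, mV for voltage-clamp steps).
#' @return An object of class `nf_trace_set`.
#' @export
nf_trace_set <- function(traces, amplitudes = NULL) {
  if (!length(traces)) stop("empty trace set")
  if (!all(vapply(traces, inherits, logical(1), "nf_trace")))
    stop("all elements must be nf_trace objects")
  kinds <- vapply(traces, `[[`, character(1), "kind")
  dts <- vapply(traces, `[[`, numeric(1), "dt")
  lens <- vapply(traces, function(t) length(t$values), integer(1))
  if (length(unique(kinds)) != 1L)
    stop("all traces in a set must share the same kind")
  if (max(dts) - min(dts) > 1e-12 * max(dts))
    stop("all traces in a set must share the same dt")
  if (length(unique(lens)) != 1L)
    stop("all traces in a set must share the same length")
  if (!is.null(amplitudes) && length(amplitudes) != length(traces))
    stop("'amplitudes' must have one entry per trace")
  structure(list(traces = traces,
                 amplitudes = if (is.null(amplitudes)) NULL else as.numeric(amplitudes)),
            class = "nf_trace_set")
}

#' @export
print.nf_trace_set <- function(x, ...) {
  t1 <- x$traces[[1L]]
  cat(sprintf("<nf_trace_set> %d %s trace(s), %d samples each, dt = %g ms\n",
              length(x$traces), t1$kind, length(t1$values), t1$dt))
  if (!is.null(x$amplitudes))
    cat("  amplitudes:", paste(x$amplitudes, collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.nf_trace_set <- function(x) length(x$traces)

unit_table <- list(
  voltage = c(V = 1e3, mV = 1, uV = 1e-3),
  current = c(uA = 1e3, nA = 1, pA = 1e-3)
)

unit_kind <- function(unit) {
  unit <- sub("µ", "u", unit)          # micro sign
  unit <- sub("μ", "u", unit)          # greek mu
  for (k in names(unit_table))
    if (unit %in% names(unit_table[[k]])) return(list(kind = k, unit = unit))
  stop("unknown unit label: '", unit, "'")
}

#' Convert values between units of the same physical kind
#'
#' Supported voltage units are V, mV, uV and current units uA, nA, pA;
#' conversion is by the exact power-of-ten factor. Converting across kinds
#' (e.g. mV to nA) is an error.
#'
#' @param values Numeric vector.
#' @param from,to Unit labels.
#' @return Rescaled numeric vector.
#' @examples
#' convert_units(0.001, "V", "mV")   # 1
#' convert_units(200, "pA", "nA")    # 0.2
#' @export
convert_units <- function(values, from, to) {
  uf <- unit_kind(from); ut <- unit_kind(to)
  if (uf$kind != ut$kind)
    stop("cannot convert ", from, " (", uf$kind, ") to ", to, " (", ut$kind, ")")
  tab <- unit_table[[uf$kind]]
  values * tab[[uf$unit]] / tab[[ut$unit]]
}

canonical_unit <- function(kind) switch(kind, voltage = "mV", current = "nA")

#' Read a trace set from a plain-text file
#'
#' The file dialect is whitespace-separated numeric columns, one column per
#' trace, no header and no time column; time is implied by `dt`. Values are
#' converted from `unit` to the canonical internal unit (mV or nA).
#'
#' @param path Path to the trace file.
#' @param kind `"voltage"` or `"current"`.
#' @param unit Unit of the stored values (e.g. `"mV"`, `"V"`, `"pA"`).
#' @param dt Sampling interval in ms.
#' @param n_traces Expected number of columns; a mismatch is an error.
#' @return An [nf_trace_set()].
#' @export
read_traces <- function(path, kind = c("voltage", "current"), unit, dt,
                        n_traces = 1L) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("trace file not found: ", path)
  dat <- tryCatch(
    read.table(path, header = FALSE, colClasses = "numeric"),
    error = function(e) stop("failed to parse trace file '", path, "': ",
                             conditionMessage(e)))
  if (ncol(dat) != n_traces)
    stop("trace file '", path, "' has ", ncol(dat), " column(s), expected ",
         n_traces)
  uk <- unit_kind(unit)
  if (uk$kind != kind)
    stop("unit '", unit, "' is a ", uk$kind, " unit but kind is '", kind, "'")
  traces <- lapply(seq_len(ncol(dat)), function(j)
    nf_trace(convert_units(dat[[j]], unit, canonical_unit(kind)), kind, dt))
  nf_trace_set(traces)
}

#' Write a trace set to a plain-text file
#'
#' Inverse of [read_traces()]: one column per trace, whitespace separated,
#' 9 significant digits.
#'
#' @param trace_set An [nf_trace_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(trace_set, path) {
  stopifnot(inherits(trace_set, "nf_trace_set"))
  m <- vapply(trace_set$traces, `[[`, numeric(length(trace_set$traces[[1L]]$values)),
              "values")
  m <- matrix(m, ncol = length(trace_set$traces))
  lines <- apply(m, 1L, function(r) paste(formatC(r, digits = 9, format = "g"),
                                          collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' Align a target trace set with the model sampling grid
#'
#' Every cost function requires both trace sets on the same grid, and the
#' alignment is done once, up front. If the target is sampled faster than the
#' model (`dt < model_dt`), the target is returned unchanged and the
#' simulation step is to be adjusted to the target's `dt`; if it is sampled
#' slower, the target is re-sampled at the model's rate by linear
#' interpolation and from then on the re-sampled set replaces the input.
#'
#' @param target An [nf_trace_set()].
#' @param model_dt Model integration step in ms (> 0).
#' @return A list with elements `target` (possibly re-sampled
#'   [nf_trace_set()]) and `effective_dt` (the common sampling step in ms).
#' @export
align_sampling <- function(target, model_dt) {
  stopifnot(inherits(target, "nf_trace_set"))
  if (!is.numeric(model_dt) || length(model_dt) != 1L || model_dt <= 0)
    stop("'model_dt' must be a single positive number (ms)")
  dt <- target$traces[[1L]]$dt
  if (dt <= model_dt * (1 + 1e-12))
    return(list(target = target, effective_dt = dt))
  resampled <- lapply(target$traces, function(tr) {
    tt <- trace_times(tr)
    grid <- seq(tr$t0, tr$t0 + trace_duration(tr), by = model_dt)
    nf_trace(approx(tt, tr$values, xout = grid)$y, tr$kind, model_dt, tr$t0)
  })
  list(target = nf_trace_set(resampled, target$amplitudes),
       effective_dt = model_dt)
}

# shared precondition for all pairwise trace comparisons
check_aligned <- function(sim, target) {
  s <- sim$traces[[1L]]; x <- target$traces[[1L]]
  if (length(sim) != length(target))
    stop("simulated and target sets have different trace counts (",
         length(sim), " vs ", length(target), ")")
  if (length(s$values) != length(x$values))
    stop("trace length mismatch: ", length(s$values), " vs ",
         length(x$values), "; align sampling first")
  if (abs(s$dt - x$dt) > 1e-12 * max(s$dt, x$dt))
    stop("trace dt mismatch: ", s$dt, " vs ", x$dt, "; align sampling first")
  invisible(TRUE)
}
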
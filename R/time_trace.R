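#' Uniformly sampled time trace
#'
#' Light container for a uniformly sampled scalar series (stimulus intensity,
#' firing rate, calcium concentration, velocity component, ...). Sample `i`
#' (0-based) sits at time `t0 + i * sample_period`; all times are milliseconds.
#'
#' @param values Numeric vector of samples.
#' @param sample_period Sampling period in ms (> 0).
#' @param t0 Time of the first sample in ms.
#' @return An object of class `"time_trace"`.
#' @examples
#' tt <- time_trace(sin(seq(0, 2 * pi, length.out = 100)), sample_period = 10)
#' trace_times(tt)[1:3]
#' @export
time_trace <- function(values, sample_period = 1, t0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("time_trace needs at least one sample")
  if (!is.finite(sample_period) || sample_period <= 0)
    stop("sample_period must be positive")
  structure(list(values = values, sample_period = sample_period, t0 = t0),
            class = "time_trace")
}

#' @export
print.time_trace <- function(x, ...) {
  cat(sprintf("<time_trace> %d samples @ %g ms, t0 = %g ms (duration %g s)\n",
              length(x$values), x$sample_period, x$t0,
              trace_duration(x) / 1000))
  invisible(x)
}

#' @export
length.time_trace <- function(x) length(x$values)

#' Sample times of a trace (ms)
#' @param tt A [time_trace()].
#' @return Numeric vector of sample times in ms.
#' @export
trace_times <- function(tt) {
  tt$t0 + (seq_along(tt$values) - 1) * tt$sample_period
}

#' Total duration covered by a trace (ms)
#' @param tt A [time_trace()].
#' @export
trace_duration <- function(tt) length(tt$values) * tt$sample_period

#' Index of the sample nearest to each query time
#'
#' Errors if any query time falls outside the trace support (half a sample
#' period of slack at either end).
#'
#' @param tt A [time_trace()].
#' @param times_ms Query times in ms.
#' @return Integer indices into `tt$values`.
#' @export
trace_index_at <- function(tt, times_ms) {
  idx <- round((times_ms - tt$t0) / tt$sample_period) + 1
  if (any(idx < 1 | idx > length(tt$values)))
    stop("time outside trace support")
  as.integer(idx)
}

#' Value of the trace at the nearest sample to each query time
#' @inheritParams trace_index_at
#' @export
trace_value_at <- function(tt, times_ms) {
  tt$values[trace_index_at(tt, times_ms)]
}

#' Standardize a trace to zero mean and unit variance
#'
#' Calcium traces and templates are standardized before the error sigmoid is
#' applied so that the half-maximum concentration C_0 = 0 falls at the trace
#' midpoint. A constant trace maps to all zeros.
#'
#' @param tt A [time_trace()].
#' @return A standardized `time_trace` on the same clock.
#' @export
standardize_trace <- function(tt) {
  v <- tt$values
  s <- stats::sd(v)
  v <- if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  time_trace(v, tt$sample_period, tt$t0)
}

#' Read / write time traces as two-column TSV
#'
#' Plain-text interchange: columns `time_ms` and `value` (or `time_ms`, `vx`,
#' `vy` for planar kinematics via `write_kinematics_tsv`). Times must be
#' uniformly spaced.
#'
#' @param path File path.
#' @return `read_trace_tsv` returns a [time_trace()].
#' @export
read_trace_tsv <- function(path) {
  d <- utils::read.delim(path)
  if (!all(c("time_ms", "value") %in% names(d)))
    stop("expected columns time_ms, value")
  per <- if (nrow(d) > 1) diff(d$time_ms[1:2]) else 1
  time_trace(d$value, sample_period = per, t0 = d$time_ms[1])
}

#' @param tt A [time_trace()] to serialize.
#' @rdname read_trace_tsv
#' @export
write_trace_tsv <- function(tt, path) {
  utils::write.table(data.frame(time_ms = trace_times(tt), value = tt$values),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param vx,vy Velocity component [time_trace()]s on a shared clock.
#' @rdname read_trace_tsv
#' @export
write_kinematics_tsv <- function(vx, vy, path) {
  stopifnot(length(vx$values) == length(vy$values),
            vx$sample_period == vy$sample_period)
  utils::write.table(data.frame(time_ms = trace_times(vx),
                                vx = vx$values, vy = vy$values),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_trace_tsv
#' @export
read_kinematics_tsv <- function(path) {
  d <- utils::read.delim(path)
  if (!all(c("time_ms", "vx", "vy") %in% names(d)))
    stop("expected columns time_ms, vx, vy")
  per <- if (nrow(d) > 1) diff(d$time_ms[1:2]) else 1
  list(vx = time_trace(d$vx, per, d$time_ms[1]),
       vy = time_trace(d$vy, per, d$time_ms[1]))
}

# Run expr with a temporarily seeded RNG, restoring prior RNG state after.
# seed = NULL leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Per-trial substreams from one master seed: reproducible and independent of
# the order trials run in.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}
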
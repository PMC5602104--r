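#' Lever position trace
#'
#' A uniformly sampled record of lever angle (degrees from rest) against
#' time, as produced by the rotary encoder for one trial or one stretch of
#' recording.
#'
#' @param samples Numeric vector of angles, degrees from rest.
#' @param t0 Absolute timestamp of the first sample, seconds since
#'   experiment start.
#' @param sample_period Sampling period, ms.
#' @return An object of class `"lever_trace"`.
#' @examples
#' tr <- lever_trace(c(0, 6, 12, 12, 12, 6, 0), t0 = 3600)
#' trace_times_ms(tr)
#' @export
lever_trace <- function(samples, t0 = 0, sample_period = 10) {
  samples <- as.numeric(samples)
  if (length(samples) < 2) stop("malformed trace: need at least 2 samples")
  if (anyNA(samples)) stop("malformed trace: NA angles")
  if (sample_period <= 0) stop("sample_period must be positive")
  structure(list(t0 = t0, samples = samples, sample_period = sample_period),
            class = "lever_trace")
}

#' Sample times of a trace
#'
#' @param trace A [lever_trace()].
#' @return Times of each sample in ms, relative to the first sample.
#' @export
trace_times_ms <- function(trace) {
  stopifnot(inherits(trace, "lever_trace"))
  (seq_along(trace$samples) - 1) * trace$sample_period
}

#' @export
print.lever_trace <- function(x, ...) {
  cat(sprintf("<lever_trace> %d samples @ %g ms (%.2f s), t0 = %.3f s, range [%.2f, %.2f] deg\n",
              length(x$samples), x$sample_period,
              (length(x$samples) - 1) * x$sample_period / 1000,
              x$t0, min(x$samples), max(x$samples)))
  invisible(x)
}

# range check against the configured mechanical limits
check_trace_range <- function(trace, cfg) {
  r <- range(trace$samples)
  if (r[1] < 0 || r[2] > cfg$lever_range_max)
    stop(sprintf("angle out of range: trace spans [%.3f, %.3f], lever range is [0, %g]",
                 r[1], r[2], cfg$lever_range_max))
  invisible(trace)
}

#' Read and write per-trial trace CSV files
#'
#' Traces are stored as two-column CSV (`time_ms`, `angle_deg`) with
#' `time_ms` starting at 0. Reading enforces uniform sampling.
#'
#' @param path CSV file path.
#' @param trace A [lever_trace()].
#' @param t0 Absolute start time to attach to the trace read, seconds.
#' @return `read_trace_csv()` returns a `lever_trace`; `write_trace_csv()`
#'   returns `path` invisibly.
#' @export
read_trace_csv <- function(path, t0 = 0) {
  df <- utils::read.csv(path)
  if (!all(c("time_ms", "angle_deg") %in% names(df)))
    stop("trace file must have columns time_ms, angle_deg: ", path)
  dt <- diff(df$time_ms)
  if (length(dt) == 0) stop("malformed trace: fewer than 2 samples in ", path)
  if (any(abs(dt - dt[1]) > 1e-9) || dt[1] <= 0)
    stop("malformed trace: non-uniform sampling in ", path)
  lever_trace(df$angle_deg, t0 = t0, sample_period = dt[1])
}

#' @rdname read_trace_csv
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "lever_trace"))
  utils::write.csv(
    data.frame(time_ms = trace_times_ms(trace), angle_deg = trace$samples),
    path, row.names = FALSE)
  invisible(path)
}
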
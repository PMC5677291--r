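#' Uniformly sampled single-channel biosignal
#'
#' Lightweight container for one channel of a physiological recording:
#' a numeric sample vector with its sampling rate, channel kind and start
#' time. All pipeline stages consume and produce this class.
#'
#' @param samples Numeric vector of samples. Units depend on the channel:
#'   arbitrary units for PPG, microsiemens for EDA, degrees Celsius for SKT.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel One of `"ppg"`, `"eda"`, `"skt"`.
#' @param t0 Time of the first sample in seconds (default 0).
#'
#' @return An object of class `time_series` with fields `samples`, `fs`,
#'   `channel`, `t0`.
#' @examples
#' ts <- time_series(sin(2 * pi * seq(0, 1, by = 1 / 100)), fs = 100,
#'                   channel = "ppg")
#' ts_duration(ts)
#' @export
time_series <- function(samples, fs, channel = c("ppg", "eda", "skt"),
                        t0 = 0) {
  channel <- match.arg(channel)
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive finite scalar", call. = FALSE)
  if (length(samples) < 1L)
    stop("`samples` must contain at least one value", call. = FALSE)
  if (!all(is.finite(samples)))
    stop("all samples must be finite", call. = FALSE)
  structure(list(samples = samples, fs = fs, channel = channel, t0 = t0),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("<time_series> channel=%s fs=%g Hz n=%d duration=%.3f s\n",
              x$channel, x$fs, length(x$samples), ts_duration(x)))
  invisible(x)
}

#' Duration of a time series in seconds
#'
#' @param x A [time_series()].
#' @return Duration `length(samples) / fs` in seconds.
#' @export
ts_duration <- function(x) {
  stopifnot(inherits(x, "time_series"))
  length(x$samples) / x$fs
}

#' Sample times of a time series
#'
#' @param x A [time_series()].
#' @return Numeric vector of sample times in seconds (first sample at `t0`).
#' @export
ts_times <- function(x) {
  stopifnot(inherits(x, "time_series"))
  x$t0 + (seq_along(x$samples) - 1L) / x$fs
}

# Extract the samples in [t_start, t_end) as a new time_series.
ts_window <- function(x, t_start, t_end) {
  i0 <- as.integer(round((t_start - x$t0) * x$fs)) + 1L
  i1 <- as.integer(round((t_end - x$t0) * x$fs))
  i0 <- max(1L, i0)
  i1 <- min(length(x$samples), i1)
  if (i1 < i0) stop("empty window", call. = FALSE)
  time_series(x$samples[i0:i1], x$fs, x$channel,
              t0 = x$t0 + (i0 - 1L) / x$fs)
}

# Run `expr` with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Deterministically derive a child stream seed from a master seed and a
# set of integer/string tags. Kept below 2^31 - 1.
derive_seed <- function(master, ...) {
  tags <- list(...)
  h <- as.numeric(master) %% 2147483647
  for (tag in tags) {
    if (is.character(tag)) tag <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
    h <- (h * 48271 + as.numeric(tag) + 1) %% 2147483647
  }
  as.integer(h)
}

# Half-up decimal rounding for report views (R's round() is banker's).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
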
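#' Band-pass filter a PPG signal
#'
#' Zero-phase (forward-backward) 4th-order Butterworth band-pass. The
#' default 0.5--4 Hz band removes slow motion artifacts (below 0.1 Hz)
#' and high-frequency noise while enhancing the heartbeat component
#' around 1 Hz. Forward-backward filtering preserves pulse-peak timing.
#'
#' @param x A `"ppg"` [time_series()].
#' @param low,high Band edges in Hz; `high` must be below the Nyquist
#'   frequency `fs / 2`.
#' @param order Butterworth order per pass (default 4).
#'
#' @return Filtered [time_series()] of the same length and sampling rate,
#'   with the DC component removed.
#' @export
bandpass_ppg <- function(x, low = 0.5, high = 4, order = 4) {
  stopifnot(inherits(x, "time_series"))
  if (x$channel != "ppg")
    stop("`x` must be a ppg channel", call. = FALSE)
  if (low <= 0 || high <= low || high >= x$fs / 2)
    stop("require 0 < low < high < fs/2", call. = FALSE)
  bf <- signal::butter(order, c(low, high) / (x$fs / 2), type = "pass")
  # demean and reflect-pad before the forward-backward pass to suppress
  # start/end transients
  v <- x$samples - mean(x$samples)
  np <- min(length(v) - 1L, round(10 * x$fs))
  padded <- c(rev(v[seq_len(np)]), v, rev(v[(length(v) - np + 1L):length(v)]))
  y <- signal::filtfilt(bf, padded)[(np + 1L):(np + length(v))]
  time_series(y, x$fs, "ppg", t0 = x$t0)
}

#' Cut a session into fixed-duration epochs
#'
#' Discards the leading `discard_lead` seconds (unstable signal at
#' session start) and splits the remainder into consecutive,
#' non-overlapping epochs of `epoch_duration` seconds; a trailing
#' remainder shorter than one epoch is dropped. Epoch `i` covers the
#' half-open interval `[discard_lead + (i-1) * d, discard_lead + i * d)`.
#' A 240-s session with the defaults yields 34 epochs.
#'
#' @param x A [time_series()].
#' @param discard_lead Leading discard in seconds (default 35).
#' @param epoch_duration Epoch length in seconds (default 6).
#'
#' @return An `epoch_set`: list with `epochs` (list of [time_series()],
#'   each of exactly `round(epoch_duration * fs)` samples), `t_start`,
#'   `t_end`, `epoch_duration`, `discard_lead`.
#' @export
segment_epochs <- function(x, discard_lead = 35, epoch_duration = 6) {
  stopifnot(inherits(x, "time_series"))
  dur <- ts_duration(x)
  if (dur <= discard_lead)
    stop("signal duration (", format(dur),
         " s) does not exceed the leading discard (", discard_lead,
         " s); no epochs can be formed", call. = FALSE)
  n_ep <- floor((dur - discard_lead) / epoch_duration + 1e-9)
  if (n_ep < 1)
    stop("signal too short for a single epoch after the leading discard",
         call. = FALSE)
  n_per <- round(epoch_duration * x$fs)
  i_off <- round(discard_lead * x$fs)
  epochs <- vector("list", n_ep)
  t_start <- numeric(n_ep)
  for (i in seq_len(n_ep)) {
    i0 <- i_off + (i - 1L) * n_per + 1L
    epochs[[i]] <- time_series(x$samples[i0:(i0 + n_per - 1L)], x$fs,
                               x$channel,
                               t0 = x$t0 + (i0 - 1L) / x$fs)
    t_start[i] <- x$t0 + discard_lead + (i - 1) * epoch_duration
  }
  structure(list(epochs = epochs, t_start = t_start,
                 t_end = t_start + epoch_duration,
                 epoch_duration = epoch_duration,
                 discard_lead = discard_lead),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs of %g s (lead discard %g s)\n",
              length(x$epochs), x$epoch_duration, x$discard_lead))
  invisible(x)
}

#' Detect pulse peaks in a filtered PPG signal
#'
#' Finds strict local maxima above an adaptive amplitude threshold
#' (median plus half the interquartile range of the filtered signal) and
#' enforces a refractory period: of any two candidates closer than
#' `min_rr` seconds, only the larger is retained. The default 0.3 s
#' refractory period caps heart rate at 200 bpm.
#'
#' @param x A band-passed `"ppg"` [time_series()].
#' @param min_rr Minimum peak separation in seconds.
#'
#' @return Numeric vector of strictly increasing peak times in seconds.
#'   Raises an error of class `stresskelm_insufficient_peaks` when fewer
#'   than two peaks are found.
#' @export
detect_peaks <- function(x, min_rr = 0.3) {
  stopifnot(inherits(x, "time_series"))
  v <- x$samples
  n <- length(v)
  thr <- stats::median(v) + 0.5 * stats::IQR(v)
  cand <- which(v[-c(1L, n)] > v[-c(n - 1L, n)] &
                  v[-c(1L, n)] > v[-c(1L, 2L)]) + 1L
  cand <- cand[v[cand] > thr]
  if (length(cand) >= 2L) {
    # refractory pruning: greedy by amplitude
    ord <- cand[order(v[cand], decreasing = TRUE)]
    keep <- logical(0)
    kept <- integer(0)
    min_gap <- min_rr * x$fs
    for (ci in ord) {
      if (!length(kept) || all(abs(kept - ci) >= min_gap))
        kept <- c(kept, ci)
    }
    cand <- sort(kept)
  }
  if (length(cand) < 2L) {
    cnd <- structure(class = c("stresskelm_insufficient_peaks", "error",
                               "condition"),
                     list(message = sprintf(
                       "fewer than 2 pulse peaks detected (%d found)",
                       length(cand)), call = sys.call()))
    stop(cnd)
  }
  x$t0 + (cand - 1L) / x$fs
}

#' Normal-to-normal (NN) intervals from pulse-peak times
#'
#' The differences between successive detected pulse peaks, in ms.
#'
#' @param peaks Strictly increasing peak times in seconds (length >= 2).
#'
#' @return An `nn_series`: list with `peak_times` (s) and `nn` (ms),
#'   where `nn[i] = (peak_times[i+1] - peak_times[i]) * 1000`.
#' @export
compute_nn <- function(peaks) {
  if (length(peaks) < 2L) {
    cnd <- structure(class = c("stresskelm_insufficient_peaks", "error",
                               "condition"),
                     list(message = "need at least 2 peaks to form NN intervals",
                          call = sys.call()))
    stop(cnd)
  }
  if (any(diff(peaks) <= 0))
    stop("peak times must be strictly increasing", call. = FALSE)
  structure(list(peak_times = peaks, nn = diff(peaks) * 1000),
            class = "nn_series")
}

#' @export
print.nn_series <- function(x, ...) {
  cat(sprintf("<nn_series> %d intervals, mean %.1f ms\n",
              length(x$nn), mean(x$nn)))
  invisible(x)
}
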
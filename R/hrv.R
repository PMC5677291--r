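#' Time-domain HRV features
#'
#' Seven statistics of the NN-interval sequence. With successive
#' differences `d[i] = nn[i+1] - nn[i]`:
#' \itemize{
#'   \item `NNavg` mean NN interval (ms); `HRavg = 60000 / NNavg` (bpm)
#'   \item `SDNN` sample SD of the NN intervals (ms)
#'   \item `SDSD` sample SD of `d`; `RMSSD = sqrt(mean(d^2))` (ms)
#'   \item `pNN20`, `pNN50`: fraction of successive differences exceeding
#'     20 / 50 ms in magnitude. The denominator is the total number of NN
#'     intervals (`pnn_denominator = "intervals"`, the convention used
#'     throughout this package) or, optionally, the number of successive
#'     pairs (`"pairs"`, the more common convention in the HRV
#'     literature).
#' }
#'
#' @param nn An `nn_series` from [compute_nn()], or a numeric vector of
#'   NN intervals in ms.
#' @param pnn_denominator `"intervals"` (default) or `"pairs"`.
#'
#' @return Named list `HRavg`, `NNavg`, `SDNN`, `SDSD`, `RMSSD`, `pNN20`,
#'   `pNN50`; all `NA` (missing-feature marker) when fewer than two
#'   intervals are available.
#' @export
hrv_time_domain <- function(nn, pnn_denominator = c("intervals", "pairs")) {
  pnn_denominator <- match.arg(pnn_denominator)
  v <- nn_values(nn)
  out <- list(HRavg = NA_real_, NNavg = NA_real_, SDNN = NA_real_,
              SDSD = NA_real_, RMSSD = NA_real_, pNN20 = NA_real_,
              pNN50 = NA_real_)
  if (length(v) < 2L) return(out)
  d <- diff(v)
  denom <- if (pnn_denominator == "intervals") length(v) else length(d)
  out$NNavg <- mean(v)
  out$HRavg <- 60000 / out$NNavg
  out$SDNN <- stats::sd(v)
  out$SDSD <- stats::sd(d)
  out$RMSSD <- sqrt(mean(d^2))
  out$pNN20 <- sum(abs(d) > 20) / denom
  out$pNN50 <- sum(abs(d) > 50) / denom
  out
}

nn_values <- function(nn) {
  if (inherits(nn, "nn_series")) nn$nn else as.numeric(nn)
}

#' NN tachogram by cubic-spline interpolation
#'
#' The NN intervals are an unevenly sampled series (one value per beat,
#' at the time of the closing peak). Spectral analysis requires a uniform
#' grid, so the intervals are cubic-spline interpolated at `resample_hz`
#' over the observed span.
#'
#' @param nn An `nn_series` (peak times are required for the grid).
#' @param resample_hz Resampling rate in Hz (default 4).
#'
#' @return A `tachogram`: list with `t` (s, uniform) and `v` (ms), or
#'   `NULL` (missing-feature marker) with fewer than 3 intervals.
#' @export
nn_tachogram <- function(nn, resample_hz = 4) {
  stopifnot(inherits(nn, "nn_series"))
  if (length(nn$nn) < 3L) return(NULL)
  t_obs <- nn$peak_times[-1L]
  grid <- seq(t_obs[1], t_obs[length(t_obs)], by = 1 / resample_hz)
  if (length(grid) < 2L) return(NULL)
  v <- stats::spline(t_obs, nn$nn, xout = grid, method = "fmm")$y
  structure(list(t = grid, v = v, fs = resample_hz), class = "tachogram")
}

#' Autoregressive power spectral density of a tachogram
#'
#' Fits an AR model by Burg's method to the demeaned tachogram and
#' evaluates the parametric one-sided PSD
#' `p(f) = 2 * s2 / fs / |1 - sum_k a_k exp(-2 pi i k f / fs)|^2`
#' on a dense grid over `[0, fs/2]`. The requested order is capped at
#' `floor(n/2) - 1` for short series.
#'
#' @param tach A `tachogram` from [nn_tachogram()].
#' @param order Requested AR order (default 16).
#' @param n_freq Number of frequency-grid points (default 512).
#'
#' @return A `psd`: list with `f` (Hz) and `p` (ms^2/Hz, non-negative),
#'   plus the fitted `order`. `NULL` when the tachogram is missing or has
#'   fewer than 5 samples. A zero-variance tachogram returns a zero PSD.
#' @export
ar_psd <- function(tach, order = 16, n_freq = 512) {
  if (is.null(tach)) return(NULL)
  stopifnot(inherits(tach, "tachogram"))
  v <- tach$v
  n <- length(v)
  if (n < 5L) return(NULL)
  f <- seq(0, tach$fs / 2, length.out = n_freq)
  if (stats::var(v) < 1e-12) {
    return(structure(list(f = f, p = rep(0, n_freq), order = 0L),
                     class = "psd"))
  }
  p_ord <- min(order, floor(n / 2) - 1L)
  fit <- stats::ar.burg(v, aic = FALSE, order.max = p_ord, demean = TRUE)
  a <- fit$ar
  s2 <- fit$var.pred
  # transfer function 1 / A(e^{-i 2 pi f / fs})
  k <- seq_along(a)
  denom <- vapply(f, function(fi) {
    z <- 1 - sum(a * exp(-2i * pi * k * fi / tach$fs))
    Mod(z)^2
  }, numeric(1))
  p <- 2 * s2 / tach$fs / denom
  structure(list(f = f, p = pmax(p, 0), order = p_ord), class = "psd")
}

#' Normalized LF/HF band powers from a PSD
#'
#' Trapezoid-rule areas under the PSD over the low-frequency band
#' (0.04--0.15 Hz) and high-frequency band (0.15--0.4 Hz), reported as
#' normalized fractions `LF/(LF+HF)`, `HF/(LF+HF)` and the ratio `LF/HF`.
#'
#' @param psd A `psd` from [ar_psd()].
#' @param lf_band,hf_band Band edges in Hz.
#' @param lf_hf_cap Value reported for `LF_HF` when the HF integral is
#'   zero (default 100).
#'
#' @return Named list `LFnormal`, `HFnormal`, `LF_HF`; all `NA` when the
#'   PSD is missing or both band integrals vanish.
#' @export
band_powers <- function(psd, lf_band = c(0.04, 0.15),
                        hf_band = c(0.15, 0.4), lf_hf_cap = 100) {
  out <- list(LFnormal = NA_real_, HFnormal = NA_real_, LF_HF = NA_real_)
  if (is.null(psd)) return(out)
  stopifnot(inherits(psd, "psd"))
  lf <- band_integral(psd$f, psd$p, lf_band[1], lf_band[2])
  hf <- band_integral(psd$f, psd$p, hf_band[1], hf_band[2])
  if (lf + hf <= 0) return(out)
  out$LFnormal <- lf / (lf + hf)
  out$HFnormal <- hf / (lf + hf)
  out$LF_HF <- if (hf > 0) min(lf / hf, lf_hf_cap) else lf_hf_cap
  out
}

# Trapezoid integral of (f, p) over [f1, f2], with linear interpolation
# at the band edges.
band_integral <- function(f, p, f1, f2) {
  if (f2 <= f[1] || f1 >= f[length(f)]) return(0)
  fi <- sort(unique(c(f[f > f1 & f < f2], f1, f2)))
  pi_ <- stats::approx(f, p, xout = fi, rule = 2)$y
  sum(diff(fi) * (pi_[-length(pi_)] + pi_[-1]) / 2)
}

#' Approximate entropy (ApEn)
#'
#' Pincus's regularity statistic: `ApEn = Phi_m(r) - Phi_{m+1}(r)` where
#' `Phi_m(r)` is the mean log fraction of template vectors of length `m`
#' within Chebyshev distance `r` of each template, self-matches included.
#'
#' @param series Numeric vector.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance; defaults to `0.2 * sd(series)`. A constant series
#'   (`r = 0`) is perfectly regular and returns 0.
#'
#' @return ApEn in nats; `NA` when the series is shorter than `m + 2`.
#' @export
approximate_entropy <- function(series, m = 2, r = 0.2 * stats::sd(series)) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < m + 2) return(NA_real_)
  if (!is.finite(r) || r <= 0) {
    if (max(x) - min(x) < 1e-12) return(0)  # constant: perfectly regular
    stop("`r` must be positive for a non-constant series", call. = FALSE)
  }
  phi <- function(mm) {
    counts <- template_match_counts(x, mm, r, self = TRUE)
    mean(log(counts / (n - mm + 1)))
  }
  phi(m) - phi(m + 1)
}

#' Sample entropy (SampEn)
#'
#' `SampEn = -log(A / B)` where `B` and `A` count template-vector pairs
#' (of length `m` and `m + 1` respectively) within Chebyshev distance
#' `r`, self-matches excluded. Unlike ApEn it carries no self-match bias.
#'
#' @inheritParams approximate_entropy
#' @return SampEn in nats; 0 for a constant series; `NA` when the series
#'   is too short or no `m`-length template pairs match (undefined).
#' @export
sample_entropy <- function(series, m = 2, r = 0.2 * stats::sd(series)) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < m + 2) return(NA_real_)
  if (!is.finite(r) || r <= 0) {
    if (max(x) - min(x) < 1e-12) return(0)
    stop("`r` must be positive for a non-constant series", call. = FALSE)
  }
  # Richman-Moorman convention: both template lengths are counted over
  # the same n - m starting positions
  nt <- n - m
  b <- template_pair_count(x, m, r, nt)
  a <- template_pair_count(x, m + 1, r, nt)
  if (b == 0 || a == 0) return(NA_real_)
  -log(a / b)
}

# Chebyshev-distance template matching. Returns, for each of the
# n - m + 1 templates of length m, the number of templates within r
# (including itself when self = TRUE).
template_match_counts <- function(x, m, r, self = TRUE) {
  n <- length(x)
  nt <- n - m + 1L
  # distance between templates i,j = max over offset k of |x[i+k]-x[j+k]|
  d <- abs(outer(x[1:nt], x[1:nt], "-"))
  if (m > 1) {
    for (k in 1:(m - 1L)) {
      d <- pmax(d, abs(outer(x[(1 + k):(nt + k)], x[(1 + k):(nt + k)], "-")))
    }
  }
  cnt <- rowSums(d <= r)
  if (!self) cnt <- cnt - 1
  cnt
}

# Number of distinct pairs (i < j) of length-m templates (starting
# positions 1..nt) whose Chebyshev distance is <= r.
template_pair_count <- function(x, m, r, nt) {
  d <- abs(outer(x[1:nt], x[1:nt], "-"))
  if (m > 1) {
    for (k in 1:(m - 1L)) {
      idx <- (1 + k):(nt + k)
      d <- pmax(d, abs(outer(x[idx], x[idx], "-")))
    }
  }
  (sum(d <= r) - nt) / 2
}

#' Poincare-plot dispersion (SD1, SD2)
#'
#' Each NN interval is plotted against the next. `SD1` is the dispersion
#' perpendicular to the identity line, `SD2` along it:
#' `SD1 = sd((nn[i+1] - nn[i]) / sqrt(2))`,
#' `SD2 = sd((nn[i+1] + nn[i]) / sqrt(2))` (sample SD).
#'
#' @param nn An `nn_series` or numeric NN vector (ms), length >= 3.
#' @return Named list `SD1`, `SD2`, `SD1_SD2` (ratio; `NA` when
#'   `SD2 = 0`). All `NA` with fewer than 3 intervals.
#' @export
poincare <- function(nn) {
  v <- nn_values(nn)
  out <- list(SD1 = NA_real_, SD2 = NA_real_, SD1_SD2 = NA_real_)
  if (length(v) < 3L) return(out)
  a <- v[-length(v)]
  b <- v[-1L]
  out$SD1 <- stats::sd((b - a) / sqrt(2))
  out$SD2 <- stats::sd((b + a) / sqrt(2))
  out$SD1_SD2 <- if (out$SD2 > 0) out$SD1 / out$SD2 else NA_real_
  out
}

#' All 15 HRV features for one epoch
#'
#' Combines the time-domain statistics, the frequency-domain band powers
#' from the Burg AR spectrum of the spline-interpolated NN tachogram,
#' and the nonlinear measures (approximate and sample entropy with
#' `m = 2`, `r = 0.2 * SDNN`; Poincare SD1/SD2). Features that cannot be
#' computed on a short epoch are returned as `NA` missing-feature markers
#' and are imputed downstream (see [build_feature_table()]).
#'
#' @param nn An `nn_series` from [compute_nn()].
#' @param resample_hz Tachogram resampling rate (Hz).
#' @param ar_order Requested Burg AR order.
#' @param pnn_denominator See [hrv_time_domain()].
#'
#' @return Named list of the 15 HRV features, in panel order.
#' @export
hrv_features <- function(nn, resample_hz = 4, ar_order = 16,
                         pnn_denominator = "intervals") {
  td <- hrv_time_domain(nn, pnn_denominator = pnn_denominator)
  tach <- if (inherits(nn, "nn_series") && length(nn$nn) >= 3L)
    nn_tachogram(nn, resample_hz) else NULL
  fd <- band_powers(ar_psd(tach, order = ar_order))
  v <- nn_values(nn)
  r <- if (length(v) >= 2L && is.finite(td$SDNN) && td$SDNN > 0)
    0.2 * td$SDNN else 0
  ap <- if (length(v) >= 4L) {
    if (r > 0) approximate_entropy(v, m = 2, r = r)
    else approximate_entropy(v, m = 2, r = 0)
  } else NA_real_
  sp <- if (length(v) >= 4L) {
    if (r > 0) sample_entropy(v, m = 2, r = r)
    else sample_entropy(v, m = 2, r = 0)
  } else NA_real_
  pc <- poincare(v)
  c(td[c("HRavg", "NNavg", "SDNN", "SDSD", "RMSSD", "pNN20", "pNN50")],
    fd[c("LFnormal", "HFnormal", "LF_HF")],
    list(ApEn = ap, SampEn = sp),
    pc[c("SD1", "SD2", "SD1_SD2")])
}

#' Names of the 24-feature panel
#'
#' @param set `"HRV"` (15), `"SC"` (6), `"SKT"` (3) or `"IT"` (all 24).
#' @return Character vector of feature column names.
#' @export
feature_names <- function(set = c("IT", "HRV", "SC", "SKT")) {
  set <- match.arg(set)
  hrv <- c("HRavg", "NNavg", "SDNN", "SDSD", "RMSSD", "pNN20", "pNN50",
           "LFnormal", "HFnormal", "LF_HF", "ApEn", "SampEn",
           "SD1", "SD2", "SD1_SD2")
  sc <- c("SCavg", "SCLavg", "SCLslope", "SCRavg", "SCRmax", "SCRpeak")
  skt <- c("SKTavg", "SKTslope", "SKTstd")
  switch(set, HRV = hrv, SC = sc, SKT = skt, IT = c(hrv, sc, skt))
}
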
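#' Decompose skin conductance into tonic and phasic components
#'
#' Joint penalized least-squares decomposition `y ~ tonic + driver (*)
#' kernel`: the tonic level (SCL) carries a stiff second-difference
#' smoothness penalty (so constant levels and linear drifts are
#' reproduced exactly while fast activity is excluded), and the
#' sudomotor driver -- constrained non-negative by active-set
#' refinement -- is ridge-penalized and convolved with a Bateman
#' biexponential kernel `exp(-t/tau2) - exp(-t/tau1)` (peak normalized)
#' to form the phasic component (SCR). Both components are estimated in
#' one sparse linear system on a decimated grid (`fs_dec`) and
#' interpolated back to the input rate.
#'
#' @param x An `"eda"` [time_series()] of duration at least `2 * tau2`.
#' @param tau1,tau2 Bateman kernel time constants, s (`0 < tau1 < tau2`).
#' @param fs_dec Internal decimation rate, Hz (default 8).
#' @param lambda_base Second-difference penalty of the tonic baseline.
#' @param lambda_deconv Ridge penalty of the deconvolution.
#'
#' @return An `sc_decomposition`: list with `tonic`, `phasic` (both
#'   [time_series()] at the input rate), `driver` (non-negative
#'   [time_series()] at `fs_dec`, stored in the `eda` channel slot),
#'   `events` (data.frame of fitted event onsets and amplitudes), and
#'   `kernel_params = c(tau1, tau2)`. `tonic + phasic` reconstructs the
#'   input to within a few percent of its range.
#' @export
decompose_sc <- function(x, tau1 = 0.75, tau2 = 2.0, fs_dec = 8,
                         lambda_base = 1e5, lambda_deconv = 0.05) {
  stopifnot(inherits(x, "time_series"))
  if (x$channel != "eda") stop("`x` must be an eda channel", call. = FALSE)
  if (tau1 <= 0 || tau2 <= 0 || tau1 >= tau2)
    stop("require 0 < tau1 < tau2", call. = FALSE)
  if (ts_duration(x) < 2 * tau2)
    stop("signal shorter than 2 * tau2; too short to decompose",
         call. = FALSE)
  fs_dec <- min(fs_dec, x$fs)
  t_full <- ts_times(x)
  # decimate by averaging over bins (acts as an anti-alias low-pass)
  step <- max(1L, round(x$fs / fs_dec))
  n_dec <- floor(length(x$samples) / step)
  y <- colMeans(matrix(x$samples[seq_len(n_dec * step)], nrow = step))
  fs_d <- x$fs / step
  t_dec <- x$t0 + (seq_len(n_dec) - 0.5) * step / x$fs

  kern <- bateman_kernel(fs_d, tau1, tau2)
  fit <- joint_sc_fit(y, kern, lambda_base, lambda_deconv)
  tonic_d <- fit$tonic
  driver <- fit$driver

  tonic <- stats::approx(t_dec, tonic_d, xout = t_full, rule = 2)$y
  # the decimated grid localizes events; their onset time and amplitude
  # are then re-fit at the full rate so the phasic component keeps the
  # kernel's sharp onset
  refit <- refit_events(x$samples - tonic, x$fs, tau1, tau2, t0 = x$t0)
  structure(list(
    tonic = time_series(tonic, x$fs, "eda", t0 = x$t0),
    phasic = time_series(refit$phasic, x$fs, "eda", t0 = x$t0),
    driver = time_series(pmax(driver, 0), fs_d, "eda", t0 = t_dec[1]),
    events = refit$events,
    kernel_params = c(tau1 = tau1, tau2 = tau2)),
    class = "sc_decomposition")
}

# Full-rate sparse event refit by orthogonal matching pursuit: the
# onset whose kernel best explains the current residual is added to the
# active set and the amplitudes of *all* active events are re-fit
# jointly (non-negative least squares via the kernel Gram matrix) before
# the next onset is searched. The joint refit is what resolves clusters
# of overlapping responses that a plain greedy pursuit misfits. The
# kernel cross-correlation of the residual is computed once by FFT and
# rebuilt incrementally from the kernel autocorrelation.
refit_events <- function(resid, fs, tau1, tau2, t0 = 0,
                         amp_min = 0.05, max_events = 400) {
  n <- length(resid)
  empty <- list(phasic = numeric(n),
                events = data.frame(time_s = numeric(0),
                                    amplitude_uS = numeric(0)))
  kern <- bateman_kernel(fs, tau1, tau2)
  nk <- length(kern)
  k2 <- sum(kern^2)
  nfft <- stats::nextn(n + nk)
  fr <- stats::fft(c(resid, rep(0, nfft - n)))
  fk <- stats::fft(c(kern, rep(0, nfft - nk)))
  # cc0[i] = sum_j resid[i + j - 1] * kern[j]  (onset alignment at i)
  cc0 <- Re(stats::fft(fr * Conj(fk), inverse = TRUE))[seq_len(n)] / nfft
  # kernel autocorrelation at lags -(nk-1)..(nk-1)
  ac <- Re(stats::fft(fk * Conj(fk), inverse = TRUE)) / nfft
  ac <- c(rev(ac[2:nk]), ac[1:nk])
  ac_at <- function(lag) {
    v <- numeric(length(lag))
    ok <- abs(lag) < nk
    v[ok] <- ac[lag[ok] + nk]
    v
  }

  sel <- integer(0)
  amps <- numeric(0)
  cc <- cc0
  masked <- logical(n)   # selected onsets are excluded from the search
  for (it in seq_len(max_events)) {
    cc_search <- cc
    cc_search[masked] <- -Inf
    i0 <- which.max(cc_search)
    if (!is.finite(cc_search[i0]) || cc_search[i0] / k2 < amp_min) break
    masked[max(1L, i0 - 1L):min(n, i0 + 1L)] <- TRUE
    sel <- c(sel, i0)
    m <- length(sel)
    G <- outer(sel, sel, function(a_, b_) ac_at(a_ - b_)) +
      diag(1e-10 * k2, m)
    b <- cc0[sel]
    a_new <- solve(G, b)
    # enforce non-negative amplitudes by active-set clipping
    for (pass in 1:3) {
      neg <- a_new < 0
      if (!any(neg)) break
      pos <- which(!neg)
      a_new <- numeric(m)
      if (length(pos))
        a_new[pos] <- solve(G[pos, pos, drop = FALSE], b[pos])
    }
    a_new[a_new < 0] <- 0
    amps <- a_new
    # rebuild cc from the closed form: residual correlation minus the
    # active events' contributions through the autocorrelation
    cc <- cc0
    for (e in seq_len(m)) {
      if (amps[e] == 0) next
      rng <- max(1L, sel[e] - nk + 1L):min(n, sel[e] + nk - 1L)
      cc[rng] <- cc[rng] - amps[e] * ac[rng - sel[e] + nk]
    }
  }
  # onset refinement: coordinate descent over event onsets -- remove
  # each event from the model, re-search its onset in a local window,
  # and re-insert with the locally optimal amplitude; all through the
  # autocorrelation updates of cc, then one final joint amplitude fit
  half_w <- round(0.5 * fs)
  for (sweep in seq_len(2)) {
    if (!length(sel)) break
    moved <- FALSE
    for (e in order(amps, decreasing = TRUE)) {
      if (amps[e] == 0) next
      rng <- max(1L, sel[e] - nk + 1L):min(n, sel[e] + nk - 1L)
      cc[rng] <- cc[rng] + amps[e] * ac[rng - sel[e] + nk]
      win <- max(1L, sel[e] - half_w):min(n, sel[e] + half_w)
      i_new <- win[which.max(cc[win])]
      a_new <- max(0, cc[i_new] / k2)
      if (i_new != sel[e]) moved <- TRUE
      sel[e] <- i_new
      amps[e] <- a_new
      if (a_new > 0) {
        rng <- max(1L, i_new - nk + 1L):min(n, i_new + nk - 1L)
        cc[rng] <- cc[rng] - a_new * ac[rng - i_new + nk]
      }
    }
    if (!moved) break
  }
  if (length(sel)) {
    # final joint non-negative amplitude fit at the refined onsets
    m <- length(sel)
    G <- outer(sel, sel, function(a_, b_) ac_at(a_ - b_)) +
      diag(1e-10 * k2, m)
    b <- cc0[sel]
    amps <- solve(G, b)
    for (pass in 1:3) {
      neg <- amps < 0
      if (!any(neg)) break
      pos <- which(!neg)
      amps <- numeric(m)
      if (length(pos))
        amps[pos] <- solve(G[pos, pos, drop = FALSE], b[pos])
    }
    amps[amps < 0] <- 0
  }
  keep <- which(amps >= amp_min)
  if (!length(keep)) return(empty)
  phasic <- numeric(n)
  for (e in keep) {
    idx <- sel[e]:min(n, sel[e] + nk - 1L)
    phasic[idx] <- phasic[idx] + amps[e] * kern[seq_along(idx)]
  }
  events <- data.frame(time_s = t0 + (sel[keep] - 1L) / fs,
                       amplitude_uS = amps[keep])
  events <- events[order(events$time_s), , drop = FALSE]
  rownames(events) <- NULL
  list(phasic = phasic, events = events)
}

# Joint tonic + non-negative driver fit: minimize over (t, d)
#   ||t + K d - y||^2 + lambda_b ||D2 t||^2 + lambda_d ||d||^2,  d >= 0
# with K the lower-triangular banded Toeplitz convolution matrix of the
# Bateman kernel and D2 the second-difference operator (linear tonic
# trends are unpenalized). The unconstrained sparse normal equations are
# solved first; non-negativity is then enforced by active-set passes
# (clip the driver's negative part, re-solve with the inactive columns
# of K removed).
joint_sc_fit <- function(y, kern, lambda_base = 1e7, lambda_deconv = 0.05,
                         n_passes = 3) {
  n <- length(y)
  nk <- min(length(kern), n)
  K <- Matrix::bandSparse(n, n, k = -(0:(nk - 1L)),
                          diagonals = lapply(seq_len(nk), function(j)
                            rep(kern[j], n - j + 1L)))
  if (n < 4) return(list(tonic = y, driver = numeric(n)))
  D2 <- Matrix::bandSparse(n - 2, n, k = 0:2,
                           diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                            rep(1, n - 2)))
  Pt <- Matrix::Diagonal(n) + lambda_base * Matrix::crossprod(D2)

  solve_joint <- function(Ks) {
    m <- ncol(Ks)
    A <- Matrix::forceSymmetric(rbind(
      cbind(Pt, Ks),
      cbind(Matrix::t(Ks),
            Matrix::crossprod(Ks) +
              lambda_deconv * Matrix::Diagonal(m))))
    rhs <- c(y, as.numeric(Matrix::crossprod(Ks, y)))
    v <- as.numeric(Matrix::solve(A, rhs))
    list(tonic = v[seq_len(n)], d = v[-seq_len(n)])
  }

  fit <- solve_joint(K)
  d <- fit$d
  tonic <- fit$tonic
  for (pass in seq_len(n_passes)) {
    supp <- which(d > 0)
    if (!length(supp)) {
      # no phasic activity: tonic-only smoothing fit
      tonic <- as.numeric(Matrix::solve(Pt, y))
      return(list(tonic = tonic, driver = numeric(n)))
    }
    fit <- solve_joint(K[, supp, drop = FALSE])
    d_new <- numeric(n)
    d_new[supp] <- pmax(fit$d, 0)
    tonic <- fit$tonic
    if (all(abs(d_new - d) < 1e-10)) { d <- d_new; break }
    d <- d_new
  }
  list(tonic = tonic, driver = d)
}

#' EDA features for one epoch
#'
#' Six skin-conductance features of the feature panel, computed from the
#' raw signal and its decomposition restricted to the epoch window:
#' `SCavg` mean of the raw signal; `SCLavg` mean tonic level; `SCLslope`
#' the tonic excursion `max(SCL) - min(SCL)` (a range, per the panel
#' definition, not a regression slope); `SCRavg` mean phasic signal;
#' `SCRmax` maximum phasic signal; `SCRpeak` number of phasic local
#' maxima with amplitude at least `peak_amp_min`.
#'
#' @param x The raw `"eda"` [time_series()] for the epoch window.
#' @param dec An `sc_decomposition` covering the epoch (typically the
#'   whole session; the epoch window is extracted by time).
#' @param peak_amp_min SCR peak-counting amplitude threshold in
#'   microsiemens (default 0.01).
#'
#' @return Named list `SCavg`, `SCLavg`, `SCLslope`, `SCRavg`, `SCRmax`,
#'   `SCRpeak`.
#' @export
eda_features <- function(x, dec, peak_amp_min = 0.01) {
  stopifnot(inherits(x, "time_series"), inherits(dec, "sc_decomposition"))
  t0 <- x$t0
  t1 <- x$t0 + ts_duration(x)
  tonic <- ts_window(dec$tonic, t0, t1)$samples
  phasic <- ts_window(dec$phasic, t0, t1)$samples
  list(SCavg = mean(x$samples),
       SCLavg = mean(tonic),
       SCLslope = max(tonic) - min(tonic),
       SCRavg = mean(phasic),
       SCRmax = max(phasic),
       SCRpeak = count_scr_peaks(phasic, peak_amp_min))
}

# Local maxima of the (smooth) phasic component with amplitude >= thr.
count_scr_peaks <- function(v, thr) {
  n <- length(v)
  if (n < 3) return(0L)
  pk <- which(v[-c(1L, n)] > v[-c(n - 1L, n)] &
                v[-c(1L, n)] >= v[-c(1L, 2L)]) + 1L
  sum(v[pk] >= thr)
}
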
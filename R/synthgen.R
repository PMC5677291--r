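#' Session parameter set for the synthetic biosignal generator
#'
#' Describes the statistical structure of one recording session: heart
#' period and its variability, respiratory sinus arrhythmia, sudomotor
#' (skin-conductance response) event rate and amplitude, tonic
#' skin-conductance level and drift, and skin-temperature level and drift.
#' The five session labels follow the stress protocol: baseline (BA-S),
#' mild (MIS-S), moderate (MOS-S) and severe (SES-S) stress, and recovery
#' (RE-S).
#'
#' @param session_label One of `"BA-S"`, `"MIS-S"`, `"MOS-S"`, `"SES-S"`,
#'   `"RE-S"`.
#' @param mean_rr Mean heart period in ms (positive).
#' @param sd_rr Marginal SD of the heart period noise in ms (non-negative).
#' @param resp_freq Respiratory modulation frequency in Hz.
#' @param rsa_amp Amplitude of the respiratory (sinus-arrhythmia)
#'   modulation of the heart period, in ms.
#' @param scr_rate Skin-conductance response event rate, events/min.
#' @param scr_amp_mean Mean SCR event amplitude in microsiemens.
#' @param tonic_level Tonic skin-conductance level in microsiemens.
#' @param tonic_drift Tonic drift in microsiemens per minute.
#' @param skt_mean Mean skin temperature in degrees Celsius.
#' @param skt_drift Skin-temperature drift in degrees Celsius per minute.
#' @param noise_sd Named list of additive white-noise SDs per channel
#'   (`ppg`, `eda`, `skt`) plus slow-wander SDs (`eda_wander`,
#'   `skt_wander`) for the low-frequency baseline wander of the EDA and
#'   SKT channels.
#'
#' @return A `session_params` object (named list).
#' @export
session_params <- function(session_label,
                           mean_rr, sd_rr,
                           resp_freq = 0.25, rsa_amp = 20,
                           scr_rate = 4, scr_amp_mean = 0.4,
                           tonic_level = 2.5, tonic_drift = 0,
                           skt_mean = 33, skt_drift = 0,
                           noise_sd = list(ppg = 0.02, eda = 0.01,
                                           skt = 0.02, eda_wander = 0.15,
                                           skt_wander = 0.1)) {
  session_label <- match.arg(session_label, session_levels())
  stopifnot(mean_rr > 0, sd_rr >= 0, scr_rate >= 0, scr_amp_mean >= 0)
  if (any(unlist(noise_sd) < 0))
    stop("all noise SDs must be non-negative", call. = FALSE)
  structure(list(session_label = session_label, mean_rr = mean_rr,
                 sd_rr = sd_rr, resp_freq = resp_freq, rsa_amp = rsa_amp,
                 scr_rate = scr_rate, scr_amp_mean = scr_amp_mean,
                 tonic_level = tonic_level, tonic_drift = tonic_drift,
                 skt_mean = skt_mean, skt_drift = skt_drift,
                 noise_sd = noise_sd),
            class = "session_params")
}

#' Canonical session labels in protocol order
#'
#' @return Character vector `c("BA-S", "MIS-S", "MOS-S", "SES-S", "RE-S")`.
#' @export
session_levels <- function() c("BA-S", "MIS-S", "MOS-S", "SES-S", "RE-S")

#' Default per-session generator parameters
#'
#' The defaults encode the expected autonomic gradient across the protocol:
#' heart rate and sudomotor activity increase monotonically from baseline
#' through mild, moderate and severe stress while beat-to-beat variability
#' decreases; the recovery session returns close to, but not onto, the
#' baseline operating point. Skin temperature rises mildly with stress and
#' carries substantial slow wander, making it the weakest of the three
#' channels, with skin conductance intermediate and heart rate strongest.
#'
#' @param separability `"low"`, `"medium"` or `"high"`. Scales the
#'   between-session contrast up (and the slow wander down) to produce
#'   cohorts that are harder or easier to classify; `"medium"` is the
#'   plain default parameterization.
#'
#' @return Named list of five [session_params()] objects in protocol order.
#' @export
default_session_params <- function(separability = c("medium", "low", "high")) {
  separability <- match.arg(separability)
  contrast <- switch(separability, low = 0.5, medium = 1, high = 1.3)
  wander <- switch(separability, low = 1.5, medium = 1, high = 0.7)

  base <- list(
    `BA-S`  = list(mean_rr = 1000, sd_rr = 34, rsa_amp = 30, scr_rate = 2,
                   scr_amp_mean = 0.30, tonic_level = 2.0,
                   tonic_drift = 0.00, skt_mean = 33.00, skt_drift = 0.00),
    `MIS-S` = list(mean_rr = 840, sd_rr = 29, rsa_amp = 24, scr_rate = 4,
                   scr_amp_mean = 0.40, tonic_level = 2.30,
                   tonic_drift = 0.05, skt_mean = 33.10, skt_drift = 0.02),
    `MOS-S` = list(mean_rr = 760, sd_rr = 23, rsa_amp = 16, scr_rate = 8,
                   scr_amp_mean = 0.55, tonic_level = 2.60,
                   tonic_drift = 0.10, skt_mean = 33.25, skt_drift = 0.04),
    `SES-S` = list(mean_rr = 670, sd_rr = 16, rsa_amp = 8, scr_rate = 12,
                   scr_amp_mean = 0.75, tonic_level = 3.00,
                   tonic_drift = 0.15, skt_mean = 33.40, skt_drift = 0.06),
    `RE-S`  = list(mean_rr = 920, sd_rr = 44, rsa_amp = 30, scr_rate = 3,
                   scr_amp_mean = 0.35, tonic_level = 2.45,
                   tonic_drift = -0.05, skt_mean = 33.15, skt_drift = -0.02))

  ref <- base$`BA-S`
  out <- lapply(names(base), function(lab) {
    p <- base[[lab]]
    # scale session deviations from baseline by the contrast factor
    scaled <- lapply(names(p), function(nm)
      ref[[nm]] + contrast * (p[[nm]] - ref[[nm]]))
    names(scaled) <- names(p)
    session_params(lab,
                   mean_rr = scaled$mean_rr, sd_rr = scaled$sd_rr,
                   rsa_amp = scaled$rsa_amp,
                   scr_rate = scaled$scr_rate,
                   scr_amp_mean = scaled$scr_amp_mean,
                   tonic_level = scaled$tonic_level,
                   tonic_drift = scaled$tonic_drift,
                   skt_mean = scaled$skt_mean, skt_drift = scaled$skt_drift,
                   noise_sd = list(ppg = 0.02, eda = 0.01, skt = 0.02,
                                   eda_wander = 0.18 * wander,
                                   skt_wander = 0.10 * wander))
  })
  names(out) <- names(base)
  out
}

#' Generate an RR (heart-period) interval sequence
#'
#' Draws successive heart periods as `mean_rr + sd_rr * AR(1)` noise plus
#' a sinusoidal respiratory modulation of amplitude `rsa_amp` at
#' `resp_freq`, then clips to the physiological range 300--2000 ms.
#' Intervals are generated until their cumulative sum covers `duration`
#' seconds.
#'
#' @param params A [session_params()] object.
#' @param duration Target coverage in seconds (positive).
#' @param seed Integer seed; identical seeds give identical sequences.
#' @param ar_phi AR(1) coefficient of the heart-period noise (default 0.2).
#'
#' @return Numeric vector of RR intervals in ms whose cumulative sum is at
#'   least `duration * 1000`.
#' @export
generate_rr_sequence <- function(params, duration, seed, ar_phi = 0.2) {
  stopifnot(inherits(params, "session_params"))
  if (!is.numeric(duration) || duration <= 0)
    stop("`duration` must be positive", call. = FALSE)
  n_guess <- ceiling(duration * 1000 / max(params$mean_rr - 3 * params$sd_rr,
                                           300)) + 16L
  with_seed(seed, {
    rr <- numeric(0)
    total <- 0
    e_prev <- rnorm(1)
    while (total < duration * 1000) {
      eps <- rnorm(n_guess)
      e <- numeric(n_guess)
      for (i in seq_len(n_guess)) {
        e[i] <- ar_phi * e_prev + sqrt(1 - ar_phi^2) * eps[i]
        e_prev <- e[i]
      }
      block <- params$mean_rr + params$sd_rr * e
      # respiratory modulation evaluated at the (approximate) beat times
      t_beat <- (total + cumsum(block)) / 1000
      block <- block + params$rsa_amp * sin(2 * pi * params$resp_freq * t_beat)
      block <- pmin(pmax(block, 300), 2000)
      rr <- c(rr, block)
      total <- total + sum(block)
    }
    keep <- which(cumsum(rr) >= duration * 1000)[1]
    rr[seq_len(keep)]
  })
}

#' Synthesize a PPG signal from an RR sequence
#'
#' Places one stereotyped pulse (a Gaussian lobe) at each cumulative RR
#' time, adds a slow sinusoidal baseline (below 0.1 Hz, emulating motion
#' and perfusion drift) and white measurement noise. Pulse peaks are
#' recoverable by [detect_peaks()] to within a few samples when the noise
#' is small.
#'
#' @param rr RR interval sequence in ms (non-empty).
#' @param fs Sampling rate in Hz.
#' @param pulse_shape_width Width of the Gaussian pulse in seconds; the
#'   Gaussian SD is `pulse_shape_width / 3`.
#' @param noise_sd Additive white-noise SD (pulse amplitude is 1).
#' @param duration Output duration in seconds; defaults to covering the
#'   whole RR sequence plus one mean interval.
#' @param baseline_amp Amplitude of the slow baseline component.
#' @param seed Seed for the noise stream.
#'
#' @return A `"ppg"` [time_series()].
#' @export
synthesize_ppg <- function(rr, fs, pulse_shape_width = 0.35, noise_sd = 0,
                           duration = NULL, baseline_amp = 0.1, seed = 1) {
  if (length(rr) < 1L) stop("`rr` must be non-empty", call. = FALSE)
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  beat_t <- cumsum(rr) / 1000
  if (is.null(duration)) duration <- beat_t[length(beat_t)] + mean(rr) / 1000
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  x <- numeric(n)
  sd_pulse <- pulse_shape_width / 3
  half <- ceiling(4 * sd_pulse * fs)
  kernel_t <- (-half:half) / fs
  kernel <- exp(-kernel_t^2 / (2 * sd_pulse^2))
  for (bt in beat_t) {
    ci <- round(bt * fs) + 1L
    lo <- ci - half
    hi <- ci + half
    kl <- max(1L, lo); kh <- min(n, hi)
    if (kl > n || kh < 1L) next
    x[kl:kh] <- x[kl:kh] + kernel[(kl - lo + 1L):(kh - lo + 1L)]
  }
  x <- x + baseline_amp * sin(2 * pi * 0.05 * t)
  if (noise_sd > 0) x <- x + with_seed(seed, rnorm(n, sd = noise_sd))
  time_series(x, fs, "ppg")
}

# Smooth slow wander: AR(1)-filtered Gaussian noise with ~tau seconds
# correlation time, scaled to marginal SD `sd`.
slow_wander <- function(n, fs, sd, tau = 30) {
  if (sd <= 0) return(numeric(n))
  phi <- exp(-1 / (tau * fs))
  e <- rnorm(n)
  w <- as.numeric(stats::filter(e, phi, method = "recursive"))
  w * sd / stats::sd(w)
}

# Bateman biexponential SCR kernel sampled at fs, normalized to unit peak.
bateman_kernel <- function(fs, tau1 = 0.75, tau2 = 2.0, t_max = NULL) {
  if (tau1 <= 0 || tau2 <= 0 || tau1 >= tau2)
    stop("require 0 < tau1 < tau2", call. = FALSE)
  if (is.null(t_max)) t_max <- tau2 * 6
  t <- seq(0, t_max, by = 1 / fs)
  k <- exp(-t / tau2) - exp(-t / tau1)
  k / max(k)
}

#' Synthesize an EDA (skin conductance) signal
#'
#' Signal model: tonic level plus linear drift plus slow wander, a phasic
#' component formed by convolving a sparse train of sudomotor events with
#' a Bateman biexponential kernel, and white noise. Events arrive as a
#' homogeneous Poisson process at `scr_rate` per minute; amplitudes are
#' log-normal with mean `scr_amp_mean`. The returned ground-truth event
#' list supports decomposition-recovery tests.
#'
#' @param params A [session_params()] object.
#' @param duration Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @param tau1,tau2 Bateman kernel time constants in seconds.
#' @param events Optional data.frame with columns `time_s`,
#'   `amplitude_uS` fixing the event train explicitly (used for
#'   controlled round-trip fixtures); when `NULL` (default) events are
#'   drawn from the Poisson model.
#'
#' @return List with `signal` (an `"eda"` [time_series()]), `events`
#'   (data.frame with columns `time_s`, `amplitude_uS`).
#' @export
synthesize_eda <- function(params, duration, fs, seed,
                           tau1 = 0.75, tau2 = 2.0, events = NULL) {
  stopifnot(inherits(params, "session_params"))
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  with_seed(seed, {
    if (is.null(events)) {
      n_ev <- rpois(1, params$scr_rate * duration / 60)
      ev_t <- sort(runif(n_ev, 0, max(duration - 4 * tau2, duration * 0.75)))
      sdlog <- 0.4
      ev_a <- if (n_ev > 0 && params$scr_amp_mean > 0)
        rlnorm(n_ev, meanlog = log(params$scr_amp_mean) - sdlog^2 / 2,
               sdlog = sdlog) else numeric(n_ev)
    } else {
      n_ev <- nrow(events)
      ev_t <- events$time_s
      ev_a <- events$amplitude_uS
    }
    x <- params$tonic_level + params$tonic_drift * t / 60 +
      slow_wander(n, fs, params$noise_sd$eda_wander)
    if (n_ev > 0) {
      kern <- bateman_kernel(fs, tau1, tau2)
      phasic <- numeric(n)
      for (i in seq_len(n_ev)) {
        i0 <- round(ev_t[i] * fs) + 1L
        idx <- i0:min(n, i0 + length(kern) - 1L)
        phasic[idx] <- phasic[idx] + ev_a[i] * kern[seq_along(idx)]
      }
      x <- x + phasic
    }
    if (params$noise_sd$eda > 0) x <- x + rnorm(n, sd = params$noise_sd$eda)
    list(signal = time_series(x, fs, "eda"),
         events = data.frame(time_s = ev_t, amplitude_uS = ev_a))
  })
}

#' Synthesize a skin-temperature signal
#'
#' `skt_mean + skt_drift * t + slow wander + white noise`.
#'
#' @inheritParams synthesize_eda
#' @return An `"skt"` [time_series()].
#' @export
synthesize_skt <- function(params, duration, fs, seed) {
  stopifnot(inherits(params, "session_params"))
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1L) / fs
  with_seed(seed, {
    x <- params$skt_mean + params$skt_drift * t / 60 +
      slow_wander(n, fs, params$noise_sd$skt_wander)
    if (params$noise_sd$skt > 0) x <- x + rnorm(n, sd = params$noise_sd$skt)
    time_series(x, fs, "skt")
  })
}

#' Generate one subject's five-session recording
#'
#' Produces the three channels (PPG, EDA, SKT) for each of the five
#' protocol sessions, with per-subject physiological offsets (heart
#' period, tonic skin conductance, skin temperature) drawn from seeded
#' subject-level streams. Ground truth (the exact RR sequence and SCR
#' event list per session) is retained for recovery tests.
#'
#' @param subject_id Subject identifier string.
#' @param params_by_session Named list of [session_params()], one per
#'   session label, in protocol order (see [default_session_params()]).
#' @param seed Master integer seed; all channel streams are derived from
#'   it.
#' @param duration Session length in seconds (default 240).
#' @param fs Sampling rate in Hz (default 400).
#' @param subject_sd Named list of between-subject offset SDs
#'   (`mean_rr` ms, `tonic` microsiemens, `skt` degrees C).
#'
#' @return A `subject_recording`: list with `subject_id`, `sessions`
#'   (per-session list of `ppg`, `eda`, `skt` time series), and
#'   `ground_truth` (per-session `params`, `rr`, `events`).
#' @export
generate_subject <- function(subject_id, params_by_session =
                               default_session_params(),
                             seed = 1, duration = 240, fs = 400,
                             subject_sd = list(mean_rr = 35, tonic = 0.25,
                                               skt = 0.25)) {
  if (!identical(names(params_by_session), session_levels()))
    stop("`params_by_session` must contain the five sessions ",
         paste(session_levels(), collapse = ", "), " in order",
         call. = FALSE)
  off <- with_seed(derive_seed(seed, subject_id, "offsets"), list(
    mean_rr = rnorm(1, sd = subject_sd$mean_rr),
    tonic = rnorm(1, sd = subject_sd$tonic),
    skt = rnorm(1, sd = subject_sd$skt)))
  sessions <- list()
  ground_truth <- list()
  for (lab in session_levels()) {
    p <- params_by_session[[lab]]
    p$mean_rr <- p$mean_rr + off$mean_rr
    p$tonic_level <- max(0.1, p$tonic_level + off$tonic)
    p$skt_mean <- p$skt_mean + off$skt
    rr <- generate_rr_sequence(p, duration,
                               derive_seed(seed, subject_id, lab, "rr"))
    ppg <- synthesize_ppg(rr, fs, noise_sd = p$noise_sd$ppg,
                          duration = duration,
                          seed = derive_seed(seed, subject_id, lab, "ppg"))
    eda <- synthesize_eda(p, duration, fs,
                          seed = derive_seed(seed, subject_id, lab, "eda"))
    skt <- synthesize_skt(p, duration, fs,
                          seed = derive_seed(seed, subject_id, lab, "skt"))
    sessions[[lab]] <- list(ppg = ppg, eda = eda$signal, skt = skt)
    ground_truth[[lab]] <- list(params = p, rr = rr, events = eda$events)
  }
  structure(list(subject_id = subject_id, sessions = sessions,
                 ground_truth = ground_truth, fs = fs, duration = duration,
                 seed = seed),
            class = "subject_recording")
}

#' Generate a synthetic cohort
#'
#' @param n_subjects Number of subjects (default 12).
#' @param params_by_session Per-session parameters; see
#'   [default_session_params()].
#' @param seed Master seed.
#' @param duration,fs Session length (s) and sampling rate (Hz).
#' @param ... Passed to [generate_subject()].
#'
#' @return List of `subject_recording` objects named `S01`, `S02`, ...
#' @export
generate_cohort <- function(n_subjects = 12,
                            params_by_session = default_session_params(),
                            seed = 1, duration = 240, fs = 400, ...) {
  ids <- sprintf("S%02d", seq_len(n_subjects))
  out <- lapply(ids, function(id)
    generate_subject(id, params_by_session, seed = seed,
                     duration = duration, fs = fs, ...))
  names(out) <- ids
  out
}

#' Write a subject recording to CSV + JSON sidecars
#'
#' One CSV per subject-session-channel with columns `time_s,value`, plus a
#' JSON sidecar carrying subject, session, channel, sampling rate and
#' generator provenance. Values are written with six decimal places.
#'
#' @param rec A `subject_recording`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of CSV paths written.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "subject_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (lab in names(rec$sessions)) {
    for (ch in names(rec$sessions[[lab]])) {
      ts <- rec$sessions[[lab]][[ch]]
      stem <- sprintf("%s_%s_%s", rec$subject_id, lab, ch)
      csv <- file.path(dir, paste0(stem, ".csv"))
      df <- data.frame(time_s = sprintf("%.6f", ts_times(ts)),
                       value = sprintf("%.6f", ts$samples))
      utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
      meta <- list(subject = rec$subject_id, session = lab, channel = ch,
                   fs_hz = ts$fs, seed = rec$seed)
      jsonlite::write_json(meta, file.path(dir, paste0(stem, ".json")),
                           auto_unbox = TRUE)
      paths <- c(paths, csv)
    }
  }
  invisible(paths)
}

#' Read a subject recording written by [write_recording()]
#'
#' @param dir Directory containing the CSV/JSON files.
#' @param subject_id Subject identifier.
#' @return A `subject_recording` (without ground truth).
#' @export
read_recording <- function(dir, subject_id) {
  sessions <- list()
  fs <- NULL
  for (lab in session_levels()) {
    chans <- list()
    for (ch in c("ppg", "eda", "skt")) {
      stem <- sprintf("%s_%s_%s", subject_id, lab, ch)
      csv <- file.path(dir, paste0(stem, ".csv"))
      sidecar <- file.path(dir, paste0(stem, ".json"))
      if (!file.exists(csv))
        stop("missing channel file: ", csv, call. = FALSE)
      meta <- jsonlite::read_json(sidecar)
      df <- utils::read.csv(csv)
      chans[[ch]] <- time_series(df$value, fs = meta$fs_hz, channel = ch,
                                 t0 = df$time_s[1])
      fs <- meta$fs_hz
    }
    sessions[[lab]] <- chans
  }
  dur <- length(sessions[[1]]$ppg$samples) / fs
  structure(list(subject_id = subject_id, sessions = sessions,
                 ground_truth = NULL, fs = fs, duration = dur, seed = NA),
            class = "subject_recording")
}
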
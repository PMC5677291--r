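test_that("noise-free RR generation is exact and deterministic", {
  p <- quiet_params(mean_rr = 1000, sd_rr = 0, rsa_amp = 0)
  rr <- generate_rr_sequence(p, 10, seed = 1)
  expect_equal(rr, rep(1000, 10))

  p2 <- quiet_params(mean_rr = 820, sd_rr = 35, rsa_amp = 12)
  expect_identical(generate_rr_sequence(p2, 60, seed = 7),
                   generate_rr_sequence(p2, 60, seed = 7))
  expect_false(identical(generate_rr_sequence(p2, 60, seed = 7),
                         generate_rr_sequence(p2, 60, seed = 8)))
  expect_error(generate_rr_sequence(p2, -5, seed = 1), "positive")
})

test_that("RR sequence matches its generative moments at large n", {
  p <- quiet_params(mean_rr = 800, sd_rr = 50, rsa_amp = 0)
  rr <- generate_rr_sequence(p, 8000, seed = 42)
  expect_gt(length(rr), 9000)
  expect_lt(abs(mean(rr) - 800), 5)
  expect_lt(abs(sd(rr) - 50), 5)
  expect_true(all(rr >= 300 & rr <= 2000))
})

test_that("RR intervals always cover the requested duration", {
  p <- quiet_params(mean_rr = 750, sd_rr = 60)
  for (dur in c(5, 33.3, 120)) {
    rr <- generate_rr_sequence(p, dur, seed = round(dur))
    expect_gte(sum(rr), dur * 1000)
    expect_lt(sum(rr[-length(rr)]), dur * 1000)
  }
})

test_that("synthetic PPG places one pulse per beat", {
  x <- synthesize_ppg(rep(1000, 3), fs = 400, noise_sd = 0,
                      baseline_amp = 0)
  v <- x$samples
  n <- length(v)
  maxima <- which(v[-c(1, n)] > v[-c(n - 1, n)] &
                    v[-c(1, n)] > v[-c(1, 2)]) + 1
  maxima <- maxima[v[maxima] > 0.5]
  expect_length(maxima, 3)
  expect_equal(diff(maxima) / 400, c(1, 1), tolerance = 1e-6)

  expect_length(synthesize_ppg(rep(900, 10), fs = 400,
                               duration = 240)$samples, 96000)
  expect_error(synthesize_ppg(numeric(0), fs = 400), "non-empty")
})

test_that("PPG round trip recovers the generator RR intervals", {
  p <- quiet_params(mean_rr = 900, sd_rr = 40)
  rr <- generate_rr_sequence(p, 60, seed = 7)
  ppg <- synthesize_ppg(rr, fs = 400, noise_sd = 0.02, duration = 60,
                        seed = 3)
  nn <- compute_nn(detect_peaks(bandpass_ppg(ppg)))
  # interior beats only: the last pulse is truncated by the window end
  k <- min(length(nn$nn), length(rr) - 2)
  expect_lt(max(abs(nn$nn[1:k] - rr[2:(k + 1)])), 25)
  expect_lt(abs(mean(nn$nn[1:k]) - mean(rr[2:(k + 1)])), 1)
})

test_that("EDA synthesis matches its additive model", {
  p0 <- quiet_params(scr_rate = 0, tonic_level = 1.7, tonic_drift = 0)
  e <- synthesize_eda(p0, 20, fs = 100, seed = 1)
  expect_equal(e$signal$samples, rep(1.7, 2000))
  expect_equal(nrow(e$events), 0)

  # Poisson event count expectation: 6 / min over 240 s -> 24 expected
  p6 <- quiet_params(scr_rate = 6, scr_amp_mean = 0.4)
  counts <- vapply(1:30, function(s)
    nrow(synthesize_eda(p6, 240, fs = 20, seed = s)$events), numeric(1))
  expect_lt(abs(mean(counts) - 24), 3)  # SE ~ 0.9

  # fixed event train is honored exactly
  ev <- data.frame(time_s = c(5, 12), amplitude_uS = c(0.4, 0.6))
  e2 <- synthesize_eda(p0, 30, fs = 100, seed = 1, events = ev)
  expect_equal(e2$events, ev)
  expect_gt(max(e2$signal$samples), 1.7 + 0.5)
})

test_that("SKT synthesis and subject assembly have the stated shape", {
  p <- quiet_params(skt_mean = 33, skt_drift = 0)
  s <- synthesize_skt(p, 10, fs = 50, seed = 2)
  expect_equal(s$samples, rep(33, 500))
  expect_identical(s$channel, "skt")

  params <- default_session_params()
  rec <- generate_subject("S01", params, seed = 5, duration = 41, fs = 50)
  expect_s3_class(rec, "subject_recording")
  expect_identical(names(rec$sessions), session_levels())
  expect_length(unlist(lapply(rec$sessions, names)), 15)
  for (lab in session_levels()) {
    for (ch in c("ppg", "eda", "skt"))
      expect_equal(ts_duration(rec$sessions[[lab]][[ch]]), 41)
  }
  expect_named(rec$ground_truth[[1]], c("params", "rr", "events"))

  bad <- params[-2]
  expect_error(generate_subject("S01", bad, seed = 1), "five sessions")
})

test_that("subject generation is seed-deterministic and cohort-sized", {
  params <- default_session_params()
  a <- generate_subject("S01", params, seed = 9, duration = 40, fs = 40)
  b <- generate_subject("S01", params, seed = 9, duration = 40, fs = 40)
  expect_identical(a, b)
  co <- generate_cohort(3, params, seed = 1, duration = 40, fs = 40)
  expect_length(co, 3)
  # 3 subjects x 5 sessions x 3 channels
  expect_equal(sum(lengths(lapply(co, function(r)
    unlist(lapply(r$sessions, names))))), 45)
})

test_that("session-graded parameters produce ordered feature means", {
  # noise-free channels: feature means must follow the generator's
  # monotone stress gradient BA < MIS < MOS < SES
  params <- default_session_params()
  params <- lapply(params, function(p) {
    p$noise_sd <- list(ppg = 0, eda = 0, skt = 0, eda_wander = 0,
                       skt_wander = 0)
    p
  })
  rec <- generate_subject("S01", params, seed = 3, duration = 95,
                          fs = 400,
                          subject_sd = list(mean_rr = 0, tonic = 0,
                                            skt = 0))
  tab <- build_feature_table(rec)
  m <- aggregate(cbind(HRavg, SCavg, SKTavg) ~ session, tab, mean)
  stress_rows <- match(c("BA-S", "MIS-S", "MOS-S", "SES-S"), m$session)
  expect_true(all(diff(m$HRavg[stress_rows]) > 0))
  expect_true(all(diff(m$SCavg[stress_rows]) > 0))
  expect_true(all(diff(m$SKTavg[stress_rows]) > 0))
})

test_that("CSV round trip preserves the recording to 6 decimals", {
  dir <- tempfile("rec")
  params <- default_session_params()
  rec <- generate_subject("S07", params, seed = 2, duration = 12, fs = 50)
  write_recording(rec, dir)
  expect_length(list.files(dir, pattern = "\\.csv$"), 15)
  back <- read_recording(dir, "S07")
  for (lab in session_levels()) {
    for (ch in c("ppg", "eda", "skt")) {
      expect_equal(back$sessions[[lab]][[ch]]$samples,
                   rec$sessions[[lab]][[ch]]$samples, tolerance = 1e-6)
      expect_equal(back$sessions[[lab]][[ch]]$fs,
                   rec$sessions[[lab]][[ch]]$fs)
    }
  }
  unlink(dir, recursive = TRUE)
})
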
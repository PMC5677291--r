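test_that("time-domain features match hand-computed values", {
  f <- hrv_time_domain(c(1000, 1000, 1000))
  expect_equal(f$HRavg, 60)
  expect_equal(f$SDNN, 0)
  expect_equal(f$RMSSD, 0)
  expect_equal(f$pNN20, 0)
  expect_equal(f$pNN50, 0)

  # diffs are [60, -5, 65]; denominator is the interval count (4)
  f2 <- hrv_time_domain(c(800, 860, 855, 920))
  expect_equal(f2$NNavg, 858.75)
  expect_equal(f2$pNN50, 2 / 4)
  expect_equal(f2$pNN20, 2 / 4)
  expect_equal(f2$RMSSD, sqrt((60^2 + 5^2 + 65^2) / 3))
  expect_equal(f2$SDSD, sd(c(60, -5, 65)))

  # the pairs convention uses the number of successive differences
  f3 <- hrv_time_domain(c(800, 860, 855, 920), pnn_denominator = "pairs")
  expect_equal(f3$pNN50, 2 / 3)

  expect_true(is.na(hrv_time_domain(c(800))$SDNN))
})

test_that("pNN20 never falls below pNN50", {
  set.seed(11)
  for (i in 1:50) {
    nn <- rnorm(sample(4:40, 1), mean = 850, sd = runif(1, 5, 80))
    f <- hrv_time_domain(nn)
    expect_gte(f$pNN20, f$pNN50)
  }
})

test_that("the NN tachogram interpolates exactly on smooth inputs", {
  nn <- structure(list(peak_times = cumsum(c(0, rep(1, 10))),
                       nn = rep(1000, 10)), class = "nn_series")
  tach <- nn_tachogram(nn)
  expect_equal(tach$v, rep(1000, length(tach$v)))
  expect_equal(diff(tach$t), rep(0.25, length(tach$t) - 1))

  # NN values linear in observation time are reproduced by the spline
  t_obs <- cumsum(runif(12, 0.7, 1.1))
  nn2 <- structure(list(peak_times = c(0, t_obs), nn = 500 + 30 * t_obs),
                   class = "nn_series")
  tach2 <- nn_tachogram(nn2)
  expect_lt(max(abs(tach2$v - (500 + 30 * tach2$t))), 1e-9)

  short <- structure(list(peak_times = c(0, 1, 2), nn = c(1000, 1000)),
                     class = "nn_series")
  expect_null(nn_tachogram(short))
})

test_that("Burg AR spectrum localizes oscillations and handles edge cases", {
  # pure sinusoid: spectral peak within 0.02 Hz of the true frequency
  t <- seq(0, 255.75, by = 0.25)
  tach <- structure(list(t = t, v = 1000 + 50 * sin(2 * pi * 0.25 * t),
                         fs = 4), class = "tachogram")
  psd <- ar_psd(tach, order = 16)
  expect_lt(abs(psd$f[which.max(psd$p)] - 0.25), 0.02)

  # white noise: approximately flat over the HRV bands at large n
  set.seed(2)
  tw <- structure(list(t = seq(0, by = 0.25, length.out = 4096),
                       v = rnorm(4096), fs = 4), class = "tachogram")
  pw <- ar_psd(tw, order = 2)
  band <- pw$f >= 0.04 & pw$f <= 0.4
  expect_lt(max(pw$p[band]) / min(pw$p[band]), 3)

  # zero variance: zero spectrum
  tz <- structure(list(t = t, v = rep(1000, length(t)), fs = 4),
                  class = "tachogram")
  expect_true(all(ar_psd(tz)$p == 0))

  # order is capped for short series
  ts_ <- structure(list(t = seq(0, 5.75, by = 0.25),
                        v = 1000 + rnorm(24), fs = 4),
                   class = "tachogram")
  expect_lte(ar_psd(ts_, order = 16)$order, 11)
})

test_that("band powers integrate the PSD analytically", {
  flat <- structure(list(f = seq(0, 0.5, by = 0.001),
                         p = rep(1, 501)), class = "psd")
  bp <- band_powers(flat)
  expect_equal(bp$LFnormal, 0.11 / 0.36, tolerance = 1e-9)
  expect_equal(bp$HFnormal, 0.25 / 0.36, tolerance = 1e-9)
  expect_equal(bp$LF_HF, 0.11 / 0.25, tolerance = 1e-9)
  expect_equal(bp$LFnormal + bp$HFnormal, 1)

  hf_only <- structure(list(f = seq(0, 0.5, by = 0.001),
                            p = as.numeric(seq(0, 0.5, by = 0.001) > 0.2)),
                       class = "psd")
  bp2 <- band_powers(hf_only)
  expect_equal(bp2$LFnormal, 0)
  expect_equal(bp2$HFnormal, 1)

  empty <- structure(list(f = c(0, 0.5), p = c(0, 0)), class = "psd")
  expect_true(is.na(band_powers(empty)$LFnormal))
})

test_that("frequency features ignore the tachogram's DC level", {
  set.seed(7)
  v <- 1000 + 40 * sin(2 * pi * 0.25 * seq(0, 63.75, by = 0.25)) + rnorm(256)
  t1 <- structure(list(t = seq(0, 63.75, by = 0.25), v = v, fs = 4),
                  class = "tachogram")
  t2 <- t1
  t2$v <- t2$v + 500
  b1 <- band_powers(ar_psd(t1))
  b2 <- band_powers(ar_psd(t2))
  expect_equal(b1$LFnormal, b2$LFnormal, tolerance = 1e-6)
  expect_equal(b1$LF_HF, b2$LF_HF, tolerance = 1e-5)
})

test_that("entropies match the brute-force double-loop oracle", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(10:50, 1)
    x <- rnorm(n)
    r <- 0.2 * sd(x)
    expect_equal(approximate_entropy(x, 2, r), apen_brute(x, 2, r),
                 tolerance = 1e-12)
    se <- sample_entropy(x, 2, r)
    sb <- sampen_brute(x, 2, r)
    if (is.na(sb)) expect_true(is.na(se))
    else expect_equal(se, sb, tolerance = 1e-12)
  }
})

test_that("entropy edge cases and regularity ordering behave", {
  expect_equal(approximate_entropy(rep(5, 30)), 0)
  expect_equal(sample_entropy(rep(5, 30)), 0)
  expect_true(is.na(approximate_entropy(c(1, 2, 3))))

  # irregular i.i.d. noise scores higher than a smooth sine at equal n
  set.seed(3)
  noise <- runif(200)
  sine <- sin(2 * pi * seq(0, 4, length.out = 200))
  expect_gt(sample_entropy(noise, 2, 0.2 * sd(noise)),
            sample_entropy(sine, 2, 0.2 * sd(sine)))
})

test_that("Poincare dispersion satisfies its algebraic identities", {
  f <- poincare(c(900, 900, 900, 900))
  expect_equal(f$SD1, 0)
  expect_equal(f$SD2, 0)
  expect_true(is.na(f$SD1_SD2))

  set.seed(5)
  for (i in 1:20) {
    nn <- rnorm(sample(5:60, 1), 850, 50)
    p <- poincare(nn)
    d <- diff(nn)
    # SD1^2 = SDSD^2 / 2 under the sample-SD convention
    expect_equal(p$SD1^2, sd(d)^2 / 2, tolerance = 1e-9)
    # SD1^2 + SD2^2 = 2 * population variance * n/(n-1) correction chain:
    # verified under the population-variance convention
    a <- nn[-length(nn)]
    b <- nn[-1]
    pv <- function(z) mean((z - mean(z))^2)
    sd1p <- sqrt(pv((b - a) / sqrt(2)))
    sd2p <- sqrt(pv((b + a) / sqrt(2)))
    expect_equal(sd1p^2 + sd2p^2, pv(a) + pv(b), tolerance = 1e-9)
  }
})

test_that("the combined HRV panel is complete and finite after extraction", {
  p <- quiet_params(mean_rr = 850, sd_rr = 45)
  rr <- generate_rr_sequence(p, 30, seed = 2)
  ppg <- synthesize_ppg(rr, 400, noise_sd = 0.01, duration = 30, seed = 1)
  nn <- compute_nn(detect_peaks(bandpass_ppg(ppg)))
  f <- hrv_features(nn)
  expect_named(f, feature_names("HRV"))
  # every feature is either finite or an explicit NA marker - never NaN
  vals <- unlist(f)
  expect_true(all(is.finite(vals) | is.na(vals)))
  expect_false(any(is.nan(vals)))
})
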
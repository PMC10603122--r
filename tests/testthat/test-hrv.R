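test_that("time-domain indices match hand computations", {
  r <- time_domain_indices(rep(1000, 10))
  expect_equal(r$hr, 60)
  expect_equal(r$rmssd, 0)
  expect_equal(r$pnn50, 0)
  expect_equal(r$sdrr, 0)

  r2 <- time_domain_indices(c(800, 850, 800))
  expect_equal(r2$rmssd, 50)            # sqrt((50^2 + 50^2)/2)

  # brute-force oracle on [800, 860, 870, 940]: diffs 60, 10, 70
  rr <- c(800, 860, 870, 940)
  r3 <- time_domain_indices(rr)                       # paper denominator: n
  expect_equal(r3$pnn50, 100 * 2 / 4)
  r3c <- time_domain_indices(rr, pnn50_denominator = "differences")
  expect_equal(r3c$pnn50, 100 * 2 / 3)
  expect_equal(r3$rmssd, sqrt(mean(diff(rr)^2)))
  expect_equal(r3$sdrr, stats::sd(rr))
  expect_equal(r3$hr, 60000 / mean(rr))

  # single interval: HR only
  r1 <- time_domain_indices(900)
  expect_equal(r1$hr, 60000 / 900)
  expect_true(is.na(r1$rmssd))
})

test_that("RMSSD/SDRR shift-invariance, HR not; pNN50 time-reversal invariance", {
  set.seed(2)
  rr <- 900 + rnorm(50, sd = 40)
  a <- time_domain_indices(rr); b <- time_domain_indices(rr + 100)
  expect_equal(a$rmssd, b$rmssd)
  expect_equal(a$sdrr, b$sdrr)
  expect_false(isTRUE(all.equal(a$hr, b$hr)))
  expect_equal(time_domain_indices(rev(rr))$pnn50, a$pnn50)
})

test_that("RR resampling reproduces constants, ramps, and modulation", {
  rr <- data.frame(beat_time_s = cumsum(rep(1, 200)), rr_ms = rep(1000, 200))
  u <- resample_rr(rr)
  expect_true(all(abs(u$rr_ms - 1000) < 1e-9))
  ramp <- data.frame(beat_time_s = cumsum(rep(1, 100)),
                     rr_ms = seq(800, 990, length.out = 100))
  ur <- resample_rr(ramp)
  fit <- stats::lm(rr_ms ~ time_s, ur)
  expect_lt(max(abs(stats::residuals(fit))), 1e-6)
  # 0.1 Hz modulation survives resampling
  t <- cumsum(rep(0.9, 400))
  mod <- data.frame(beat_time_s = t, rr_ms = 900 + 50 * sin(2 * pi * 0.1 * t))
  um <- resample_rr(mod)
  p <- welch_psd(um$rr_ms - mean(um$rr_ms), 4)
  expect_lt(abs(p$freq[which.max(p$psd)] - 0.1), 2 * p$df)
  expect_error(resample_rr(data.frame(beat_time_s = 1:2, rr_ms = c(1, 1))),
               "3 beats")
})

test_that("Pan-Tompkins hits clean synthetic beats within 10 ms, no false positives", {
  g <- generate_rr_and_ecg(rr_config(2, duration = 120), 1, ecg = TRUE,
                           ecg_noise_sd = 0)
  det <- pan_tompkins(g$ecg)
  truth <- g$ground_truth$r_times
  miss <- vapply(truth, function(t) min(abs(det$beat_time_s - t)), 0)
  expect_equal(mean(miss < 0.010), 1)                  # 100% sensitivity
  fp <- vapply(det$beat_time_s, function(t) min(abs(truth - t)), 0)
  expect_equal(sum(fp > 0.010), 0)
  expect_error(pan_tompkins(recording(matrix(0, 512 * 20, 1), 512, "ECG",
                                      "mV")), "flat")
  # detected HR within 1% of ground-truth HR
  hr_det <- windowed_hrv(clean_rr(det), window_length = 60,
                         duration = 120)$hr
  hr_tru <- windowed_hrv(g$rr, window_length = 60, duration = 120)$hr
  expect_lt(max(abs(hr_det - hr_tru) / hr_tru), 0.01)
})

test_that("Pan-Tompkins keeps >= 95% sensitivity at 10 dB SNR", {
  sens <- vapply(1:5, function(s) {     # scaled down from 20 seeds
    g0 <- generate_rr_and_ecg(rr_config(s, duration = 60), 1, ecg = TRUE,
                              ecg_noise_sd = 0)
    snr_sd <- stats::sd(g0$ecg$data[, 1]) / sqrt(10)
    g <- generate_rr_and_ecg(rr_config(s, duration = 60), 1, ecg = TRUE,
                             ecg_noise_sd = snr_sd)
    det <- pan_tompkins(g$ecg)
    miss <- vapply(g$ground_truth$r_times,
                   function(t) min(abs(det$beat_time_s - t)), 0)
    mean(miss < 0.05)
  }, 0)
  expect_gte(mean(sens), 0.95)
})

test_that("frequency-domain indices separate the LF and HF lobes", {
  t <- seq(0, 300, by = 0.25)
  lf_only <- data.frame(time_s = t, rr_ms = 900 + 40 * sin(2 * pi * 0.1 * t))
  f <- freq_domain_indices(lf_only)
  expect_gt(f$lf_nu, 0.9)
  expect_lt(f$hf_nu, 0.05)
  hf_only <- data.frame(time_s = t, rr_ms = 900 + 40 * sin(2 * pi * 0.3 * t))
  f2 <- freq_domain_indices(hf_only)
  expect_gt(f2$hf_nu, 0.9)
  expect_true(f$lf_nu + f$hf_nu <= 1 + 1e-9)
  expect_true(f2$lf_nu + f2$hf_nu <= 1 + 1e-9)
})

test_that("windowed HRV: window count, unreliable flag, finite indices", {
  rr <- data.frame(beat_time_s = cumsum(rep(0.9, 3200)))
  rr$rr_ms <- 900 + c(0, diff(rr$beat_time_s)) * 0 + rnorm(3200, sd = 30)
  h <- windowed_hrv(rr, duration = 2880)               # 48 min
  expect_equal(nrow(h), 16)
  expect_true(all(h$reliable))
  expect_true(all(is.finite(h$hr) & h$hr > 0))
  expect_true(all(h$pnn50 >= 0 & h$pnn50 <= 100))
  expect_true(all(h$lf_nu >= 0 & h$lf_nu <= 1, na.rm = TRUE))
  # sparse window flagged unreliable
  sparse <- data.frame(beat_time_s = seq(0, 360, by = 10),
                       rr_ms = rep(1000, 37))
  hs <- windowed_hrv(sparse, duration = 360)
  expect_false(any(hs$reliable))
})

test_that("RR cleaning removes ectopics and interpolates", {
  rr <- data.frame(beat_time_s = cumsum(rep(0.9, 100)),
                   rr_ms = rep(900, 100))
  rr$rr_ms[50] <- 4000                                  # implausible
  cl <- clean_rr(rr)
  expect_lt(abs(cl$rr_ms[50] - 900), 50)
})
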
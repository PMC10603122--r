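test_that("Welch PSD is Parseval-consistent on a sinusoid and locates its peak", {
  s <- sin(2 * pi * 10 * seq(0, 180, by = 1 / 512))
  p <- welch_psd(s, 512)
  expect_equal(p$freq[which.max(p$psd)], 10, tolerance = p$df)
  expect_lt(abs(band_power(p, 0, 256) - 0.5) / 0.5, 0.05)
  z <- welch_psd(numeric(4096), 512)
  expect_true(all(z$psd == 0))
  expect_error(welch_psd(rnorm(20), 512), "too short|short")
})

test_that("integrated PSD of white noise matches its variance", {
  err <- vapply(1:20, function(s) {
    set.seed(s)
    x <- rnorm(8192, sd = 2)
    p <- welch_psd(x, 512)
    band_power(p, 0, 256) / stats::var(x) - 1
  }, 0)
  expect_lt(abs(mean(err)), 0.10)
})

test_that("normalized band powers resolve single- and two-line spectra", {
  t <- seq(0, 180 - 1 / 512, by = 1 / 512)
  rec <- recording(matrix(sin(2 * pi * 10 * t)), 512, "Fz")
  bp <- normalized_band_powers(rec)
  expect_equal(bp$value[bp$band == "Alpha"], 1, tolerance = 0.05)
  expect_true(all(bp$value[bp$band != "Alpha"] < 0.05))

  rec2 <- recording(matrix(sin(2 * pi * 6 * t) + sin(2 * pi * 10 * t)),
                    512, "Fz")
  bp2 <- normalized_band_powers(rec2)
  expect_lt(abs(bp2$value[bp2$band == "Theta"] -
                  bp2$value[bp2$band == "Alpha"]), 0.05)
})

test_that("non-finite windows are flagged missing, not fatal", {
  t <- seq(0, 360 - 1 / 512, by = 1 / 512)
  x <- sin(2 * pi * 10 * t)
  x[100000] <- NA
  bp <- normalized_band_powers(recording(matrix(x), 512, "Fz"))
  expect_true(all(is.na(bp$value[bp$window_index == 2])))
  expect_true(all(is.finite(bp$value[bp$window_index == 1])))
})

test_that("theta/beta ratio arithmetic and normalization invariance", {
  f <- data.frame(channel = "Fz", band = rep(c("Theta", "Beta"), each = 3),
                  window_start_s = rep(c(0, 180, 360), 2),
                  window_mid_s = rep(c(90, 270, 450), 2),
                  window_index = rep(1:3, 2),
                  value = c(0.2, 0.3, 0.1, 0.1, 0.3, 0),
                  window_length_s = 180)
  r <- theta_beta_ratio(f)
  expect_equal(r$value[1], 2.0)
  expect_equal(r$value[2], 1.0)
  expect_true(is.na(r$value[3]))   # zero Beta -> missing
  # normalization cancels: ratio of raw Welch band powers equals the ratio
  # of normalized powers
  t <- seq(0, 180 - 1 / 512, by = 1 / 512)
  x <- sin(2 * pi * 6 * t) + 0.5 * sin(2 * pi * 20 * t)
  psd <- welch_psd(x, 512)
  raw_ratio <- band_power(psd, 4, 7.5) / band_power(psd, 13, 30)
  bp <- normalized_band_powers(recording(matrix(x), 512, "Fz"))
  norm_ratio <- theta_beta_ratio(bp)$value
  expect_equal(norm_ratio, raw_ratio, tolerance = 1e-12)
})

test_that("linear_trend recovers exact lines and is calibrated on noise", {
  t <- (1:16) * 180 - 90
  y <- 0.2 + 3e-6 * t
  tr <- linear_trend(y, t, "seconds")
  expect_equal(tr$slope, 3e-6, tolerance = 1e-10)
  expect_lt(tr$p_value, 1e-6)
  # constant series
  trc <- linear_trend(rep(1, 10), 1:10, "index")
  expect_equal(trc$slope, 0)
  expect_equal(trc$p_value, 1)
  # type-I calibration
  set.seed(42)
  rej <- mean(replicate(2000,
    linear_trend(rnorm(16), 1:16, "index")$p_value < 0.05))
  expect_gt(rej, 0.03); expect_lt(rej, 0.07)
  # shift invariance and scaling
  y2 <- rnorm(16)
  expect_equal(linear_trend(y2 + 5, t, "seconds")$slope,
               linear_trend(y2, t, "seconds")$slope, tolerance = 1e-12)
  expect_equal(linear_trend(3 * y2, t, "seconds")$slope,
               3 * linear_trend(y2, t, "seconds")$slope, tolerance = 1e-12)
  expect_error(linear_trend(c(1, 2), c(1, 2)), "3 non-missing")
})

test_that("a 50-min recording yields exactly 16 complete 3-min windows", {
  w <- window_indices(3000 * 512, 512, 180)
  expect_equal(nrow(w), 16)
  expect_equal(w$mid_s[1], 90)
})
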
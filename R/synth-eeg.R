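# EEG channel montage used throughout
EEG_CHANNELS <- c("Fz", "Cz", "Pz", "O1", "O2")

# Fraction of 1/f (power ~ 1/f) background power falling inside each band,
# relative to the full 0.5-30 Hz range: ln(high/low) / ln(30/0.5).
bg_band_fractions <- function(bands = eeg_bands(), total_range = c(0.5, 30)) {
  f <- log(bands$high / bands$low) / log(total_range[2] / total_range[1])
  names(f) <- bands$band
  f
}

# Blink spatial weighting: strongly frontal, faint occipitally.
BLINK_WEIGHTS <- c(Fz = 1, Cz = 0.5, Pz = 0.25, O1 = 0.05, O2 = 0.05)

# Per-channel linear trajectories of normalized band power. Injected drifts
# are balanced by proportional counter-drifts of the non-drifting bands'
# oscillatory power so that total 0.5-30 Hz power stays constant; this makes
# the injected slope exact (the stationary background only shifts intercepts).
# Returns baseline/slope of the *targets* and of the oscillatory powers.
band_power_plan <- function(baseline, drift, duration, p_tot = 100) {
  bands <- eeg_bands()$band
  b0 <- baseline[bands]
  d <- setNames(numeric(4), bands)
  if (length(drift)) {
    assert_that(all(names(drift) %in% bands), "unknown band in band_drift")
    d[names(drift)] <- drift
  }
  f <- bg_band_fractions()
  s0 <- sum(b0)
  assert_that(s0 <= 1 + 1e-12, "band baselines sum above 1")
  p_bg <- p_tot * (1 - s0) / (1 - sum(f))
  p_osc0 <- p_tot * b0 - f * p_bg
  assert_that(all(p_osc0 >= -1e-12),
    "band baselines leave no oscillatory power above the 1/f background")
  p_osc0 <- pmax(p_osc0, 0)
  drifting <- d != 0
  eff <- d
  if (any(drifting)) {
    total_d <- sum(d[drifting])
    assert_that(sum(p_osc0[!drifting]) > 0,
      "drift compensation impossible: non-drifting bands carry no power")
    w <- p_osc0[!drifting] / sum(p_osc0[!drifting])
    eff[!drifting] <- -total_d * w
  }
  tgt_end <- b0 + eff * duration
  assert_that(all(tgt_end >= 0 & tgt_end <= 1) && all(b0 >= 0 & b0 <= 1),
              "drift drives a normalized band power outside [0, 1]")
  osc_slope <- p_tot * eff
  assert_that(all(p_osc0 + osc_slope * duration >= -1e-12),
              "drift exhausts a band's oscillatory power; reduce the slope")
  list(target0 = b0, target_slope = eff, p_osc0 = p_osc0,
       p_osc_slope = osc_slope, p_bg = p_bg, p_tot = p_tot)
}

# 1/f^1 band-limited Gaussian background, synthesized directly in the
# frequency domain (random complex amplitudes with 1/sqrt(f) magnitude on the
# band bins, one inverse FFT) and normalized to the requested variance.
one_over_f_noise <- function(n, srate, low = 0.5, high = 30, variance = 1) {
  if (variance <= 0) return(numeric(n))
  kmin <- max(1L, ceiling(low * n / srate))
  kmax <- min(floor(high * n / srate), floor((n - 1) / 2))
  k <- kmin:kmax
  amp <- 1 / sqrt(k * srate / n)
  X <- complex(length.out = n)
  z <- complex(real = stats::rnorm(length(k)),
               imaginary = stats::rnorm(length(k))) * amp
  X[k + 1] <- z
  X[n - k + 1] <- Conj(z)
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y) * sqrt(variance)
}

# Stereotyped eye-blink transient: 300 ms smooth positive bump.
blink_template <- function(srate, amplitude) {
  t <- seq(0, 0.3, by = 1 / srate)
  amplitude * sin(pi * t / 0.3)^2
}

#' Generate a continuous multichannel EEG recording with known ground truth
#'
#' Synthesizes a 5-channel (Fz, Cz, Pz, O1, O2) EEG as the sum of a 1/f
#' band-limited background, per-band sinusoid mixtures whose power envelopes
#' follow linear normalized-power trajectories, frontal-dominant stereotyped
#' blink transients, and a 50 Hz line-noise sinusoid. Injected band drifts are
#' exact in expectation: total 0.5-30 Hz power per channel is held constant by
#' counter-drifting the non-drifting bands (the ground truth records these
#' effective slopes for every band). Fully deterministic given the config seed.
#'
#' @param config a [sim_config()].
#' @param subject subject identifier (used to derive the subject's substream
#'   of the config seed).
#' @return list with `recording` (a [recording], microvolts) and
#'   `ground_truth` (effective normalized-power slopes and baselines per
#'   channel/band, blink onset times, line-noise amplitude).
#' @export
generate_continuous_eeg <- function(config, subject = 1) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  srate <- config$sampling_rate
  dur <- config$lecture_duration
  n <- round(dur * srate)
  tt <- (seq_len(n) - 1) / srate
  bands <- eeg_bands()
  with_seed(child_seed(config$seed, "eeg", subject, config$condition), {
    data <- matrix(0, n, length(EEG_CHANNELS))
    gt_slope <- gt_base <- matrix(0, length(EEG_CHANNELS), nrow(bands),
                                  dimnames = list(EEG_CHANNELS, bands$band))
    for (ci in seq_along(EEG_CHANNELS)) {
      ch <- EEG_CHANNELS[ci]
      plan <- band_power_plan(config$band_baseline,
                              config$band_drift[[ch]], dur)
      x <- one_over_f_noise(n, srate, variance = plan$p_bg)
      for (bi in seq_len(nrow(bands))) {
        m <- 3
        fr <- bands$low[bi] + (c(1, 2, 3) / 4) * (bands$high[bi] - bands$low[bi])
        ph <- stats::runif(m, 0, 2 * pi)
        p_osc <- plan$p_osc0[bi] + plan$p_osc_slope[bi] * tt
        amp <- sqrt(2 * pmax(p_osc, 0) / m)
        for (j in seq_len(m)) x <- x + amp * cos(2 * pi * fr[j] * tt + ph[j])
      }
      data[, ci] <- x
      gt_slope[ci, ] <- plan$target_slope
      gt_base[ci, ] <- plan$target0
    }
    blink_onsets <- numeric(0)
    if (config$blink_rate > 0 && config$blink_amplitude > 0) {
      n_blink <- stats::rpois(1, config$blink_rate * dur / 60)
      blink_onsets <- sort(stats::runif(n_blink, 0, dur - 0.35))
      tmpl <- blink_template(srate, config$blink_amplitude)
      for (b in blink_onsets) {
        i0 <- round(b * srate) + 1
        idx <- i0:(i0 + length(tmpl) - 1)
        data[idx, ] <- data[idx, ] +
          outer(tmpl, BLINK_WEIGHTS[EEG_CHANNELS])
      }
    }
    if (config$line_noise_amp > 0) {
      ln <- config$line_noise_amp * sin(2 * pi * 50 * tt + stats::runif(1, 0, 2 * pi))
      data <- data + ln
    }
    list(recording = recording(data, srate, EEG_CHANNELS, "uV"),
         ground_truth = list(band_slopes = gt_slope,
                             band_baselines = gt_base,
                             blink_onsets = blink_onsets,
                             line_noise_amp = config$line_noise_amp))
  })
}
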
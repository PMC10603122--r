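# Band-limited zero-mean unit-power process as a stratified-frequency,
# random-phase sinusoid superposition. Can be evaluated at arbitrary times and
# has a deterministic time-average autocorrelation
#   rho(tau) = mean(cos(2 pi f_j tau)).
band_process <- function(low, high, m = 64) {
  f <- low + (seq_len(m) - 0.5) / m * (high - low)
  ph <- stats::runif(m, 0, 2 * pi)
  list(f = f, ph = ph, m = m,
       eval = function(t) {
         a <- sqrt(2 / m)
         colSums(a * cos(2 * pi * outer(f, t) + ph))
       },
       rho = function(tau) colMeans(cos(2 * pi * outer(f, tau))))
}

# LF + HF mixture with ln(LF/HF) = log_ratio; unit total power.
rr_variability_process <- function(log_ratio, m = 64) {
  r <- exp(log_ratio)
  lf <- band_process(0.04, 0.15, m)
  hf <- band_process(0.15, 0.40, m)
  w_lf <- sqrt(r / (1 + r)); w_hf <- sqrt(1 / (1 + r))
  list(eval = function(t) w_lf * lf$eval(t) + w_hf * hf$eval(t),
       rho = function(tau) w_lf^2 * lf$rho(tau) + w_hf^2 * hf$rho(tau))
}

# SD envelope (ms) realizing a linear profile of one windowed HRV index.
# Inversion uses closed-form Gaussian-process relations:
#   SDRR   = sigma
#   RMSSD  = sigma * sqrt(2 (1 - rho(RRbar)))
#   pNN50  = 200 * (1 - Phi(50 / (sigma * sqrt(2 (1 - rho(RRbar))))))
rr_sigma_envelope <- function(target, t, rrbar_s, rho_fun, jitter_sd) {
  w <- t / 180
  switch(target$index,
    none = rep(jitter_sd, length(t)),
    sdrr = target$baseline + target$slope * w,
    rmssd = {
      val <- target$baseline + target$slope * w
      val / sqrt(2 * (1 - rho_fun(rrbar_s)))
    },
    pnn50 = {
      p <- target$baseline + target$slope * w
      assert_that(all(p > 0 & p < 100), "pNN50 profile leaves (0, 100)")
      sig_d <- 50 / stats::qnorm(1 - p / 200)
      sig_d / sqrt(2 * (1 - rho_fun(rrbar_s)))
    })
}

# QRS-like template (mV) on a +-0.3 s support: Q and S dips, dominant R
# spike, low broad T wave. Morphology is minimal but Pan-Tompkins-detectable.
qrs_template <- function(srate) {
  t <- seq(-0.3, 0.45, by = 1 / srate)
  g <- function(a, mu, s) a * exp(-(t - mu)^2 / (2 * s^2))
  list(t = t, y = g(-0.15, -0.025, 0.008) + g(1, 0, 0.008) +
         g(-0.2, 0.025, 0.008) + g(0.25, 0.16, 0.04))
}

#' Generate a synthetic RR-interval series and ECG trace with ground truth
#'
#' The RR series is a linear mean-heart-rate trend plus zero-mean variability
#' shaped into two spectral lobes (LF 0.04-0.15 Hz, HF 0.15-0.4 Hz) whose
#' power ratio matches `lf_hf_log_ratio`. The variability SD follows a scale
#' envelope: constant (`rr_target$index = "none"`, SD `rr_jitter_sd`), or
#' inverted from a linear profile of windowed SDRR, RMSSD or pNN50 (per-window
#' slope convention). The ECG trace places a QRS-like template at each
#' cumulative RR time; the exact R times are returned as ground truth and are
#' never consumed by the analysis modules.
#'
#' @param config a [sim_config()].
#' @param subject subject identifier (seed substream).
#' @param ecg logical; if `FALSE`, skip synthesizing the ECG trace (fast path
#'   for RR-level recovery studies).
#' @param ecg_noise_sd additive white measurement noise on the ECG, mV.
#' @return list: `rr` (data.frame `beat_time_s`, `rr_ms`, the ground-truth RR
#'   series), `ecg` (a [recording] in mV, or NULL), `ground_truth` (injected
#'   HR slope, HRV index profile, exact R times).
#' @export
generate_rr_and_ecg <- function(config, subject = 1, ecg = TRUE,
                                ecg_noise_sd = 0.02) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  dur <- config$lecture_duration
  with_seed(child_seed(config$seed, "ecg", subject, config$condition), {
    proc <- rr_variability_process(config$lf_hf_log_ratio)
    hr_fun <- function(t) config$hr_baseline + config$hr_slope * t / 180
    assert_that(min(hr_fun(c(0, dur))) >= 30 && max(hr_fun(c(0, dur))) <= 200,
                "unphysiological heart-rate trajectory")
    # sequential beat placement
    times <- numeric(ceiling(dur * hr_fun(0) / 60 * 1.5) + 16)
    rrs <- numeric(length(times))
    t <- 0.2; i <- 0
    while (t < dur) {
      i <- i + 1
      hr <- hr_fun(t)
      rr_mean <- 60000 / hr
      sig <- rr_sigma_envelope(config$rr_target, t, rr_mean / 1000,
                               proc$rho, config$rr_jitter_sd)
      rr <- rr_mean + sig * proc$eval(t)
      rr <- min(max(rr, 200), 3000)
      times[i] <- t
      rrs[i] <- rr
      t <- t + rr / 1000
    }
    beats <- data.frame(beat_time_s = times[seq_len(i)],
                        rr_ms = rrs[seq_len(i)])
    rec <- NULL
    if (ecg) {
      srate <- config$sampling_rate
      n <- round(dur * srate)
      sig <- stats::rnorm(n, sd = ecg_noise_sd)
      tmpl <- qrs_template(srate)
      off <- round(tmpl$t[1] * srate)
      for (bt in beats$beat_time_s) {
        i0 <- round(bt * srate) + 1 + off
        idx <- i0:(i0 + length(tmpl$y) - 1)
        keep <- idx >= 1 & idx <= n
        sig[idx[keep]] <- sig[idx[keep]] + tmpl$y[keep]
      }
      rec <- recording(matrix(sig, ncol = 1), srate, "ECG", "mV")
    }
    list(rr = beats, ecg = rec,
         ground_truth = list(r_times = beats$beat_time_s,
                             hr_baseline = config$hr_baseline,
                             hr_slope = config$hr_slope,
                             rr_target = config$rr_target,
                             lf_hf_log_ratio = config$lf_hf_log_ratio))
  })
}
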
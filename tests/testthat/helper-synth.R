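# Shared test fixtures: small, artifact-free configs built in code.

quiet_eeg_config <- function(seed, duration = 720, drift = list(),
                             blink_rate = 0, line_noise_amp = 0, ...) {
  sim_config(lecture_duration = duration, blink_rate = blink_rate,
             line_noise_amp = line_noise_amp, band_drift = drift,
             seed = seed, ...)
}

rr_config <- function(seed, duration = 3000, hr_slope = 0,
                      target = list(index = "none"), ...) {
  sim_config(lecture_duration = duration, hr_slope = hr_slope,
             rr_target = target, seed = seed, ...)
}

rmse <- function(a, b) sqrt(mean((a - b)^2))

# sinusoid recording helper
sine_rec <- function(freq, dur = 10, srate = 512, channels = "Fz", amp = 1) {
  t <- (0:(round(dur * srate) - 1)) / srate
  recording(matrix(rep(amp * sin(2 * pi * freq * t), length(channels)),
                   ncol = length(channels)), srate, channels)
}

# flat multichannel recording for ERP construction
zero_rec <- function(dur, srate = 512,
                     channels = c("Fz", "Cz", "Pz", "O1", "O2")) {
  recording(matrix(0, round(dur * srate), length(channels)), srate, channels)
}

fz_theta_series <- function(cfg) {
  g <- generate_continuous_eeg(cfg, 1)
  bp <- normalized_band_powers(rec_subset(g$recording, "Fz"))
  bp[bp$band == "Theta", ]
}
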
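#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults describe the
#' experimental setting emulated throughout the package: a 50-min lecture
#' (3000 s) recorded at 512 Hz on five EEG channels (Fz, Cz, Pz, O1, O2) plus
#' a 2-lead ECG. With `condition = "videoconference"` the fatigue signatures
#' reported for that condition are injected (frontal Theta and all-channel
#' Alpha normalized-power drifts, a -0.1482 bpm-per-window heart-rate decline,
#' and a rising short-term HRV envelope); `"face_to_face"` injects none.
#'
#' Slope-unit conventions (fixed, documented): EEG band drifts are in
#' normalized power per second; HR and HRV drifts are in index units per
#' 3-min window.
#'
#' @param n_subjects number of subjects (default 35).
#' @param sampling_rate Hz (default 512).
#' @param lecture_duration seconds (default 3000, i.e. 50 min).
#' @param condition "videoconference" or "face_to_face".
#' @param band_baseline named numeric, baseline normalized power per band.
#'   Must leave room for the 1/f background (see vignette).
#' @param band_drift named list: channel -> named numeric of normalized-power
#'   slopes per second, e.g. `list(Fz = c(Theta = 2.724e-06))`. `NULL` gives
#'   condition defaults.
#' @param hr_baseline mean heart rate at lecture start, bpm (default 75).
#' @param hr_slope bpm per 3-min window. `NULL` gives the condition default.
#' @param lf_hf_log_ratio target ln(LF/HF) of RR variability (default 0.3).
#' @param rr_jitter_sd baseline RR variability SD in ms (default 30), used
#'   when no HRV index profile is injected.
#' @param rr_target `list(index, baseline, slope)` injecting a linear profile
#'   of one windowed HRV index: index one of "none", "sdrr" (ms), "rmssd"
#'   (ms), "pnn50" (%); slope per 3-min window. `NULL` gives condition
#'   defaults ("rmssd" rising for videoconference, "none" otherwise).
#' @param erp_template component table from [default_erp_template()].
#' @param erp_after_gain multiplicative ERP amplitude change after the
#'   lecture (fatigue-induced modulation; default 0.85 for videoconference,
#'   1 otherwise).
#' @param blink_rate eye blinks per minute (default 12).
#' @param blink_amplitude blink peak amplitude at Fz in microvolts (default 100).
#' @param line_noise_amp 50 Hz line-noise amplitude in microvolts (default 5).
#' @param latent_fatigue_effect standardized shift of the latent fatigue
#'   variable in the videoconference condition (default 0.8).
#' @param seed integer; fully determines all generator outputs.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 35,
                       sampling_rate = 512,
                       lecture_duration = 3000,
                       condition = c("videoconference", "face_to_face"),
                       band_baseline = c(Delta = 0.42, Theta = 0.16,
                                         Alpha = 0.23, Beta = 0.15),
                       band_drift = NULL,
                       hr_baseline = 75,
                       hr_slope = NULL,
                       lf_hf_log_ratio = 0.3,
                       rr_jitter_sd = 30,
                       rr_target = NULL,
                       erp_template = default_erp_template(),
                       erp_after_gain = NULL,
                       blink_rate = 12,
                       blink_amplitude = 100,
                       line_noise_amp = 5,
                       latent_fatigue_effect = 0.8,
                       seed = 1L) {
  condition <- match.arg(condition)
  vc <- condition == "videoconference"
  if (is.null(band_drift)) {
    band_drift <- if (vc) list(
      Fz = c(Theta = 2.7240e-06, Alpha = 5.3551e-06),
      Cz = c(Alpha = 4.8269e-06),
      Pz = c(Alpha = 1.0847e-05),
      O1 = c(Alpha = 1.2191e-05),
      O2 = c(Alpha = 1.2820e-05)) else list()
  }
  if (is.null(hr_slope)) hr_slope <- if (vc) -0.1482 else 0
  if (is.null(rr_target)) {
    rr_target <- if (vc) list(index = "rmssd", baseline = 30, slope = 0.4955)
                 else list(index = "none")
  }
  if (is.null(erp_after_gain)) erp_after_gain <- if (vc) 0.85 else 1
  cfg <- list(n_subjects = n_subjects, sampling_rate = sampling_rate,
              lecture_duration = lecture_duration, condition = condition,
              band_baseline = band_baseline, band_drift = band_drift,
              hr_baseline = hr_baseline, hr_slope = hr_slope,
              lf_hf_log_ratio = lf_hf_log_ratio,
              rr_jitter_sd = rr_jitter_sd, rr_target = rr_target,
              erp_template = erp_template, erp_after_gain = erp_after_gain,
              blink_rate = blink_rate, blink_amplitude = blink_amplitude,
              line_noise_amp = line_noise_amp,
              latent_fatigue_effect = latent_fatigue_effect,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  assert_that(cfg$sampling_rate > 0, "sampling_rate must be > 0")
  assert_that(cfg$lecture_duration > 0, "lecture_duration must be > 0")
  assert_that(cfg$n_subjects >= 1, "n_subjects must be >= 1")
  assert_that(all(c("Delta", "Theta", "Alpha", "Beta") %in%
                    names(cfg$band_baseline)),
              "band_baseline must name Delta, Theta, Alpha, Beta")
  assert_that(all(cfg$band_baseline >= 0) && sum(cfg$band_baseline) <= 1,
              "band baselines must be non-negative and sum to at most 1")
  assert_that(cfg$blink_rate >= 0 && cfg$blink_amplitude >= 0 &&
                cfg$line_noise_amp >= 0, "amplitudes and rates must be >= 0")
  n_win <- floor(cfg$lecture_duration / 180)
  hr_end <- cfg$hr_baseline + cfg$hr_slope * n_win
  assert_that(cfg$hr_baseline >= 30 && cfg$hr_baseline <= 200 &&
                hr_end >= 30 && hr_end <= 200,
              "heart-rate trajectory leaves the physiological range [30, 200] bpm")
  assert_that(cfg$rr_target$index %in% c("none", "sdrr", "rmssd", "pnn50"),
              "rr_target$index must be none, sdrr, rmssd or pnn50")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d subject(s), %s, %.0f s at %g Hz, seed %d\n",
              x$n_subjects, x$condition, x$lecture_duration,
              x$sampling_rate, x$seed))
  invisible(x)
}

#' Read / write a simulation configuration as JSON
#'
#' The on-disk schema is a flat JSON object mirroring the [sim_config()]
#' arguments; `erp_template` is stored as a records table.
#'
#' @param cfg a `sim_config`.
#' @param path file path.
#' @return `read_sim_config` returns a `sim_config`.
#' @export
write_sim_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$band_baseline <- as.list(x$band_baseline)     # keep names in JSON
  x$band_drift <- lapply(x$band_drift, as.list)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$band_baseline <- unlist(x$band_baseline)
  x$band_drift <- lapply(x$band_drift, unlist)
  x$erp_template <- as.data.frame(x$erp_template)
  do.call(sim_config, x)
}
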
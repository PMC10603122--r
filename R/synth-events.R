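#' Generate an oddball stimulus sequence
#'
#' Produces an event stream of rare targets among frequent standards:
#' exactly `n_events * p_target` targets (the product must be an integer),
#' order randomized by `seed`, each presentation lasting 500 ms, with a fixed
#' 1.0 s onset-to-onset interval by default.
#'
#' @param n_events total number of events (default 500).
#' @param p_target target probability (default 0.10, i.e. 50 of 500).
#' @param seed integer seed controlling the order.
#' @param isi onset-to-onset interval in seconds (default 1.0).
#' @param duration presentation duration in seconds (default 0.5).
#' @param t0 onset of the first event in seconds (default 1.0, leaving room
#'   for a pre-stimulus epoch window).
#' @return data.frame (`onset_s`, `duration_s`, `label`) with label
#'   "target" or "standard".
#' @export
#' @examples
#' ev <- generate_oddball_sequence(500, 0.10, seed = 1)
#' table(ev$label)  # 50 targets, 450 standards
generate_oddball_sequence <- function(n_events, p_target = 0.1, seed = 1L,
                                      isi = 1.0, duration = 0.5, t0 = 1.0) {
  assert_that(p_target > 0 && p_target < 1, "p_target must lie in (0, 1)")
  n_target <- n_events * p_target
  assert_that(abs(n_target - round(n_target)) < 1e-9,
              sprintf("n_events * p_target = %g is not an integer; %s",
                      n_target,
                      "choose counts giving a whole number of targets"))
  n_target <- round(n_target)
  labels <- rep("standard", n_events)
  labels[with_seed(seed, sample.int(n_events, n_target))] <- "target"
  data.frame(onset_s = t0 + (seq_len(n_events) - 1) * isi,
             duration_s = duration, label = labels)
}

#' Default ERP component templates
#'
#' Gaussian-windowed deflections: a negative N2 (fronto-central), a positive
#' P3a (fronto-central) and a positive P300 (centro-parietal). Latencies fall
#' inside the conventional component search windows (N2 0.2-0.35 s,
#' P3a 0.25-0.5 s, P300 0.3-0.7 s).
#'
#' @return data.frame with `component`, `amplitude` (microvolts, signed),
#'   `latency` (s, peak), `width` (s, Gaussian SD), and one weight column per
#'   EEG channel.
#' @export
default_erp_template <- function() {
  data.frame(component = c("N2", "P3a", "P300"),
             amplitude = c(-5, 6, 8),
             latency = c(0.25, 0.35, 0.45),
             width = c(0.03, 0.05, 0.08),
             Fz = c(0.9, 1.0, 0.5),
             Cz = c(1.0, 0.9, 0.8),
             Pz = c(0.6, 0.6, 1.0),
             O1 = c(0.3, 0.3, 0.4),
             O2 = c(0.3, 0.3, 0.4))
}

# Sum of the Gaussian component waveforms for one channel over time axis t
# (seconds relative to stimulus onset).
erp_waveform_from_template <- function(template, channel, t, gain = 1) {
  w <- numeric(length(t))
  for (k in seq_len(nrow(template))) {
    cw <- if (channel %in% names(template)) template[[channel]][k] else 1
    w <- w + gain * template$amplitude[k] * cw *
      exp(-(t - template$latency[k])^2 / (2 * template$width[k]^2))
  }
  w
}

#' Embed stimulus-locked ERP components into a recording
#'
#' Adds the Gaussian component templates at each event onset. Target events
#' receive the full template; standard events a reduced response
#' (`standard_gain`, default 0.3), preserving the target > standard oddball
#' contrast. Events whose response window would extend past the end of the
#' recording are rejected.
#'
#' @param rec a [recording].
#' @param events event stream from [generate_oddball_sequence()].
#' @param template component table as from [default_erp_template()].
#' @param gain overall multiplicative scaling of all components (e.g. the
#'   post-lecture amplitude modulation).
#' @param standard_gain relative amplitude of the response to standards.
#' @return a [recording] with ERPs added.
#' @export
embed_erp <- function(rec, events, template = default_erp_template(),
                      gain = 1, standard_gain = 0.3) {
  assert_that(inherits(rec, "recording"), "rec must be a recording")
  span <- max(template$latency + 8 * template$width)
  assert_that(all(events$onset_s >= 0) &&
                all(events$onset_s + span <= rec_duration(rec)),
              "event beyond recording end")
  if (all(template$amplitude == 0)) return(rec)
  srate <- rec$srate
  nt <- round(span * srate)
  t_rel <- (0:nt) / srate
  out <- rec$data
  wave <- vapply(rec$channels, function(ch)
    erp_waveform_from_template(template, ch, t_rel, gain), t_rel)
  for (e in seq_len(nrow(events))) {
    g <- if (events$label[e] == "target") 1 else standard_gain
    i0 <- round(events$onset_s[e] * srate) + 1
    idx <- i0:(i0 + nt)
    out[idx, ] <- out[idx, ] + g * wave
  }
  recording(out, srate, rec$channels, rec$units)
}
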
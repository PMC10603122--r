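#' Pan-Tompkins QRS detection
#'
#' Classic chain: zero-phase 5-15 Hz band-pass, five-point derivative,
#' squaring, 150 ms moving-window integration, adaptive dual thresholds with
#' a 200 ms refractory period and search-back at half threshold. Detected
#' peaks are refined to the local maximum of the band-passed signal and
#' returned as R times.
#'
#' @param rec single-channel ECG [recording] of at least 10 s.
#' @return data.frame (`beat_time_s`, `rr_ms`) of class `rr_series` with
#'   `attr(, "provenance") = "detected"`; errors when no beat is found.
#' @export
pan_tompkins <- function(rec) {
  assert_that(inherits(rec, "recording") && ncol(rec$data) == 1,
              "single ECG channel required")
  srate <- rec$srate
  assert_that(nrow(rec$data) >= 10 * srate, "need at least 10 s of ECG")
  x <- rec$data[, 1]
  assert_that(stats::sd(x) > 0, "flat-line ECG; no beats detectable")
  h <- fir_design_bandpass_ls(5, 15, 128, srate)
  bp <- fir_apply_centered(x, h)
  der <- c(0, 0, diff(bp, lag = 4) / 4, 0, 0) * srate / 2
  sq <- der^2
  wl <- round(0.150 * srate)
  mwi <- as.numeric(stats::filter(sq, rep(1 / wl, wl), sides = 2))
  mwi[is.na(mwi)] <- 0
  refr <- round(0.200 * srate)
  # candidate peaks of the integrated signal
  pk <- which(diff(sign(diff(mwi))) < 0) + 1
  assert_that(length(pk) > 0, "no peaks in the integrated ECG signal")
  spki <- max(mwi[seq_len(min(2 * srate, length(mwi)))]) * 0.5
  npki <- mean(mwi[seq_len(min(2 * srate, length(mwi)))]) * 0.5
  beats <- integer(0)
  last <- -Inf
  i <- 1
  while (i <= length(pk)) {
    p <- pk[i]
    thr <- npki + 0.25 * (spki - npki)
    if (p - last >= refr && mwi[p] > thr) {
      beats <- c(beats, p)
      spki <- 0.125 * mwi[p] + 0.875 * spki
      last <- p
    } else if (mwi[p] <= thr) {
      npki <- 0.125 * mwi[p] + 0.875 * npki
    }
    # search-back: expected beat missed by > 1.66 x running RR average
    if (length(beats) >= 2) {
      rr_avg <- mean(diff(utils::tail(beats, 8)))
      if (p - last > 1.66 * rr_avg) {
        cand <- pk[pk > last + refr & pk < p]
        cand <- cand[mwi[cand] > npki + 0.125 * (spki - npki)]
        if (length(cand)) {
          b <- cand[which.max(mwi[cand])]
          beats <- sort(c(beats, b))
          spki <- 0.25 * mwi[b] + 0.75 * spki
          last <- max(beats)
        }
      }
    }
    i <- i + 1
  }
  assert_that(length(beats) >= 2, "fewer than 2 beats detected")
  # refine to the band-passed R peak within a centered integration window
  half <- wl
  r_idx <- vapply(beats, function(b) {
    lo <- max(1, b - half); hi <- min(length(bp), b + half)
    lo + which.max(bp[lo:hi]) - 1
  }, 0)
  r_idx <- sort(unique(r_idx))
  t_r <- (r_idx - 1) / srate
  rr <- data.frame(beat_time_s = t_r,
                   rr_ms = c(NA, diff(t_r) * 1000))
  structure(rr, provenance = "detected", class = c("rr_series", "data.frame"))
}

#' Clean an RR series of ectopic or implausible intervals
#'
#' Removes intervals outside `[200, 3000]` ms or differing more than 30% from
#' the previous interval, and linearly interpolates the gap.
#'
#' @param rr data.frame with `beat_time_s`, `rr_ms`.
#' @param limits plausible interval range in ms.
#' @param rel_jump maximum relative change between successive intervals.
#' @return cleaned RR data.frame.
#' @export
clean_rr <- function(rr, limits = c(200, 3000), rel_jump = 0.3) {
  v <- rr$rr_ms
  ok <- is.finite(v) & v >= limits[1] & v <= limits[2]
  prev <- c(NA, v[-length(v)])
  jump <- is.finite(prev) & abs(v - prev) / prev > rel_jump
  ok <- ok & !jump
  if (any(!ok) && sum(ok) >= 2)
    v[!ok] <- stats::approx(rr$beat_time_s[ok], v[ok],
                            xout = rr$beat_time_s[!ok], rule = 2)$y
  rr$rr_ms <- v
  rr
}

#' Resample an RR series to a uniform grid
#'
#' Cubic-spline interpolation of the instantaneous RR interval (ms) on a
#' uniform grid (default 4 Hz) spanning the beats.
#'
#' @param rr data.frame with `beat_time_s`, `rr_ms` (NA first interval
#'   allowed).
#' @param rate grid rate in Hz (default 4).
#' @return data.frame (`time_s`, `rr_ms`).
#' @export
resample_rr <- function(rr, rate = 4) {
  ok <- is.finite(rr$rr_ms)
  assert_that(sum(ok) >= 3, "need at least 3 beats to resample")
  t0 <- min(rr$beat_time_s[ok]); t1 <- max(rr$beat_time_s[ok])
  grid <- seq(t0, t1, by = 1 / rate)
  sp <- stats::spline(rr$beat_time_s[ok], rr$rr_ms[ok], xout = grid,
                      method = "fmm")
  data.frame(time_s = grid, rr_ms = sp$y)
}

#' Time-domain HRV indices of one window of RR intervals
#'
#' HR = 60000 / mean(RR); RMSSD = root mean square of successive differences;
#' NN50 = count of successive differences exceeding 50 ms;
#' pNN50 = 100 * NN50 / denominator; SDRR = sample SD of the intervals.
#' The default pNN50 denominator is the total number of RR intervals (the
#' literal instrument definition used here); `pnn50_denominator =
#' "differences"` selects the conventional successive-difference count.
#'
#' @param rr_ms numeric vector of RR intervals in ms (at least 2 for the
#'   variability indices; HR alone is computed from 1).
#' @param pnn50_denominator "intervals" (default) or "differences".
#' @return list: `hr` (bpm), `rmssd` (ms), `pnn50` (%), `sdrr` (ms),
#'   `n_beats`.
#' @export
time_domain_indices <- function(rr_ms,
                                pnn50_denominator = c("intervals",
                                                      "differences")) {
  pnn50_denominator <- match.arg(pnn50_denominator)
  rr_ms <- rr_ms[is.finite(rr_ms)]
  assert_that(length(rr_ms) >= 1, "empty RR window")
  hr <- 60000 / mean(rr_ms)
  if (length(rr_ms) < 2)
    return(list(hr = hr, rmssd = NA_real_, pnn50 = NA_real_,
                sdrr = NA_real_, n_beats = length(rr_ms)))
  d <- diff(rr_ms)
  nn50 <- sum(abs(d) > 50)
  denom <- if (pnn50_denominator == "intervals") length(rr_ms) else length(d)
  list(hr = hr,
       rmssd = sqrt(mean(d^2)),
       pnn50 = 100 * nn50 / denom,
       sdrr = stats::sd(rr_ms),
       n_beats = length(rr_ms))
}

#' Frequency-domain HRV indices from a uniformly resampled RR series
#'
#' Welch PSD (8 Hamming segments, 50% overlap, linear detrend) of the 4 Hz RR
#' series; LF = integral over 0.04-0.15 Hz, HF over 0.15-0.4 Hz, total over
#' `total_low`-0.4 Hz (default lower edge 0.003 Hz, excluding DC).
#' LF_nu = LF/total, HF_nu = HF/total, ln_lf_hf = ln(LF/HF) (NA when HF = 0).
#'
#' @param uniform data.frame from [resample_rr()] covering >= 180 s.
#' @param rate grid rate in Hz.
#' @param total_low lower edge of the total-power integral in Hz.
#' @return list: `lf_nu`, `hf_nu`, `ln_lf_hf`.
#' @export
freq_domain_indices <- function(uniform, rate = 4, total_low = 0.003) {
  assert_that(nrow(uniform) >= 180 * rate * 0.98,
              "need at least ~180 s of uniformly resampled series")
  psd <- welch_psd(uniform$rr_ms, rate, detrend = "linear")
  lf <- band_power(psd, 0.04, 0.15)
  hf <- band_power(psd, 0.15 + psd$df / 2, 0.40)   # disjoint from LF
  tot <- band_power(psd, max(total_low, psd$df / 2), 0.40)
  list(lf_nu = lf / tot, hf_nu = hf / tot,
       ln_lf_hf = if (hf > 0) log(lf / hf) else NA_real_)
}

#' Windowed HRV indices over a recording-long RR series
#'
#' Computes all seven indices (HR, RMSSD, pNN50, SDRR, LF_nu, HF_nu,
#' ln[LF/HF]) per complete non-overlapping window (default 3 min). Windows
#' with fewer than 30 beats are flagged unreliable (`reliable = FALSE`).
#'
#' @param rr data.frame (`beat_time_s`, `rr_ms`), detected or ground truth.
#' @param window_length seconds (default 180).
#' @param duration total span in seconds; defaults to the last beat time.
#' @param pnn50_denominator passed to [time_domain_indices()].
#' @return tidy data.frame: `window_index`, `window_start_s`, `window_mid_s`,
#'   the seven indices, `n_beats`, `reliable`.
#' @export
windowed_hrv <- function(rr, window_length = 180, duration = NULL,
                         pnn50_denominator = c("intervals", "differences")) {
  pnn50_denominator <- match.arg(pnn50_denominator)
  duration <- duration %||% max(rr$beat_time_s)
  n_win <- floor(duration / window_length)
  assert_that(n_win >= 1, "series shorter than one window")
  uni <- resample_rr(rr)
  out <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    lo <- (w - 1) * window_length; hi <- w * window_length
    sel <- rr$beat_time_s >= lo & rr$beat_time_s < hi
    td <- time_domain_indices(rr$rr_ms[sel], pnn50_denominator)
    useg <- uni[uni$time_s >= lo & uni$time_s < hi, ]
    fd <- if (nrow(useg) >= 180 * 4 * 0.98)
      freq_domain_indices(useg)
      else list(lf_nu = NA_real_, hf_nu = NA_real_, ln_lf_hf = NA_real_)
    out[[w]] <- data.frame(window_index = w, window_start_s = lo,
                           window_mid_s = lo + window_length / 2,
                           hr = td$hr, rmssd = td$rmssd, pnn50 = td$pnn50,
                           sdrr = td$sdrr, lf_nu = fd$lf_nu,
                           hf_nu = fd$hf_nu, ln_lf_hf = fd$ln_lf_hf,
                           n_beats = td$n_beats, reliable = td$n_beats >= 30)
  }
  do.call(rbind, out)
}
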
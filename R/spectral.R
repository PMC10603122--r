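#' Default EEG frequency band definitions
#'
#' Delta 0.5-3.5, Theta 4-7.5, Alpha 8-12.5, Beta 13-30 Hz. The gaps between
#' bands (3.5-4, 7.5-8, 12.5-13 Hz) are deliberately excluded from all band
#' integrals; band edges are treated literally.
#'
#' @return data.frame with columns `band`, `low`, `high`.
#' @export
eeg_bands <- function() {
  data.frame(band = c("Delta", "Theta", "Alpha", "Beta"),
             low = c(0.5, 4, 8, 13),
             high = c(3.5, 7.5, 12.5, 30))
}

#' Windowed normalized EEG band powers
#'
#' For every channel and every complete non-overlapping window (default 3 min)
#' computes the Welch PSD and the band power in each band divided by the total
#' power, where "total" is the PSD integral over `total_range`
#' (default 0.5-30 Hz, the union of the defined bands plus their gaps).
#' A window containing non-finite samples is flagged missing.
#'
#' @param rec a [recording] (EEG, typically after preprocessing).
#' @param bands band table as from [eeg_bands()].
#' @param window_length window length in seconds (default 180).
#' @param total_range length-2 numeric, normalization range in Hz.
#' @return tidy data.frame: `channel`, `band`, `window_start_s`,
#'   `window_mid_s`, `window_index`, `value` (normalized power in `[0, 1]`,
#'   NA for flagged windows), `window_length_s`.
#' @export
normalized_band_powers <- function(rec, bands = eeg_bands(),
                                   window_length = 180,
                                   total_range = c(0.5, 30)) {
  assert_that(inherits(rec, "recording"), "rec must be a recording")
  win <- window_indices(nrow(rec$data), rec$srate, window_length)
  out <- vector("list", ncol(rec$data) * nrow(win))
  k <- 0
  for (ci in seq_len(ncol(rec$data))) {
    for (wi in seq_len(nrow(win))) {
      seg <- rec$data[win$start[wi]:win$end[wi], ci]
      if (all(is.finite(seg))) {
        psd <- welch_psd(seg, rec$srate)
        tot <- band_power(psd, total_range[1], total_range[2])
        val <- vapply(seq_len(nrow(bands)), function(b)
          band_power(psd, bands$low[b], bands$high[b]) / tot, 0)
      } else {
        val <- rep(NA_real_, nrow(bands))
      }
      k <- k + 1
      out[[k]] <- data.frame(channel = rec$channels[ci], band = bands$band,
                             window_start_s = win$start_s[wi],
                             window_mid_s = win$mid_s[wi],
                             window_index = wi, value = val,
                             window_length_s = window_length)
    }
  }
  do.call(rbind, out)
}

#' Frontal Theta/Beta power ratio
#'
#' Element-wise Theta divided by Beta normalized power at a frontal channel
#' (default Fz). Because the same total-power normalization appears in both
#' numerator and denominator, the ratio is identical for normalized and raw
#' band powers. Windows with zero Beta power yield NA.
#'
#' @param features tidy feature table from [normalized_band_powers()].
#' @param channel channel to use (default "Fz").
#' @return data.frame with the window columns plus `value` = Theta/Beta.
#' @export
theta_beta_ratio <- function(features, channel = "Fz") {
  th <- features[features$channel == channel & features$band == "Theta", ]
  be <- features[features$channel == channel & features$band == "Beta", ]
  assert_that(nrow(th) > 0 && nrow(be) > 0,
              sprintf("Theta and Beta series at %s required", channel))
  th <- th[order(th$window_index), ]
  be <- be[order(be$window_index), ]
  assert_that(identical(th$window_index, be$window_index),
              "Theta and Beta series misaligned")
  ratio <- ifelse(is.na(be$value) | be$value == 0, NA_real_,
                  th$value / be$value)
  data.frame(channel = channel, band = "Theta/Beta",
             window_start_s = th$window_start_s,
             window_mid_s = th$window_mid_s,
             window_index = th$window_index,
             value = ratio, window_length_s = th$window_length_s)
}

#' Linear trend of a windowed feature series
#'
#' Ordinary least squares of the feature value on time with a two-sided t test
#' of the slope. The time axis is either the window mid-point in seconds
#' ("seconds", the primary convention) or the 1-based window index
#' ("index", one unit per 3-min window). Missing windows are dropped.
#'
#' @param value numeric vector of per-window values (NA allowed).
#' @param time numeric vector of window mid-points in seconds, or window
#'   indices; must match `axis`.
#' @param axis "seconds" or "index" (documentation of the convention used;
#'   the regression simply uses `time` as given).
#' @return list of class `trend_result`: `slope`, `intercept`, `p_value`,
#'   `n_points`, `axis`.
#' @export
linear_trend <- function(value, time, axis = c("seconds", "index")) {
  axis <- match.arg(axis)
  ok <- is.finite(value) & is.finite(time)
  value <- value[ok]; time <- time[ok]
  assert_that(length(value) >= 3, "need at least 3 non-missing windows")
  if (stats::var(value) == 0)
    return(structure(list(slope = 0, intercept = value[1], p_value = 1,
                          n_points = length(value), axis = axis),
                     class = "trend_result"))
  fit <- stats::lm(value ~ time)
  sm <- summary(fit)$coefficients
  structure(list(slope = unname(sm["time", "Estimate"]),
                 intercept = unname(sm["(Intercept)", "Estimate"]),
                 p_value = unname(sm["time", "Pr(>|t|)"]),
                 n_points = length(value), axis = axis),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("<trend> slope %.4g per %s (p = %.3g, n = %d)\n",
              x$slope, sub("s$", "", x$axis), x$p_value, x$n_points))
  invisible(x)
}
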
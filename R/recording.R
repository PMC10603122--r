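#' Multichannel uniformly sampled biosignal recording
#'
#' Lightweight container for a block of uniformly sampled signals: a numeric
#' matrix (samples x channels) plus sampling rate, channel labels and units.
#' EEG recordings use microvolts ("uV"), ECG millivolts ("mV").
#'
#' @param data numeric matrix, one column per channel.
#' @param srate sampling rate in Hz (> 0).
#' @param channels character vector of channel labels, one per column.
#' @param units unit string, e.g. "uV" or "mV".
#' @return an object of class `recording`.
#' @export
#' @examples
#' r <- recording(matrix(rnorm(1024), ncol = 2), 512, c("Fz", "Cz"))
#' rec_duration(r)
recording <- function(data, srate, channels, units = "uV") {
  data <- as.matrix(data)
  assert_that(is.numeric(data), "recording data must be numeric")
  assert_that(is.numeric(srate) && length(srate) == 1L && srate > 0,
              "sampling rate must be a positive scalar")
  assert_that(length(channels) == ncol(data),
              "one channel label per data column required")
  structure(list(data = data, srate = srate,
                 channels = as.character(channels), units = units),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) [%s], %.1f s at %g Hz (%s)\n",
              ncol(x$data), paste(x$channels, collapse = ", "),
              rec_duration(x), x$srate, x$units))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec a [recording].
#' @return numeric scalar, `nrow(data) / srate`.
#' @export
rec_duration <- function(rec) nrow(rec$data) / rec$srate

#' Extract one channel as a numeric vector
#' @param rec a [recording].
#' @param channel channel label.
#' @return numeric vector.
#' @export
rec_channel <- function(rec, channel) {
  i <- match(channel, rec$channels)
  assert_that(!is.na(i), sprintf("channel '%s' not found", channel))
  rec$data[, i]
}

#' Subset a recording to a set of channels
#' @param rec a [recording].
#' @param channels labels to keep (order preserved as given).
#' @return a [recording].
#' @export
rec_subset <- function(rec, channels) {
  i <- match(channels, rec$channels)
  assert_that(!anyNA(i), "unknown channel in subset")
  recording(rec$data[, i, drop = FALSE], rec$srate, rec$channels[i], rec$units)
}

#' Sample indices of non-overlapping analysis windows
#'
#' Splits a recording into complete non-overlapping windows of
#' `window_length` seconds; a trailing partial window is discarded.
#'
#' @param n_samples number of samples available.
#' @param srate sampling rate in Hz.
#' @param window_length window length in seconds (default 180, i.e. 3 min).
#' @return data.frame with columns `start` and `end` (1-based sample indices)
#'   and `start_s`, `mid_s` (window start and mid-point in seconds).
#' @export
window_indices <- function(n_samples, srate, window_length = 180) {
  wl <- round(window_length * srate)
  n_win <- floor(n_samples / wl)
  assert_that(n_win >= 1, "recording shorter than one analysis window")
  start <- (seq_len(n_win) - 1L) * wl + 1L
  data.frame(start = start, end = start + wl - 1L,
             start_s = (start - 1) / srate,
             mid_s = (start - 1) / srate + window_length / 2)
}
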
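#' Welch power spectral density estimate
#'
#' Averaged modified periodograms: the signal is divided into `n_segments`
#' segments with `overlap` fractional overlap (defaults: 8 segments, 50%),
#' each segment is Hamming-windowed, and the one-sided periodograms are
#' averaged. Scaling is Parseval-consistent: `sum(psd) * df` approximates the
#' signal variance.
#'
#' @param x numeric vector, a single-channel signal segment.
#' @param srate sampling rate in Hz.
#' @param n_segments number of segments (default 8).
#' @param overlap fractional overlap between segments (default 0.5).
#' @param detrend per-segment detrending: "constant" (default, removes the
#'   segment mean), "linear", or "none".
#' @return list with `freq` (Hz), `psd` (power per Hz) and `df` (bin width).
#' @export
#' @examples
#' s <- sin(2 * pi * 10 * seq(0, 10, by = 1/512))
#' p <- welch_psd(s, 512)
#' p$freq[which.max(p$psd)]  # 10 Hz
welch_psd <- function(x, srate, n_segments = 8, overlap = 0.5,
                      detrend = c("constant", "linear", "none")) {
  detrend <- match.arg(detrend)
  n <- length(x)
  denom <- 1 + (n_segments - 1) * (1 - overlap)
  seg_len <- floor(n / denom)
  assert_that(seg_len >= 8, "segment too short for Welch estimation")
  step <- floor(seg_len * (1 - overlap))
  starts <- seq(1, n - seg_len + 1, by = max(step, 1))
  if (length(starts) > n_segments) starts <- starts[seq_len(n_segments)]
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(seg_len - 1)) / (seg_len - 1))
  u <- sum(w^2)
  nf <- floor(seg_len / 2) + 1
  acc <- numeric(nf)
  tt <- seq_len(seg_len)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1)]
    seg <- switch(detrend,
                  constant = seg - mean(seg),
                  linear = stats::residuals(stats::lm.fit(cbind(1, tt), seg)),
                  none = seg)
    X <- stats::fft(seg * w)[seq_len(nf)]
    p <- Mod(X)^2 / (srate * u)
    p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]          # one-sided
    if (seg_len %% 2 == 1) p[nf] <- 2 * p[nf]
    acc <- acc + p
  }
  df <- srate / seg_len
  list(freq = (seq_len(nf) - 1) * df, psd = acc / length(starts), df = df)
}

#' Integrate a PSD over a frequency band
#'
#' Rectangle-rule integral of the Welch PSD over bins whose center frequency
#' falls in `[low, high]` (inclusive).
#'
#' @param psd a list as returned by [welch_psd()].
#' @param low,high band edges in Hz.
#' @return numeric scalar band power (signal units squared).
#' @export
band_power <- function(psd, low, high) {
  sel <- psd$freq >= low & psd$freq <= high
  sum(psd$psd[sel]) * psd$df
}
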
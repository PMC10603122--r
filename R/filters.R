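#' FIR filter design: Hamming windowed-sinc and least-squares
#'
#' `fir_design_highpass()` designs a zero-phase (type I, odd-length) high-pass
#' filter by spectral inversion of a Hamming windowed-sinc low-pass; the cutoff
#' is the approximately -6 dB point. This is the classic windowed-sinc design
#' used for slow-drift removal in EEG (0.5 Hz, order 1128 by default).
#'
#' `fir_design_bandpass_ls()` returns the unweighted least-squares (truncated
#' Fourier series) approximation of an ideal band-pass response; applied
#' forward and backward it gives the "two-way least-squares FIR" band-pass of
#' the ERP path (0.5-30 Hz).
#'
#' @param cutoff,low,high corner frequencies in Hz.
#' @param order filter order (number of taps minus one; forced even).
#' @param srate sampling rate in Hz.
#' @return numeric vector of `order + 1` symmetric filter coefficients.
#' @export
fir_design_highpass <- function(cutoff, order, srate) {
  assert_that(cutoff > 0 && cutoff < srate / 2, "cutoff must lie in (0, Nyquist)")
  assert_that(order > 0, "order must be positive")
  if (order %% 2 == 1) order <- order + 1L
  n <- 0:order
  x <- n - order / 2
  fc <- cutoff / srate
  h <- ifelse(x == 0, 2 * fc, sin(2 * pi * fc * x) / (pi * x))
  w <- 0.54 - 0.46 * cos(2 * pi * n / order)
  hl <- h * w
  hl <- hl / sum(hl)                    # exact unity DC gain for the low-pass
  hh <- -hl
  hh[order / 2 + 1] <- hh[order / 2 + 1] + 1
  hh
}

#' @rdname fir_design_highpass
#' @export
fir_design_bandpass_ls <- function(low, high, order, srate) {
  assert_that(low > 0 && high > low && high < srate / 2,
              "band edges must satisfy 0 < low < high < Nyquist")
  if (order %% 2 == 1) order <- order + 1L
  x <- (0:order) - order / 2
  f1 <- low / srate; f2 <- high / srate
  # truncated Fourier series of the ideal band-pass = unweighted LS optimum
  ifelse(x == 0, 2 * (f2 - f1),
         (sin(2 * pi * f2 * x) - sin(2 * pi * f1 * x)) / (pi * x))
}

#' Magnitude frequency response of an FIR filter
#' @param h filter coefficients.
#' @param freq frequencies (Hz) at which to evaluate.
#' @param srate sampling rate in Hz.
#' @return numeric vector of magnitude gains.
#' @export
fir_freq_response <- function(h, freq, srate) {
  n <- seq_along(h) - 1
  vapply(freq, function(f) Mod(sum(h * exp(-2i * pi * f / srate * n))), 0)
}

# Linear convolution via FFT, zero-padded to a 5-smooth length (avoids the
# near-quadratic behaviour of mixed-radix FFTs on awkward lengths).
fft_conv <- function(x, h) {
  L <- length(x) + length(h) - 1
  N <- stats::nextn(L, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(N - length(x))))
  H <- stats::fft(c(h, numeric(N - length(h))))
  Re(stats::fft(X * H, inverse = TRUE))[seq_len(L)] / N
}

# Centered FFT convolution with reflect padding of one filter length; for a
# symmetric (type I) FIR this realizes exactly zero phase. Output length = input.
fir_apply_centered <- function(x, h) {
  nh <- length(h)
  m <- (nh - 1) / 2
  pad <- min(nh, length(x) - 1)
  xe <- c(rev(x[2:(pad + 1)]), x, rev(x[(length(x) - pad):(length(x) - 1)]))
  y <- fft_conv(xe, h)
  y[(pad + m + 1):(pad + m + length(x))]
}

#' Zero-phase high-pass FIR filtering of a recording
#'
#' Removes slow drifts channel-wise with a Hamming windowed-sinc high-pass
#' (default 0.5 Hz cutoff, order 1128) applied with zero phase via centered
#' convolution after reflect padding. Output length equals input length.
#'
#' @param rec a [recording].
#' @param cutoff cutoff frequency in Hz (-6 dB point). Default 0.5.
#' @param order filter order. Default 1128.
#' @return filtered [recording].
#' @export
highpass_zero_phase <- function(rec, cutoff = 0.5, order = 1128) {
  assert_that(inherits(rec, "recording"), "rec must be a recording")
  assert_that(nrow(rec$data) > order, "recording shorter than filter order")
  h <- fir_design_highpass(cutoff, order, rec$srate)
  out <- apply(rec$data, 2, fir_apply_centered, h = h)
  recording(out, rec$srate, rec$channels, rec$units)
}

#' Two-way least-squares FIR band-pass for the ERP path
#'
#' Band-pass filters each channel between `low` and `high` Hz (default
#' 0.5-30 Hz) with a least-squares FIR applied forward and backward
#' (zero phase, squared magnitude response).
#'
#' @param rec a [recording].
#' @param low,high band edges in Hz.
#' @param order filter order. Default 1690.
#' @return filtered [recording].
#' @export
bandpass_erp <- function(rec, low = 0.5, high = 30, order = 1690) {
  assert_that(inherits(rec, "recording"), "rec must be a recording")
  assert_that(nrow(rec$data) > order, "recording shorter than filter order")
  h <- fir_design_bandpass_ls(low, high, order, rec$srate)
  out <- apply(rec$data, 2, function(x)
    rev(fir_apply_centered(rev(fir_apply_centered(x, h)), h)))
  recording(out, rec$srate, rec$channels, rec$units)
}

# Single biquad notch (second-order IIR) at f0 with the given -3 dB bandwidth.
biquad_notch_coef <- function(f0, bw, srate) {
  w0 <- 2 * pi * f0 / srate
  r <- 1 - pi * bw / srate              # pole radius for ~bw notch width
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  # normalize passband gain (evaluate midway between DC and the notch)
  g <- Mod(sum(b * exp(-1i * w0 / 2 * (0:2)))) /
       Mod(sum(a * exp(-1i * w0 / 2 * (0:2))))
  list(b = b / g, a = a)
}

iir_filter <- function(x, b, a) {
  y <- stats::filter(x, b, method = "convolution", sides = 1)
  y[is.na(y)] <- 0
  as.numeric(stats::filter(y, -a[-1], method = "recursive"))
}

# Zero-phase IIR filtering: reflect-pad, filter forward and backward.
iir_filtfilt <- function(x, b, a, pad_s, srate) {
  pad <- min(round(pad_s * srate), length(x) - 1)
  xe <- c(rev(x[2:(pad + 1)]), x, rev(x[(length(x) - pad):(length(x) - 1)]))
  y <- iir_filter(xe, b, a)
  y <- rev(iir_filter(rev(y), b, a))
  y[(pad + 1):(pad + length(x))]
}

#' Comb notch filter for power-line interference
#'
#' Suppresses `base_freq` (default 50 Hz) and its harmonics with a cascade of
#' zero-phase biquad notches (default notch bandwidth 1 Hz). Harmonics at or
#' above Nyquist are dropped with a warning.
#'
#' @param rec a [recording].
#' @param base_freq line frequency in Hz.
#' @param n_harmonics number of harmonics (including the fundamental).
#' @param bandwidth -3 dB notch width in Hz.
#' @return filtered [recording].
#' @export
comb_notch <- function(rec, base_freq = 50, n_harmonics = 4, bandwidth = 1) {
  assert_that(inherits(rec, "recording"), "rec must be a recording")
  freqs <- base_freq * seq_len(n_harmonics)
  keep <- freqs < rec$srate / 2
  if (!all(keep)) {
    warning("harmonics at or above Nyquist dropped: ",
            paste(freqs[!keep], collapse = ", "), " Hz")
    freqs <- freqs[keep]
  }
  assert_that(length(freqs) > 0, "no harmonic below Nyquist")
  out <- rec$data
  for (f0 in freqs) {
    co <- biquad_notch_coef(f0, bandwidth, rec$srate)
    out <- apply(out, 2, iir_filtfilt, b = co$b, a = co$a,
                 pad_s = 2, srate = rec$srate)
  }
  recording(out, rec$srate, rec$channels, rec$units)
}
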
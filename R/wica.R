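# --- FastICA (deflation, logcosh contrast) -------------------------------
# Minimal one-unit fixed-point ICA with Gram-Schmidt deflation; the symmetric
# variant oscillates on the near-Gaussian subspace of typical EEG, while the
# heavy-tailed artifact components converge in a few iterations here.
# Deterministic (fixed internal init seed).
fastica_decompose <- function(X, n_components = ncol(X), max_iter = 500,
                              tol = 1e-4) {
  n <- nrow(X); p <- ncol(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  ev <- eigen(stats::cov(Xc), symmetric = TRUE)
  keep <- seq_len(n_components)
  K <- ev$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(pmax(ev$values[keep], 1e-12)), n_components)
  Z <- Xc %*% K                                   # whitened, n x k
  W <- matrix(0, n_components, n_components)
  converged <- TRUE
  with_seed(20240101, {
    for (ci in seq_len(n_components)) {
      w <- stats::rnorm(n_components)
      ortho <- function(v) {
        if (ci > 1) {
          Wp <- W[seq_len(ci - 1), , drop = FALSE]
          v <- v - as.numeric(t(Wp) %*% (Wp %*% v))
        }
        v / sqrt(sum(v^2))
      }
      w <- ortho(w)
      ok <- FALSE
      for (it in seq_len(max_iter)) {
        g <- tanh(as.numeric(Z %*% w))
        w1 <- ortho(colMeans(Z * g) - mean(1 - g^2) * w)
        d <- abs(abs(sum(w1 * w)) - 1)
        w <- w1
        if (d < tol) { ok <- TRUE; break }
      }
      if (!ok) converged <- FALSE
      W[ci, ] <- w
    }
  })
  S <- Z %*% t(W)                                 # sources, unit variance
  # mixing matrix via least squares: Xc ~ S A^T
  A <- t(qr.solve(S, Xc))                          # p x k
  list(S = S, A = A, center = ctr, converged = converged)
}

# --- Periodic orthogonal DWT, Daubechies-4 -------------------------------
DB4_H <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
DB4_G <- rev(DB4_H) * c(1, -1, 1, -1)

dwt_step <- function(x, h, g) {
  n <- length(x)
  k <- seq(0, n / 2 - 1)
  idx <- outer(2 * k, seq_along(h) - 1, "+") %% n + 1
  list(a = as.numeric(matrix(x[idx], ncol = length(h)) %*% h),
       d = as.numeric(matrix(x[idx], ncol = length(g)) %*% g))
}

idwt_step <- function(a, d, h, g) {
  n <- 2 * length(a)
  x <- numeric(n)
  for (m in seq_along(h)) {
    pos <- (outer(2 * (seq_along(a) - 1), m - 1, "+") %% n) + 1
    x[pos] <- x[pos] + a * h[m] + d * g[m]
  }
  x
}

#' Periodic discrete wavelet transform (Daubechies-4)
#'
#' Orthogonal periodic DWT used by the wavelet-enhanced ICA cleaning step.
#' The signal is reflect-padded to a multiple of `2^levels` internally.
#'
#' @param x numeric vector.
#' @param levels decomposition depth (default 5).
#' @return list with `approx`, `details` (list, finest first), and padding
#'   bookkeeping; invert with [idwt_db4()].
#' @export
dwt_db4 <- function(x, levels = 5) {
  n0 <- length(x)
  blk <- 2^levels
  pad <- (blk - n0 %% blk) %% blk
  if (pad > 0) x <- c(x, rev(x)[seq_len(pad)])
  details <- vector("list", levels)
  a <- x
  for (l in seq_len(levels)) {
    st <- dwt_step(a, DB4_H, DB4_G)
    details[[l]] <- st$d
    a <- st$a
  }
  list(approx = a, details = details, n = n0, pad = pad, levels = levels)
}

#' @rdname dwt_db4
#' @param w a decomposition from [dwt_db4()].
#' @export
idwt_db4 <- function(w) {
  a <- w$approx
  for (l in rev(seq_len(w$levels))) a <- idwt_step(a, w$details[[l]], DB4_H, DB4_G)
  a[seq_len(w$n)]
}

# Universal threshold from the finest detail level (MAD estimate of sigma).
universal_threshold <- function(w, factor = 1) {
  sig <- stats::mad(w$details[[1]], constant = 1.4826)
  factor * sig * sqrt(2 * log(w$n))
}

# Zero all wavelet coefficients (details and approximation) whose magnitude
# exceeds thr; sub-threshold structure is retained.
wavelet_suppress <- function(x, thr, levels = 5) {
  w <- dwt_db4(x, levels)
  nz <- 0
  for (l in seq_len(levels)) {
    hit <- abs(w$details[[l]]) > thr
    w$details[[l]][hit] <- 0
    nz <- nz + sum(hit)
  }
  hit <- abs(w$approx) > thr
  w$approx[hit] <- 0
  nz <- nz + sum(hit)
  list(x = idwt_db4(w), n_zeroed = nz)
}

excess_kurtosis <- function(x) mean((x - mean(x))^4) / stats::var(x)^2 - 3

#' Wavelet-enhanced ICA artifact removal
#'
#' Decomposes the recording with FastICA, wavelet-transforms the selected
#' artifact components, zeroes coefficients whose magnitude exceeds the
#' (scaled universal) threshold, inverse-transforms and re-mixes. Unlike full
#' component removal, sub-threshold neural structure inside artifact
#' components is retained. By default components are selected automatically:
#' excess kurtosis above `kurtosis_cutoff` (blinks are heavy-tailed) with the
#' frontal channel carrying the dominant loading; a manual `components` list
#' overrides this. If ICA does not converge the input is returned unmodified,
#' flagged via `attr(, "uncleaned")`, with a warning.
#'
#' @param rec a [recording] with at least 2 channels.
#' @param components integer indices of components to clean, or `NULL` for
#'   automatic selection.
#' @param kurtosis_cutoff selection cutoff on excess kurtosis (default 5).
#' @param threshold_factor scaling of the universal wavelet threshold.
#' @param levels wavelet decomposition depth (default 5).
#' @param frontal_channel channel whose loading must dominate for automatic
#'   selection (default "Fz"; ignored when absent from the montage).
#' @return cleaned [recording]; `attr(, "wica_report")` holds the selected
#'   components, threshold and number of zeroed coefficients.
#' @export
wica_clean <- function(rec, components = NULL, kurtosis_cutoff = 5,
                       threshold_factor = 1, levels = 5,
                       frontal_channel = "Fz") {
  assert_that(inherits(rec, "recording"), "rec must be a recording")
  assert_that(ncol(rec$data) >= 2, "wICA needs at least 2 channels")
  assert_that(all(is.finite(rec$data)), "signal must be finite")
  if (!is.null(components) && length(components) == 0) return(rec)
  ica <- fastica_decompose(rec$data)
  if (!ica$converged) {
    warning("ICA did not converge; returning input unmodified")
    out <- rec
    attr(out, "uncleaned") <- TRUE
    return(out)
  }
  k <- ncol(ica$S)
  if (is.null(components)) {
    kur <- apply(ica$S, 2, excess_kurtosis)
    fi <- match(frontal_channel, rec$channels)
    frontal_dom <- if (is.na(fi)) rep(TRUE, k)
      else apply(abs(ica$A), 2, which.max) == fi
    components <- which(kur > kurtosis_cutoff & frontal_dom)
  }
  report <- list(selected = components, threshold = NA_real_, n_zeroed = 0L)
  S <- ica$S
  for (ci in components) {
    w <- dwt_db4(S[, ci], levels)
    thr <- universal_threshold(w, threshold_factor)
    sup <- wavelet_suppress(S[, ci], thr, levels)
    S[, ci] <- sup$x
    report$threshold <- thr
    report$n_zeroed <- report$n_zeroed + sup$n_zeroed
  }
  clean <- S %*% t(ica$A)
  clean <- sweep(clean, 2, ica$center, "+")
  out <- recording(clean, rec$srate, rec$channels, rec$units)
  attr(out, "wica_report") <- report
  out
}
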
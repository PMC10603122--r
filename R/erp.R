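#' Epoch a recording around target events
#'
#' Cuts one trial per target event over `window` seconds relative to onset
#' (default -0.2 to 0.8 s) from a band-passed recording, subtracting the
#' mean of the pre-stimulus interval per trial and channel (baseline
#' correction). Events whose window exceeds the recording are dropped and
#' logged in `attr(, "dropped")`.
#'
#' @param rec a [recording] (ERP path: band-passed 0.5-30 Hz).
#' @param events event stream; only rows with `label == event_label` are used.
#' @param window length-2 numeric, epoch window in seconds relative to onset.
#' @param event_label which events to epoch (default "target").
#' @param baseline logical; subtract the pre-stimulus mean (default TRUE).
#' @return object of class `epoch_set`: `data` (trials x channels x time
#'   array, microvolts), `time` (s relative to onset), `channels`,
#'   `retained` (logical rejection mask, all TRUE initially).
#' @export
epoch <- function(rec, events, window = c(-0.2, 0.8),
                  event_label = "target", baseline = TRUE) {
  assert_that(inherits(rec, "recording"), "rec must be a recording")
  assert_that(window[1] < 0 && window[2] > 0, "window must straddle onset")
  srate <- rec$srate
  onsets <- events$onset_s[events$label == event_label]
  i_rel <- round(window[1] * srate):round(window[2] * srate)
  t_rel <- i_rel / srate
  n <- nrow(rec$data)
  dropped <- onsets[round(onsets * srate) + 1 + i_rel[1] < 1 |
                      round(onsets * srate) + 1 + i_rel[length(i_rel)] > n]
  onsets <- setdiff(onsets, dropped)
  assert_that(length(onsets) > 0, "no event with a complete epoch window")
  arr <- array(NA_real_, c(length(onsets), ncol(rec$data), length(i_rel)))
  pre <- t_rel < 0
  for (e in seq_along(onsets)) {
    idx <- round(onsets[e] * srate) + 1 + i_rel
    seg <- t(rec$data[idx, , drop = FALSE])          # channels x time
    if (baseline) seg <- seg - rowMeans(seg[, pre, drop = FALSE])
    arr[e, , ] <- seg
  }
  out <- structure(list(data = arr, time = t_rel, channels = rec$channels,
                        retained = rep(TRUE, length(onsets)),
                        onsets = onsets),
                   class = "epoch_set")
  attr(out, "dropped") <- dropped
  out
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trial(s) (%d retained), %d channel(s), %.2f..%.2f s\n",
              dim(x$data)[1], sum(x$retained), dim(x$data)[2],
              min(x$time), max(x$time)))
  invisible(x)
}

#' Reject trials exceeding an amplitude threshold
#'
#' Marks a trial rejected when its absolute amplitude exceeds `threshold`
#' (default 100 microvolts) at any channel or time point. Idempotent and
#' order-independent; the mask is combined with any previous rejections.
#'
#' @param epochs an [epoch()] set.
#' @param threshold amplitude bound in microvolts (> 0).
#' @return the `epoch_set` with an updated `retained` mask.
#' @export
reject_amplitude <- function(epochs, threshold = 100) {
  assert_that(threshold > 0, "threshold must be positive")
  mx <- apply(abs(epochs$data), 1, max)
  epochs$retained <- epochs$retained & (mx <= threshold)
  epochs
}

#' Per-subject average ERP waveforms
#'
#' Average of the retained trials of one subject's epoch set, per channel.
#'
#' @param epochs an [epoch()] set.
#' @return matrix channels x time; errors if no trial survives rejection.
#' @export
subject_average <- function(epochs) {
  keep <- which(epochs$retained)
  assert_that(length(keep) > 0,
              "no retained trials; relax the rejection threshold")
  out <- apply(epochs$data[keep, , , drop = FALSE], c(2, 3), mean)
  dimnames(out) <- list(epochs$channels, NULL)
  out
}

#' Grand-average ERP across subjects
#'
#' Subject averages first, then an unweighted average across subjects.
#' Subjects with zero retained trials are excluded with a message.
#'
#' @param epoch_list list of [epoch()] sets, one per subject.
#' @return list: `waveforms` (matrix channels x time), `time`, `channels`,
#'   `n_subjects`.
#' @export
grand_average <- function(epoch_list) {
  assert_that(length(epoch_list) >= 1, "need at least one subject")
  subj <- list()
  for (i in seq_along(epoch_list)) {
    if (!any(epoch_list[[i]]$retained)) {
      message(sprintf("subject %d excluded: no retained trials", i))
      next
    }
    subj[[length(subj) + 1]] <- subject_average(epoch_list[[i]])
  }
  assert_that(length(subj) > 0, "no subject with retained trials")
  wf <- Reduce(`+`, subj) / length(subj)
  list(waveforms = wf, time = epoch_list[[1]]$time,
       channels = epoch_list[[1]]$channels, n_subjects = length(subj))
}

#' Onset latency of an ERP component
#'
#' Earliest time inside `component_window` at which the waveform magnitude
#' departs from baseline -- crossing `criterion` times the pre-stimulus SD --
#' and stays departed for at least `sustain` seconds. Returns `NA` (with a
#' message) when the criterion is never met, e.g. on a flat waveform.
#'
#' @param amplitude numeric waveform (one channel).
#' @param time time axis in seconds (0 = stimulus onset).
#' @param component_window length-2 numeric search window in seconds.
#' @param criterion multiple of the pre-stimulus SD (default 2); if the
#'   pre-stimulus SD is zero, any departure from zero counts.
#' @param sustain minimum duration above criterion in seconds (default 0.010).
#' @return onset time in seconds, or `NA_real_`.
#' @export
onset_latency <- function(amplitude, time, component_window,
                          criterion = 2, sustain = 0.010) {
  assert_that(min(time) <= component_window[1] &&
                max(time) >= component_window[2],
              "waveform does not cover the component window")
  dt <- stats::median(diff(time))
  pre_sd <- stats::sd(amplitude[time < 0])
  thr <- if (is.finite(pre_sd) && pre_sd > 0) criterion * pre_sd else
    .Machine$double.eps^0.5
  need <- max(1L, round(sustain / dt))
  idx <- which(time >= component_window[1] & time <= component_window[2])
  above <- abs(amplitude) > thr
  for (i in idx) {
    run <- i:min(i + need - 1, length(above))
    if (length(run) >= need && all(above[run])) return(time[i])
  }
  message("onset criterion never met; returning NA")
  NA_real_
}

# BH adjustment helper with the family across the supplied vector.
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Time-point-wise phase effect on ERP amplitudes (mixed model)
#'
#' At every time sample fits amplitude ~ phase + (1 | subject) over the
#' paired before/after subject-average waveforms (phase coded 0 = before,
#' 1 = after), REML, with singular fits falling back to OLS (flagged). Raw
#' p-values are Benjamini-Hochberg corrected across time samples (one family
#' per call, i.e. per channel).
#'
#' @param before,after matrices subjects x time of subject-average amplitudes
#'   at one channel, aligned rows.
#' @param time optional time axis (defaults to sample index).
#' @return data.frame per time sample: `time`, `estimate` (microvolts),
#'   `std_effect` (estimate / residual SD), `p`, `p_adj`, `significant`
#'   (at 0.05 after BH), `fallback`.
#' @export
fit_phase_lme <- function(before, after, time = NULL) {
  assert_that(all(dim(before) == dim(after)),
              "before/after must be subjects x time with equal shape")
  ns <- nrow(before); nt <- ncol(before)
  time <- time %||% seq_len(nt)
  subj <- factor(rep(seq_len(ns), 2))
  phase <- rep(c(0, 1), each = ns)
  res <- vector("list", nt)
  for (i in seq_len(nt)) {
    d <- data.frame(amp = c(before[, i], after[, i]), phase = phase)
    f <- fit_lme_term(amp ~ phase, d, subj, "phase")
    res[[i]] <- data.frame(time = time[i], estimate = f$estimate,
                           std_effect = if (f$sigma > 0)
                             f$estimate / f$sigma else 0,
                           p = f$p, fallback = f$fallback)
  }
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- !is.na(out$p_adj) & out$p_adj < 0.05
  out
}

#' Time-point-wise questionnaire-item effect on post-lecture ERP (mixed model)
#'
#' Per time sample fits the post-lecture amplitude on the pre-lecture
#' amplitude (controlling regression to the mean), the item score(s) and a
#' by-subject random intercept:
#' model "bmis": after ~ before + item_before + item_after + (1 | subject);
#' model "zef":  after ~ before + item_after + (1 | subject).
#' The after-score fixed effect divided by the residual SD is the
#' standardized effect; BH correction runs across time samples (family per
#' channel x model x item). Item scores must already be z-normalized across
#' all subjects and conditions (see [normalize_item_scores()]); constant
#' scores yield missing effects with a warning.
#'
#' @param after,before matrices observations x time (observations are
#'   subject or subject-channel units; `subject` gives the grouping).
#' @param item_after,item_before numeric score vectors, length = rows.
#' @param subject grouping vector, length = rows.
#' @param model "bmis" (uses both scores) or "zef" (after only).
#' @param time optional time axis.
#' @return data.frame per time sample: `time`, `estimate`, `std_effect`,
#'   `p`, `p_adj`, `significant`, `fallback`.
#' @export
fit_item_lme <- function(after, before, item_after, subject,
                         item_before = NULL,
                         model = c("bmis", "zef"), time = NULL) {
  model <- match.arg(model)
  assert_that(all(dim(after) == dim(before)), "after/before shapes differ")
  assert_that(length(item_after) == nrow(after), "item_after length mismatch")
  if (model == "bmis")
    assert_that(!is.null(item_before) && length(item_before) == nrow(after),
                "bmis model needs item_before")
  if (stats::sd(item_after) == 0) {
    warning("constant item scores; effect undefined")
    nt <- ncol(after)
    return(data.frame(time = (time %||% seq_len(nt)), estimate = NA_real_,
                      std_effect = NA_real_, p = NA_real_, p_adj = NA_real_,
                      significant = FALSE, fallback = FALSE))
  }
  nt <- ncol(after)
  time <- time %||% seq_len(nt)
  res <- vector("list", nt)
  for (i in seq_len(nt)) {
    d <- data.frame(y = after[, i], x = before[, i], ia = item_after)
    if (model == "bmis") {
      d$ib <- item_before
      f <- fit_lme_term(y ~ x + ib + ia, d, subject, "ia")
    } else {
      f <- fit_lme_term(y ~ x + ia, d, subject, "ia")
    }
    res[[i]] <- data.frame(time = time[i], estimate = f$estimate,
                           std_effect = if (is.finite(f$sigma) && f$sigma > 0)
                             f$estimate / f$sigma else NA_real_,
                           p = f$p, fallback = f$fallback)
  }
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- !is.na(out$p_adj) & out$p_adj < 0.05
  out
}

#' z-normalize item scores across all subjects and conditions
#'
#' @param x numeric vector of raw item scores pooled over subjects and
#'   conditions.
#' @return numeric vector with mean 0 and SD 1 (or all zeros if constant).
#' @export
normalize_item_scores <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}
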
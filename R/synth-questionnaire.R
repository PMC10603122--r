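#' Item metadata for the mood and fatigue questionnaires
#'
#' `bmis_items()`: the 16 mood adjectives rated 1-4, split 8 pleasant /
#' 8 unpleasant following the standard instrument. `zef_items()`: the 18
#' fatigue items rated 1-5; five dimensions of three items each (general,
#' visual, social, motivational, emotional) plus three unassigned items that
#' contribute only to the overall mean.
#'
#' @return data.frame with `item` and `polarity` (BMIS) or `dimension` (ZEF).
#' @export
bmis_items <- function() {
  data.frame(
    item = c("lively", "happy", "caring", "content", "peppy", "calm",
             "loving", "active",
             "sad", "tired", "gloomy", "jittery", "drowsy", "grouchy",
             "nervous", "fed_up"),
    polarity = rep(c("pleasant", "unpleasant"), each = 8))
}

#' @rdname bmis_items
#' @export
zef_items <- function() {
  data.frame(
    item = sprintf("zef%02d", 1:18),
    dimension = c(rep(c("general", "visual", "social", "motivational",
                        "emotional"), each = 3), rep("unassigned", 3)))
}

# Ordinal response via a thresholded latent-variable model:
# score = 1 + #(loading * latent + noise > thresholds).
ordinal_response <- function(latent, loading, thresholds) {
  z <- loading * latent + stats::rnorm(length(latent))
  as.integer(1 + rowSums(outer(z, thresholds, ">")))
}

#' Generate questionnaire item tables coupled to a latent fatigue variable
#'
#' Per subject and condition a latent fatigue value is drawn
#' (`N(shift, 1)` with `shift = latent_fatigue_effect` in the
#' videoconference condition, 0 otherwise, around a persistent subject
#' intercept). Item responses follow a thresholded latent-variable model:
#' fatigue-congruent items (all ZEF items, unpleasant BMIS adjectives) load
#' positively, pleasant-mood items negatively. BMIS is produced before and
#' after the lecture (fatigue acts only on "after"); ZEF after only.
#'
#' @param config a [sim_config()]; both conditions are generated so that
#'   paired comparisons are possible (the config's own `condition` field is
#'   ignored here).
#' @param latent_fatigue optional matrix (n_subjects x 2, columns
#'   "videoconference", "face_to_face") of latent values overriding the
#'   internal draw.
#' @param loading absolute item loading on the latent variable (default 0.8).
#' @param bmis_thresholds,zef_thresholds latent-scale cutpoints (3 for the
#'   1-4 BMIS range, 4 for the 1-5 ZEF range).
#' @return list: `bmis` (subject, condition, phase, 16 item columns), `zef`
#'   (subject, condition, 18 item columns), `truth` (latent values and the
#'   injected effect).
#' @export
generate_questionnaires <- function(config, latent_fatigue = NULL,
                                    loading = 0.8,
                                    bmis_thresholds = c(-0.8, 0, 0.8),
                                    zef_thresholds = c(-1.2, -0.4, 0.4, 1.2)) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config")
  ns <- config$n_subjects
  conds <- c("videoconference", "face_to_face")
  with_seed(child_seed(config$seed, "quest"), {
    if (is.null(latent_fatigue)) {
      u <- stats::rnorm(ns, 0, 0.7)            # persistent subject trait
      latent_fatigue <- vapply(conds, function(cc)
        u + stats::rnorm(ns, 0, 0.7) +
          if (cc == "videoconference") config$latent_fatigue_effect else 0,
        numeric(ns))
      latent_fatigue <- matrix(latent_fatigue, nrow = ns,
                               dimnames = list(NULL, conds))
    }
    assert_that(all(is.finite(latent_fatigue)), "latent values must be finite")
    bm <- bmis_items(); zf <- zef_items()
    bmis_rows <- list(); zef_rows <- list()
    for (cc in conds) {
      lat_after <- latent_fatigue[, cc]
      lat_before <- stats::rnorm(ns, 0, 0.7)   # pre-lecture mood, no effect
      for (phase in c("before", "after")) {
        lat <- if (phase == "after") lat_after else lat_before
        sc <- vapply(seq_len(nrow(bm)), function(k) {
          lam <- if (bm$polarity[k] == "pleasant") -loading else loading
          ordinal_response(lat, lam, bmis_thresholds)
        }, integer(ns))
        sc <- matrix(sc, nrow = ns, dimnames = list(NULL, bm$item))
        bmis_rows[[paste(cc, phase)]] <-
          data.frame(subject = seq_len(ns), condition = cc, phase = phase, sc)
      }
      sc <- vapply(seq_len(nrow(zf)), function(k)
        ordinal_response(lat_after, loading, zef_thresholds), integer(ns))
      sc <- matrix(sc, nrow = ns, dimnames = list(NULL, zf$item))
      zef_rows[[cc]] <-
        data.frame(subject = seq_len(ns), condition = cc, sc)
    }
    list(bmis = do.call(rbind, c(bmis_rows, make.row.names = FALSE)),
         zef = do.call(rbind, c(zef_rows, make.row.names = FALSE)),
         truth = list(latent = latent_fatigue,
                      effect = config$latent_fatigue_effect,
                      loading = loading))
  })
}
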
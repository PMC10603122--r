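PIPELINE_STAGES <- c("simulate", "features", "hrv", "erp", "scores", "link",
                     "report")

FIXTURE_PROFILES <- c("null", "fatigue_injected", "erp_only", "hrv_only")

# Configs for the two conditions of a fixture profile.
fixture_configs <- function(profile, seed, n_subjects, lecture_duration) {
  assert_that(profile %in% FIXTURE_PROFILES,
              paste("unknown profile; available:",
                    paste(FIXTURE_PROFILES, collapse = ", ")))
  null_overrides <- list(band_drift = list(), hr_slope = 0,
                         rr_target = list(index = "none"),
                         erp_after_gain = 1, latent_fatigue_effect = 0)
  overrides <- switch(profile,
    null = null_overrides,
    fatigue_injected = list(),
    erp_only = null_overrides[c("band_drift", "hr_slope", "rr_target")],
    hrv_only = null_overrides[c("band_drift", "erp_after_gain",
                                "latent_fatigue_effect")])
  lapply(c("videoconference", "face_to_face"), function(cond)
    do.call(sim_config, c(list(n_subjects = n_subjects,
                               lecture_duration = lecture_duration,
                               condition = cond, seed = seed), overrides)))
}

#' Build a miniature deterministic dataset for testing
#'
#' Generates a small in-memory dataset (default 3 subjects, 6-min lecture,
#' both conditions) with ground truth, for CI-scale pipeline tests. Profiles:
#' "null" (all effects zero), "fatigue_injected" (the default
#' videoconference signatures), "erp_only", "hrv_only".
#'
#' @param profile one of the profiles above.
#' @param seed integer seed (fully determines the fixture).
#' @param n_subjects number of subjects (default 3).
#' @param lecture_duration seconds (default 360; two 3-min windows).
#' @param n_events oddball events per run (default 60).
#' @return nested list: `configs`, per-condition `subjects` holding `eeg`,
#'   `rr`, `ecg`, ground truths, `questionnaires`, `events`.
#' @export
make_fixture <- function(profile = "fatigue_injected", seed = 1L,
                         n_subjects = 3, lecture_duration = 360,
                         n_events = 60) {
  cfgs <- fixture_configs(profile, seed, n_subjects, lecture_duration)
  names(cfgs) <- vapply(cfgs, `[[`, "", "condition")
  out <- list(profile = profile, seed = seed, configs = cfgs)
  out$questionnaires <- generate_questionnaires(cfgs[[1]])
  out$events <- generate_oddball_sequence(n_events, 0.1,
                                          seed = child_seed(seed, "oddball"))
  for (cond in names(cfgs)) {
    cfg <- cfgs[[cond]]
    subs <- lapply(seq_len(n_subjects), function(s) {
      eeg <- generate_continuous_eeg(cfg, s)
      heart <- generate_rr_and_ecg(cfg, s)
      list(eeg = eeg$recording, eeg_truth = eeg$ground_truth,
           rr = heart$rr, ecg = heart$ecg, ecg_truth = heart$ground_truth)
    })
    out[[cond]] <- subs
  }
  out
}

read_manifest <- function(out_dir) {
  p <- file.path(out_dir, "manifest.json")
  if (file.exists(p)) jsonlite::read_json(p) else list()
}

append_manifest <- function(out_dir, stage, seed, info = list()) {
  m <- read_manifest(out_dir)
  m[[length(m) + 1]] <- c(list(stage = stage, seed = seed,
                               time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                          info)
  jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

require_upstream <- function(out_dir, file, stage_needed) {
  assert_that(file.exists(file.path(out_dir, file)),
              sprintf("missing artifact '%s'; run stage '%s' first",
                      file, stage_needed))
}

#' Run one pipeline stage against an output directory
#'
#' Stages: "simulate" (write EDF recordings, event tables, questionnaire
#' CSVs, ground truth), "features" (preprocess EEG, windowed normalized band
#' powers and Theta/Beta ratio), "hrv" (Pan-Tompkins, windowed HRV indices),
#' "erp" (oddball epoching, rejection, grand averages), "scores"
#' (questionnaire scoring and paired tests), "link" (trends and averaged
#' condition tests), "report" (plain-text summary). Each stage checks its
#' upstream artifacts and appends to `manifest.json`. Per-subject failures
#' (e.g. a corrupted EDF) are logged and skipped, not fatal.
#'
#' @param stage stage name.
#' @param out_dir artifact directory (created if needed).
#' @param profile fixture profile (simulate stage).
#' @param seed integer seed (simulate stage).
#' @param n_subjects,lecture_duration,n_events simulate-stage size knobs.
#' @param wica apply wavelet-enhanced ICA during "features" (default TRUE).
#' @return invisibly, a list of the artifacts written.
#' @export
run_stage <- function(stage, out_dir, profile = "fatigue_injected", seed = 1L,
                      n_subjects = 3, lecture_duration = 360, n_events = 60,
                      wica = TRUE) {
  assert_that(stage %in% PIPELINE_STAGES,
              paste("unknown stage; available:",
                    paste(PIPELINE_STAGES, collapse = ", ")))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fn <- get(paste0("stage_", stage), mode = "function")
  arts <- fn(out_dir, profile = profile, seed = seed,
             n_subjects = n_subjects, lecture_duration = lecture_duration,
             n_events = n_events, wica = wica)
  append_manifest(out_dir, stage, seed, list(artifacts = unname(arts)))
  invisible(arts)
}

#' Run the full pipeline
#'
#' Convenience wrapper executing every stage of [run_stage()] in order.
#'
#' @inheritParams run_stage
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(out_dir, profile = "fatigue_injected", seed = 1L,
                         n_subjects = 3, lecture_duration = 360,
                         n_events = 60, wica = TRUE) {
  for (st in PIPELINE_STAGES)
    run_stage(st, out_dir, profile, seed, n_subjects, lecture_duration,
              n_events, wica)
  invisible(out_dir)
}

subject_conditions <- function(out_dir) {
  cfg <- jsonlite::read_json(file.path(out_dir, "run_config.json"),
                             simplifyVector = TRUE)
  expand.grid(subject = seq_len(cfg$n_subjects),
              condition = c("videoconference", "face_to_face"),
              stringsAsFactors = FALSE)
}

stage_simulate <- function(out_dir, profile, seed, n_subjects,
                           lecture_duration, n_events, ...) {
  cfgs <- fixture_configs(profile, seed, n_subjects, lecture_duration)
  names(cfgs) <- vapply(cfgs, `[[`, "", "condition")
  jsonlite::write_json(list(profile = profile, seed = seed,
                            n_subjects = n_subjects,
                            lecture_duration = lecture_duration,
                            n_events = n_events),
                       file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE)
  arts <- "run_config.json"
  truth <- list()
  ev <- generate_oddball_sequence(n_events, 0.1,
                                  seed = child_seed(seed, "oddball"))
  write_events(ev, file.path(out_dir, "events.tsv"))
  arts <- c(arts, "events.tsv")
  for (cond in names(cfgs)) {
    cfg <- cfgs[[cond]]
    for (s in seq_len(n_subjects)) {
      tag <- sprintf("s%d_%s", s, cond)
      eeg <- generate_continuous_eeg(cfg, s)
      write_edf(eeg$recording, file.path(out_dir, sprintf("eeg_%s.edf", tag)))
      heart <- generate_rr_and_ecg(cfg, s)
      write_edf(heart$ecg, file.path(out_dir, sprintf("ecg_%s.edf", tag)))
      # oddball runs before/after, ERP amplitude modulated after the lecture
      for (phase in c("before", "after")) {
        g <- if (phase == "after") cfg$erp_after_gain else 1
        ocfg <- sim_config(n_subjects = n_subjects,
                           lecture_duration = max(ev$onset_s) + 2,
                           condition = cond,
                           band_drift = list(), hr_slope = 0,
                           rr_target = list(index = "none"),
                           latent_fatigue_effect = 0,
                           seed = child_seed(seed, "odd", s, phase))
        orec <- generate_continuous_eeg(ocfg, s)$recording
        orec <- embed_erp(orec, ev, cfg$erp_template, gain = g)
        write_edf(orec, file.path(out_dir, sprintf("odd_%s_%s.edf", tag, phase)))
      }
      truth[[tag]] <- list(band_slopes = eeg$ground_truth$band_slopes,
                           hr_slope = heart$ground_truth$hr_slope,
                           rr_target = heart$ground_truth$rr_target)
      arts <- c(arts, sprintf("eeg_%s.edf", tag), sprintf("ecg_%s.edf", tag))
    }
  }
  q <- generate_questionnaires(cfgs[[1]])
  utils::write.csv(q$bmis, file.path(out_dir, "bmis.csv"), row.names = FALSE)
  utils::write.csv(q$zef, file.path(out_dir, "zef.csv"), row.names = FALSE)
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  c(arts, "bmis.csv", "zef.csv", "ground_truth.json")
}

stage_features <- function(out_dir, wica, ...) {
  require_upstream(out_dir, "run_config.json", "simulate")
  sc <- subject_conditions(out_dir)
  rows <- list()
  for (i in seq_len(nrow(sc))) {
    tag <- sprintf("s%d_%s", sc$subject[i], sc$condition[i])
    res <- tryCatch({
      rec <- read_edf(file.path(out_dir, sprintf("eeg_%s.edf", tag)))
      rec <- highpass_zero_phase(rec)
      rec <- comb_notch(rec)
      if (wica) rec <- wica_clean(rec)
      bp <- normalized_band_powers(rec)
      tb <- theta_beta_ratio(bp)
      cbind(subject = sc$subject[i], condition = sc$condition[i],
            rbind(bp, tb))
    }, error = function(e) {
      message(sprintf("features: subject %s failed (%s); skipping",
                      tag, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[tag]] <- res
  }
  assert_that(length(rows) > 0, "features stage produced no output")
  utils::write.csv(do.call(rbind, rows), file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  "features.csv"
}

stage_hrv <- function(out_dir, ...) {
  require_upstream(out_dir, "run_config.json", "simulate")
  sc <- subject_conditions(out_dir)
  rows <- list()
  for (i in seq_len(nrow(sc))) {
    tag <- sprintf("s%d_%s", sc$subject[i], sc$condition[i])
    res <- tryCatch({
      rec <- read_edf(file.path(out_dir, sprintf("ecg_%s.edf", tag)))
      rr <- clean_rr(pan_tompkins(rec))
      cbind(subject = sc$subject[i], condition = sc$condition[i],
            windowed_hrv(rr, duration = rec_duration(rec)))
    }, error = function(e) {
      message(sprintf("hrv: subject %s failed (%s); skipping",
                      tag, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[tag]] <- res
  }
  assert_that(length(rows) > 0, "hrv stage produced no output")
  utils::write.csv(do.call(rbind, rows), file.path(out_dir, "hrv.csv"),
                   row.names = FALSE)
  "hrv.csv"
}

stage_erp <- function(out_dir, ...) {
  require_upstream(out_dir, "run_config.json", "simulate")
  require_upstream(out_dir, "events.tsv", "simulate")
  sc <- subject_conditions(out_dir)
  ev <- read_events(file.path(out_dir, "events.tsv"))
  arts <- character(0)
  for (cond in unique(sc$condition)) {
    for (phase in c("before", "after")) {
      eps <- list()
      for (s in unique(sc$subject)) {
        f <- file.path(out_dir, sprintf("odd_s%d_%s_%s.edf", s, cond, phase))
        res <- tryCatch({
          rec <- bandpass_erp(read_edf(f))
          reject_amplitude(epoch(rec, ev))
        }, error = function(e) {
          message(sprintf("erp: %s failed (%s); skipping", basename(f),
                          conditionMessage(e)))
          NULL
        })
        if (!is.null(res)) eps[[length(eps) + 1]] <- res
      }
      ga <- grand_average(eps)
      out <- data.frame(time_s = ga$time, t(ga$waveforms))
      names(out) <- c("time_s", ga$channels)
      fn <- sprintf("erp_grand_average_%s_%s.csv", cond, phase)
      utils::write.csv(out, file.path(out_dir, fn), row.names = FALSE)
      arts <- c(arts, fn)
    }
  }
  arts
}

stage_scores <- function(out_dir, ...) {
  require_upstream(out_dir, "bmis.csv", "simulate")
  bmis <- utils::read.csv(file.path(out_dir, "bmis.csv"))
  zef <- utils::read.csv(file.path(out_dir, "zef.csv"))
  bs <- do.call(rbind, lapply(seq_len(nrow(bmis)), function(i) {
    s <- bmis_scores(bmis[i, bmis_items()$item])
    data.frame(subject = bmis$subject[i], condition = bmis$condition[i],
               phase = bmis$phase[i], positive = s$positive,
               negative = s$negative, overall = s$overall)
  }))
  zs <- do.call(rbind, lapply(seq_len(nrow(zef)), function(i) {
    s <- zef_scores(zef[i, zef_items()$item])
    data.frame(subject = zef$subject[i], condition = zef$condition[i],
               overall = s$overall, t(s$dimensions))
  }))
  utils::write.csv(bs, file.path(out_dir, "bmis_scores.csv"), row.names = FALSE)
  utils::write.csv(zs, file.path(out_dir, "zef_scores.csv"), row.names = FALSE)
  vc <- zs[zs$condition == "videoconference", ]
  ff <- zs[zs$condition == "face_to_face", ]
  vc <- vc[order(vc$subject), ]; ff <- ff[order(ff$subject), ]
  tst <- paired_condition_tests(as.matrix(vc[, -(1:2)]),
                                as.matrix(ff[, -(1:2)]),
                                items = colnames(vc)[-(1:2)])
  utils::write.csv(tst, file.path(out_dir, "zef_condition_tests.csv"),
                   row.names = FALSE)
  c("bmis_scores.csv", "zef_scores.csv", "zef_condition_tests.csv")
}

stage_link <- function(out_dir, ...) {
  require_upstream(out_dir, "features.csv", "features")
  require_upstream(out_dir, "hrv.csv", "hrv")
  feats <- utils::read.csv(file.path(out_dir, "features.csv"))
  hrv <- utils::read.csv(file.path(out_dir, "hrv.csv"))
  trends <- list()
  for (cond in unique(feats$condition)) {
    for (ch in unique(feats$channel)) {
      for (bd in unique(feats$band)) {
        sub <- feats[feats$condition == cond & feats$channel == ch &
                       feats$band == bd, ]
        if (nrow(sub) == 0 || all(is.na(sub$value))) next
        agg <- stats::aggregate(value ~ window_mid_s, sub, mean)
        if (nrow(agg) < 3) next
        tr <- linear_trend(agg$value, agg$window_mid_s, "seconds")
        trends[[paste(cond, ch, bd)]] <-
          data.frame(condition = cond, index = paste(ch, bd),
                     slope = tr$slope, p = tr$p_value, n = tr$n_points)
      }
    }
    for (ix in c("hr", "rmssd", "pnn50", "sdrr")) {
      sub <- hrv[hrv$condition == cond, ]
      agg <- stats::aggregate(stats::as.formula(paste(ix, "~ window_index")),
                              sub, mean)
      if (nrow(agg) < 3) next
      tr <- linear_trend(agg[[ix]], agg$window_index, "index")
      trends[[paste(cond, ix)]] <-
        data.frame(condition = cond, index = ix, slope = tr$slope,
                   p = tr$p_value, n = tr$n_points)
    }
  }
  utils::write.csv(do.call(rbind, trends), file.path(out_dir, "trends.csv"),
                   row.names = FALSE)
  "trends.csv"
}

stage_report <- function(out_dir, ...) {
  require_upstream(out_dir, "trends.csv", "link")
  tr <- utils::read.csv(file.path(out_dir, "trends.csv"))
  lines <- c("vcfatigue pipeline report",
             sprintf("generated: %s", format(Sys.time())),
             "", "Per-condition linear trends (slope, p):",
             sprintf("  %-16s %-12s %+.4g (p=%.3g)",
                     tr$condition, tr$index, tr$slope, tr$p))
  writeLines(lines, file.path(out_dir, "report.txt"))
  "report.txt"
}
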
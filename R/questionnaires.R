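#' BMIS mood scores
#'
#' Positive score = sum of the 8 pleasant adjectives, negative score = sum of
#' the 8 unpleasant adjectives, overall = positive - negative (range -24 to
#' 24 for 1-4 ratings under the 8/8 polarity split).
#'
#' @param scores named numeric vector (or 1-row data.frame slice) holding all
#'   16 item scores, names as in [bmis_items()].
#' @return list: `positive`, `negative`, `overall`.
#' @export
bmis_scores <- function(scores) {
  it <- bmis_items()
  scores <- unlist(scores[it$item])
  assert_that(length(scores) == 16 && !anyNA(scores),
              "all 16 BMIS items required (no imputation)")
  assert_that(all(scores %in% 1:4), "BMIS items must be integers 1-4")
  pos <- sum(scores[it$item[it$polarity == "pleasant"]])
  neg <- sum(scores[it$item[it$polarity == "unpleasant"]])
  list(positive = pos, negative = neg, overall = pos - neg)
}

#' ZEF fatigue scores
#'
#' Overall = mean of all 18 items; dimension scores = means of each
#' dimension's three items (general, visual, social, motivational,
#' emotional); the three unassigned items enter only the overall mean.
#'
#' @param scores named numeric vector with all 18 items (`zef01`..`zef18`).
#' @return list: `overall`, `dimensions` (named numeric).
#' @export
zef_scores <- function(scores) {
  it <- zef_items()
  scores <- unlist(scores[it$item])
  assert_that(length(scores) == 18 && !anyNA(scores),
              "all 18 ZEF items required (no imputation)")
  assert_that(all(scores %in% 1:5), "ZEF items must be integers 1-5")
  dims <- setdiff(unique(it$dimension), "unassigned")
  dm <- vapply(dims, function(d) mean(scores[it$item[it$dimension == d]]), 0)
  list(overall = mean(scores), dimensions = dm)
}

#' Cronbach's alpha
#'
#' `k/(k-1) * (1 - sum(item variances) / variance of item sums)`.
#'
#' @param item_matrix numeric matrix subjects x items (>= 3 subjects,
#'   >= 2 items).
#' @return alpha, or `NA` when the total-score variance is zero.
#' @export
cronbach_alpha <- function(item_matrix) {
  item_matrix <- as.matrix(item_matrix)
  k <- ncol(item_matrix)
  assert_that(k >= 2 && nrow(item_matrix) >= 3,
              "need >= 2 items and >= 3 subjects")
  tot_var <- stats::var(rowSums(item_matrix))
  if (!is.finite(tot_var) || tot_var == 0) return(NA_real_)
  k / (k - 1) * (1 - sum(apply(item_matrix, 2, stats::var)) / tot_var)
}

# Wilcoxon signed-rank on paired values: exact distribution for <= 25
# non-zero pairs (when tie-free), normal approximation with continuity
# correction otherwise. All-zero differences give p = 1.
paired_wilcoxon <- function(a, b) {
  d <- a - b
  if (all(d == 0)) return(list(statistic = 0, p = 1))
  nz <- sum(d != 0)
  exact <- nz <= 25 && !any(duplicated(abs(d[d != 0])))
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                            exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                       ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Paired condition comparisons with BH correction
#'
#' Wilcoxon signed-rank test per item on paired per-subject values
#' (videoconference vs face-to-face), Benjamini-Hochberg adjustment across
#' items, significance stars at 0.05 / 0.01 / 0.001.
#'
#' @param a,b numeric matrices subjects x items (same subjects, same order);
#'   vectors are treated as single items.
#' @param items item labels (defaults to column names).
#' @return data.frame: `item`, `statistic`, `p`, `p_adj`, `stars`.
#' @export
paired_condition_tests <- function(a, b, items = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  assert_that(all(dim(a) == dim(b)), "paired matrices must match in shape")
  items <- items %||% colnames(a) %||% sprintf("item%02d", seq_len(ncol(a)))
  res <- lapply(seq_len(ncol(a)), function(j) paired_wilcoxon(a[, j], b[, j]))
  p <- vapply(res, `[[`, 0, "p")
  padj <- bh_adjust(p)
  data.frame(item = items,
             statistic = vapply(res, `[[`, 0, "statistic"),
             p = p, p_adj = padj, stars = significance_stars(padj))
}

#' Lecture-order effect check (mixed model)
#'
#' Fits score ~ order + lecture_type + order:lecture_type + (1 | subject)
#' over both conditions, returning the fixed-effect table. `order` labels the
#' starting condition of each subject (carry-over check in a crossover
#' design).
#'
#' @param scores numeric vector, one value per subject x condition row.
#' @param subject subject identifiers.
#' @param lecture_type condition factor ("videoconference"/"face_to_face").
#' @param order starting-condition factor per row (constant within subject).
#' @return data.frame: `term`, `estimate`, `se`, `p`, `fallback`. Factors are
#'   sum-to-zero coded, so each main-effect estimate is half the
#'   corresponding group difference, averaged over the other factor.
#' @export
order_effect_check <- function(scores, subject, lecture_type, order) {
  d <- data.frame(y = scores,
                  lecture = factor(lecture_type),
                  ord = factor(order))
  # sum-to-zero coding: main effects are averages over the other factor
  stats::contrasts(d$lecture) <- stats::contr.sum(2)
  stats::contrasts(d$ord) <- stats::contr.sum(2)
  f <- fit_lme_all(y ~ ord * lecture, d, subject)
  out <- f$table[f$table$term != "(Intercept)", ]
  out$term <- c("order", "lecture", "order:lecture")[seq_len(nrow(out))]
  out$fallback <- f$fallback
  row.names(out) <- NULL
  out
}
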